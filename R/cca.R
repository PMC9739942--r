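#' Assemble derivation matrices for canonical correlation
#'
#' Builds the two matrices the derivation stage correlates: `X1` holds the
#' per-stride tunable constant of the magnitude-range model,
#' `K_i = d_ref_i / a_r_i^0.1`, and `X2` holds candidate gait parameters
#' per stride — stride frequency, stride duration, and the mean, median and
#' range of a marker's filtered acceleration and velocity in each of the
#' three dimensions (2 + 2*3*3 = 20 columns).  Rows align by stride;
#' strides with `a_r = 0` or any non-finite assembled value are dropped
#' with a message.
#'
#' @param strides stride table with finite positive `d_ref` and `a_r`, and
#'   `t_start`/`t_end` giving each stride's time window.
#' @param kin a [marker_kinematics] result for one marker spanning the
#'   strides.
#' @return list of class `derivation_matrices` with `X1` (n x 1), `X2`
#'   (n x 20, labeled columns), `dropped` (row count removed).
#' @export
build_cca_matrices <- function(strides, kin) {
  stopifnot(inherits(kin, "kinematic_series"))
  need <- c("d_ref", "a_r", "F", "duration", "t_start", "t_end")
  check_features(strides, need)
  ok <- is.finite(strides$d_ref) & strides$d_ref > 0 & strides$a_r > 0
  dropped <- sum(!ok)
  if (dropped)
    message(sprintf("build_cca_matrices: dropped %d stride(s) with zero a_r or missing d_ref",
                    dropped))
  s <- strides[ok, , drop = FALSE]
  if (!nrow(s)) stopf("no usable strides for the derivation matrices")
  dims <- c("x", "y", "z")
  stat_block <- function(mat, idx, prefix) {
    vals <- lapply(seq_len(3L), function(j) {
      v <- mat[idx, j]
      c(mean(v), stats::median(v), diff(range(v)))
    })
    out <- unlist(vals)
    names(out) <- as.vector(vapply(dims, function(d)
      paste0(c("mean_", "median_", "range_"), prefix, "_", d),
      character(3)))
    out
  }
  rows <- lapply(seq_len(nrow(s)), function(i) {
    idx <- which(kin$t >= s$t_start[i] & kin$t < s$t_end[i])
    if (length(idx) < 2L) return(NULL)
    c(F = s$F[i], duration = s$duration[i],
      stat_block(kin$acceleration, idx, "acc"),
      stat_block(kin$velocity, idx, "vel"))
  })
  keep <- !vapply(rows, is.null, logical(1))
  X2 <- do.call(rbind, rows[keep])
  X1 <- matrix(s$d_ref[keep] / s$a_r[keep]^0.1, ncol = 1L,
               dimnames = list(NULL, "K"))
  fin <- apply(cbind(X1, X2), 1L, function(r) all(is.finite(r)))
  if (any(!fin))
    message(sprintf("build_cca_matrices: dropped %d row(s) with non-finite entries",
                    sum(!fin)))
  structure(list(X1 = X1[fin, , drop = FALSE], X2 = X2[fin, , drop = FALSE],
                 dropped = dropped + sum(!keep) + sum(!fin)),
            class = "derivation_matrices")
}

#' Canonical correlation between constants and gait parameters
#'
#' Columns of both matrices are centered and scaled to unit variance
#' (zero-variance columns of `X2` are dropped with a warning), then the
#' canonical pairs are computed.  Correlations are clamped to `[0, 1]` and
#' sorted non-increasing.  With a single-column `X1`, the first canonical
#' correlation equals the multiple correlation coefficient of regressing
#' `X1` on `X2`.
#'
#' @param X1 n x p1 numeric matrix (per-stride constants).
#' @param X2 n x p2 numeric matrix (candidate parameters, labeled columns).
#' @param flag_threshold first-correlation level below which the result is
#'   flagged as uninformative (rankings from near-noise data).
#' @return object of class `sl_cca`: `correlations`, coefficient matrices
#'   `A1`, `A2` (rows = retained columns), `standardized_A2` (coefficients
#'   on the unit-variance scale used for ranking), `kept` (retained X2
#'   column labels), `flagged` (logical).
#' @export
sl_cca <- function(X1, X2, flag_threshold = 0.1) {
  if (inherits(X1, "derivation_matrices")) {
    X2 <- X1$X2; X1 <- X1$X1
  }
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (nrow(X1) != nrow(X2)) stopf("X1 and X2 must have equal row counts")
  if (nrow(X2) <= ncol(X2) + 1L)
    stopf("need more strides (%d) than parameters + 1 (%d)",
          nrow(X2), ncol(X2) + 1L)
  if (is.null(colnames(X2)))
    colnames(X2) <- paste0("V", seq_len(ncol(X2)))
  sds <- apply(X2, 2L, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop))
    warnf("dropping zero-variance column(s): %s",
          paste(colnames(X2)[drop], collapse = ", "))
  X2 <- X2[, !drop, drop = FALSE]
  if (!ncol(X2)) stopf("no X2 columns left after zero-variance drops")
  Z1 <- scale(X1)
  Z2 <- scale(X2)
  qr2 <- qr(Z2)
  if (qr2$rank < ncol(Z2)) {
    dep <- colnames(Z2)[qr2$pivot[(qr2$rank + 1L):ncol(Z2)]]
    stopf("rank-deficient X2 after scaling: linearly dependent column(s) %s",
          paste(dep, collapse = ", "))
  }
  cc <- stats::cancor(Z1, Z2, xcenter = FALSE, ycenter = FALSE)
  cors <- sort(pmin(1, pmax(0, cc$cor)), decreasing = TRUE)
  ## cancor coefficient rows follow the input columns; inputs are already
  ## unit variance, so ycoef IS the standardized coefficient matrix
  A2 <- cc$ycoef
  rownames(A2) <- colnames(Z2)
  A1 <- cc$xcoef
  rownames(A1) <- colnames(X1)
  structure(list(correlations = cors, A1 = A1, A2 = A2,
                 standardized_A2 = A2, kept = colnames(Z2),
                 flagged = cors[1L] < flag_threshold,
                 flag_threshold = flag_threshold, n = nrow(Z2)),
            class = "sl_cca")
}

#' @export
print.sl_cca <- function(x, ...) {
  cat(sprintf("Canonical correlation (n = %d, %d parameter column(s))\n",
              x$n, length(x$kept)))
  cat("  correlations:", paste(sprintf("%.4f", x$correlations),
                               collapse = ", "), "\n")
  if (x$flagged)
    cat(sprintf("  flagged: first correlation below %.2f; ranking likely uninformative\n",
                x$flag_threshold))
  top <- utils::head(rank_parameters(x), 3L)
  cat("  top parameters:",
      paste(sprintf("%s (%.3f)", top$parameter, top$coefficient),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rank gait parameters by canonical contribution
#'
#' Orders the retained parameter columns by the absolute value of their
#' standardized first-pair canonical coefficient, the scale-free measure of
#' how much each parameter contributes to the linear combination most
#' correlated with the per-stride constants.  Ties break by column order.
#'
#' @param result an [sl_cca] result.
#' @return data frame with columns `parameter`, `coefficient` (absolute
#'   standardized first-pair coefficient), `rank`.
#' @export
rank_parameters <- function(result) {
  stopifnot(inherits(result, "sl_cca"))
  w <- abs(result$standardized_A2[, 1L])
  ord <- order(-w, seq_along(w))
  data.frame(parameter = names(w)[ord], coefficient = unname(w[ord]),
             rank = seq_along(w), row.names = NULL)
}
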