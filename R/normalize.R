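#' Inter-array quantile normalisation
#'
#' Maps every sample's beta values onto a common reference distribution —
#' the mean of the per-sample order statistics — so that all samples share
#' the same marginal distribution while within-sample ranks are preserved.
#' With complete data the reference is exactly the row mean of the sorted
#' columns. Missing entries stay missing: each sample's ranks are computed
#' on its non-missing values and the reference quantiles are linearly
#' interpolated to that sample's own number of observations. Tied values
#' receive the mean of the reference values at their tied rank positions.
#'
#' @param beta A [beta_matrix()] with at least two samples.
#' @return A [beta_matrix()] of the same shape; values stay in \[0, 1\]
#'   because the reference is an average of values in \[0, 1\].
#' @export
quantile_normalize <- function(beta) {
  x <- beta$values
  n_probe <- nrow(x); n_samp <- ncol(x)
  if (n_samp < 2) stop("quantile normalisation needs at least 2 samples")
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0))
    stop("sample with no non-missing values: ",
         colnames(x)[n_obs == 0][1L])

  grid <- seq(0, 1, length.out = n_probe)
  ref_cols <- vapply(seq_len(n_samp), function(j) {
    v <- sort(x[, j][!is.na(x[, j])])
    if (length(v) == n_probe) v
    else if (length(v) == 1L) rep(v, n_probe)
    else approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n_probe))
  ref <- rowMeans(ref_cols)

  out <- x
  for (j in seq_len(n_samp)) {
    idx <- which(!is.na(x[, j]))
    v <- x[idx, j]
    nj <- length(v)
    refj <- if (nj == n_probe) ref
            else approx(seq(0, 1, length.out = n_probe), ref,
                        xout = seq(0, 1, length.out = nj))$y
    o <- order(v)
    # ties: average the reference over each run of equal input values
    vs <- v[o]
    runs <- cumsum(c(TRUE, vs[-1] != vs[-nj]))
    mapped <- stats::ave(refj, runs)
    out[idx[o], j] <- mapped
  }
  beta_matrix(out, beta$detected)
}

#' Impute missing beta values by per-probe means
#'
#' SVD-based steps need a complete matrix; missing entries are replaced by
#' the probe's mean across samples (per-CpG Cox fits instead drop the
#' affected samples, so imputation never feeds the regression predictor).
#'
#' @param beta A [beta_matrix()].
#' @return A complete [beta_matrix()]; the detection mask is unchanged, so
#'   imputed entries remain flagged as undetected.
#' @export
impute_probe_means <- function(beta) {
  x <- beta$values
  if (!anyNA(x)) return(beta)
  rm <- rowMeans(x, na.rm = TRUE)
  rm[is.nan(rm)] <- mean(x, na.rm = TRUE)  # probe with no data at all
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- rm[idx[, 1L]]
  structure(list(values = x, detected = beta$detected),
            class = "beta_matrix")
}

#' Remove the dominant mean-profile component
#'
#' The leading component of an (uncentred) SVD of a methylation beta matrix
#' captures the bimodal mean methylation profile — typically over 90% of the
#' total variation — and is uninformative about phenotype. This function
#' subtracts the best rank-1 approximation, which is essentially equivalent
#' to normalising the matrix by its mean profile, so that the significance
#' of the remaining components can be judged.
#'
#' @param beta A complete [beta_matrix()] (impute first, see
#'   [impute_probe_means()]) or a plain numeric matrix.
#' @return An object of class `adjusted_beta`: list with `values` (input
#'   minus its rank-1 approximation), `removed_fraction`
#'   (\eqn{\sigma_1^2/\sum_k \sigma_k^2} of the input) and the probe/sample
#'   ids.
#' @export
adjust_top_component <- function(beta) {
  x <- if (inherits(beta, "beta_matrix")) beta$values else beta
  if (anyNA(x))
    stop("matrix must be complete; impute missing values first")
  s <- svd(x)
  if (s$d[1L] <= 0) stop("degenerate all-zero input matrix")
  adj <- x - s$d[1L] * tcrossprod(s$u[, 1L], s$v[, 1L])
  dimnames(adj) <- dimnames(x)
  structure(list(values = adj,
                 removed_fraction = s$d[1L]^2 / sum(s$d^2)),
            class = "adjusted_beta")
}

#' @export
print.adjusted_beta <- function(x, ...) {
  cat(sprintf(
    "adjusted_beta: %d probes x %d samples; removed top component (%.1f%% of variation)\n",
    nrow(x$values), ncol(x$values), 100 * x$removed_fraction))
  invisible(x)
}

adjusted_values <- function(x) {
  if (inherits(x, "adjusted_beta")) x$values
  else if (inherits(x, "beta_matrix")) x$values
  else as.matrix(x)
}
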