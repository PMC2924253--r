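#' Compute methylation beta values from channel intensities
#'
#' The beta value of a CpG is the ratio of the methylated-channel signal to
#' the total (methylated plus unmethylated) signal, optionally stabilised by
#' a nonnegative offset added to the denominator:
#' \deqn{\beta = M / (M + U + \alpha)}
#' Beta ranges from 0 (unmethylated) to 1 (fully methylated).
#'
#' @param m_signal Nonnegative methylated-channel intensity (vectorised).
#' @param u_signal Nonnegative unmethylated-channel intensity.
#' @param offset Nonnegative regularisation constant added to the
#'   denominator; default 0 (the plain ratio). Vendor pipelines commonly use
#'   a positive constant (e.g. 100) to stabilise low-intensity probes.
#' @return Numeric vector of beta values in \[0, 1\].
#' @examples
#' compute_beta(500, 500)            # 0.5
#' compute_beta(300, 100, offset = 100)  # 0.6
#' @export
compute_beta <- function(m_signal, u_signal, offset = 0) {
  if (any(m_signal < 0) || any(u_signal < 0) || any(offset < 0))
    stop("signal intensities and offset must be nonnegative")
  denom <- m_signal + u_signal + offset
  if (any(denom == 0))
    stop("degenerate input: m_signal + u_signal + offset is zero")
  m_signal / denom
}

#' Construct a beta-value matrix object
#'
#' A `beta_matrix` holds a probes-by-samples matrix of methylation beta
#' values in \[0, 1\] together with a same-shape logical detection mask
#' (`TRUE` where the probe's signal was distinguishable from background).
#' Missing values (`NA`) are allowed and are always marked undetected.
#'
#' @param values Numeric matrix, probes in rows and samples in columns, with
#'   unique non-empty rownames (probe ids) and colnames (sample ids).
#' @param detected Optional logical matrix of the same shape; defaults to
#'   `!is.na(values)`. Entries with missing values are forced to `FALSE`.
#' @return An object of class `beta_matrix` with elements `values` and
#'   `detected`.
#' @export
beta_matrix <- function(values, detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop("values must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(pid))
    stop("duplicate probe id: ", pid[duplicated(pid)][1L])
  if (anyDuplicated(sid))
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("beta value out of [0,1] at probe '%s', sample '%s': %g",
                 pid[bad[1L, 1L]], sid[bad[1L, 2L]],
                 values[bad[1L, , drop = FALSE]]))
  if (is.null(detected)) detected <- !is.na(values)
  if (!is.logical(detected) || !identical(dim(detected), dim(values)))
    stop("detected must be a logical matrix with the shape of values")
  detected[is.na(values)] <- FALSE
  dimnames(detected) <- dimnames(values)
  structure(list(values = values, detected = detected),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("beta_matrix: %d probes x %d samples\n", nrow(v), ncol(v)))
  cat(sprintf("  detected: %.1f%%; missing: %d entries\n",
              100 * mean(x$detected), sum(is.na(v))))
  qs <- quantile(v, c(0, .25, .5, .75, 1), na.rm = TRUE)
  cat(sprintf("  beta quartiles: %s\n",
              paste(sprintf("%.3f", qs), collapse = " ")))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

probe_ids <- function(x) rownames(x$values)
sample_ids <- function(x) colnames(x$values)

# subset a beta_matrix by probe and/or sample ids (or indices)
subset_beta <- function(x, probes = NULL, samples = NULL) {
  v <- x$values; d <- x$detected
  if (!is.null(probes)) { v <- v[probes, , drop = FALSE]; d <- d[probes, , drop = FALSE] }
  if (!is.null(samples)) { v <- v[, samples, drop = FALSE]; d <- d[, samples, drop = FALSE] }
  beta_matrix(v, d)
}

#' Read a beta-value matrix from a tab-separated file
#'
#' Expects probes in rows and samples in columns (GEO series-matrix-like
#' layout): a header row of sample ids, first column probe ids. Empty cells
#' and the token `NA` are read as missing.
#'
#' @param path Path to the TSV file.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = c("", "NA"), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs a probe-id column plus samples")
  pid <- as.character(df[[1L]])
  if (anyDuplicated(pid))
    stop("duplicate probe id in ", path, ": ", pid[duplicated(pid)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- pid
  beta_matrix(m)
}

#' Write a beta-value matrix to a tab-separated file
#'
#' Inverse of [read_beta_matrix()]; missing entries are written as `NA`.
#'
#' @param beta A [beta_matrix()].
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = probe_ids(beta), beta$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
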