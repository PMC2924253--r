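#' Quality-control thresholds
#'
#' Bundles the thresholds used by [sample_qc()] and [probe_filter()].
#' The defaults remove samples whose coverage (fraction of probes detected
#' above background) falls below 0.75 or whose worse bisulphite-conversion
#' metric falls below 0.90 (on a scale where complete conversion is ~1),
#' and retain probes detected in at least 95% of the retained samples.
#'
#' @param min_sample_coverage Minimum per-sample coverage fraction.
#' @param bsce_min Minimum acceptable conversion-efficiency metric.
#' @param min_probe_detection_rate Minimum fraction of retained samples in
#'   which a probe must be detected.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_sample_coverage = 0.75, bsce_min = 0.90,
                          min_probe_detection_rate = 0.95) {
  stopifnot(min_sample_coverage >= 0, min_sample_coverage <= 1,
            bsce_min >= 0,
            min_probe_detection_rate >= 0, min_probe_detection_rate <= 1)
  structure(list(min_sample_coverage = min_sample_coverage,
                 bsce_min = bsce_min,
                 min_probe_detection_rate = min_probe_detection_rate),
            class = "qc_thresholds")
}

#' Per-sample quality control
#'
#' Flags and removes samples with low coverage (fraction of probes with a
#' detectable signal above background) or poor bisulphite conversion
#' efficiency. A sample is removed iff its coverage is below
#' `min_sample_coverage` or `min(bsce_c1, bsce_c2)` is below `bsce_min`.
#'
#' @param beta A [beta_matrix()].
#' @param samples Sample table as returned by [read_sample_sheet()];
#'   sample ids must match the matrix columns (any order).
#' @param thresholds A [qc_thresholds()] object.
#' @return An object of class `qc_report` with per-sample coverage, BSCE
#'   flags, removed samples with reason codes, and retained sample ids.
#' @export
sample_qc <- function(beta, samples, thresholds = qc_thresholds()) {
  sid <- sample_ids(beta)
  if (!setequal(sid, samples$sample_id))
    stop("sample ids in the beta matrix and sample sheet do not match")
  samples <- samples[match(sid, samples$sample_id), , drop = FALSE]
  coverage <- colMeans(beta$detected)
  bsce <- pmin(samples$bsce_c1, samples$bsce_c2)
  low_cov <- coverage < thresholds$min_sample_coverage
  low_bsce <- bsce < thresholds$bsce_min
  reason <- ifelse(low_cov & low_bsce, "coverage+bsce",
                   ifelse(low_cov, "coverage",
                          ifelse(low_bsce, "bsce", "")))
  removed <- sid[low_cov | low_bsce]
  structure(list(
    coverage = setNames(coverage, sid),
    bsce = setNames(bsce, sid),
    bsce_pass = setNames(!low_bsce, sid),
    removed = data.frame(sample_id = removed,
                         reason = reason[low_cov | low_bsce],
                         stringsAsFactors = FALSE),
    retained = sid[!(low_cov | low_bsce)],
    thresholds = thresholds
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  n <- length(x$coverage)
  cat(sprintf("sample QC: %d samples in, %d removed, %d retained\n",
              n, nrow(x$removed), length(x$retained)))
  if (nrow(x$removed) > 0) {
    cat("  removed:\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("    %s (%s; coverage %.3f, bsce %.3f)\n",
                  x$removed$sample_id[i], x$removed$reason[i],
                  x$coverage[x$removed$sample_id[i]],
                  x$bsce[x$removed$sample_id[i]]))
  }
  invisible(x)
}

#' Probe-level detection filter
#'
#' Retains a probe iff it is detected in at least
#' `min_probe_detection_rate` of the retained samples. Output order follows
#' the input probe order.
#'
#' @param beta A [beta_matrix()].
#' @param retained_samples Character vector of sample ids surviving
#'   [sample_qc()].
#' @param thresholds A [qc_thresholds()] object.
#' @return Character vector of retained probe ids.
#' @export
probe_filter <- function(beta, retained_samples,
                         thresholds = qc_thresholds()) {
  if (length(retained_samples) == 0)
    stop("retained_samples must be nonempty")
  det <- beta$detected[, retained_samples, drop = FALSE]
  rate <- rowMeans(det)
  probe_ids(beta)[rate >= thresholds$min_probe_detection_rate]
}

#' Apply sample and probe QC in one step
#'
#' Convenience wrapper running [sample_qc()] then [probe_filter()] and
#' subsetting the matrix and sample table to the retained set. The report
#' gains `retained_probes` and `global_coverage` (mean detection fraction
#' over the retained matrix).
#'
#' @inheritParams sample_qc
#' @return List with `beta`, `samples` (both filtered) and `report`.
#' @export
apply_qc <- function(beta, samples, thresholds = qc_thresholds()) {
  rep <- sample_qc(beta, samples, thresholds)
  probes <- probe_filter(beta, rep$retained, thresholds)
  out <- subset_beta(beta, probes = probes, samples = rep$retained)
  rep$retained_probes <- probes
  rep$global_coverage <- mean(out$detected)
  list(beta = out,
       samples = droplevels(samples[match(rep$retained, samples$sample_id), ,
                                    drop = FALSE]),
       report = rep)
}
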