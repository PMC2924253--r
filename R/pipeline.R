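#' Run the full methylation survival-EWAS pipeline
#'
#' Orchestrates the stages in order: sample/probe QC, inter-array quantile
#' normalisation, per-probe mean imputation, removal of the dominant
#' mean-profile component, the SVD significance screen with its
#' permutation null and component-by-factor association matrix, the
#' per-CpG multivariate Cox scan with q-value FDR, and the proximal-pair
#' analysis. When `out_dir` is given, per-stage artifacts, a run log and a
#' machine-readable JSON summary are written there; reruns with the same
#' inputs and seed are byte-identical.
#'
#' @param beta A [beta_matrix()] (or path to a beta TSV).
#' @param samples Sample table (or path to a sample-sheet CSV).
#' @param manifest Probe manifest (or path to a manifest CSV); may be
#'   `NULL` to skip the pair analysis.
#' @param thresholds A [qc_thresholds()].
#' @param n_permutations,seed SVD null settings.
#' @param covariates,ties_method,predictor_scaling,pi0_method Passed to
#'   [run_ewas()].
#' @param fdr_thresholds FDR levels summarised (default 0.05 and 0.15).
#' @param max_pair_dist Maximum proximal-pair distance in bp.
#' @param factor_spec Passed to [associate_components()].
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `methsurv_run` bundling every stage result
#'   plus a `summary` list (sample/probe counts per stage, removed
#'   variance fraction, significant components, directional hit counts).
#' @export
run_pipeline <- function(beta, samples, manifest = NULL,
                         thresholds = qc_thresholds(),
                         n_permutations = 10, seed = 1,
                         covariates = c("chip", "bsce_c1", "bsce_c2",
                                        "sex", "cohort", "age_at_draw"),
                         ties_method = "efron",
                         predictor_scaling = "zscore",
                         pi0_method = "smoother",
                         fdr_thresholds = c(0.05, 0.15),
                         max_pair_dist = 1000,
                         factor_spec = default_factor_spec(),
                         out_dir = NULL) {
  if (is.character(beta)) beta <- read_beta_matrix(beta)
  if (is.character(samples)) samples <- read_sample_sheet(samples)
  if (is.character(manifest)) manifest <- read_probe_manifest(manifest)
  stopifnot(all(fdr_thresholds > 0), all(fdr_thresholds < 1))

  qc <- apply_qc(beta, samples, thresholds)
  norm <- quantile_normalize(qc$beta)
  complete <- impute_probe_means(norm)
  adjusted <- adjust_top_component(complete)

  screen <- svd_decompose(adjusted,
                          n_components = min(dim(adjusted$values)) - 1L)
  null <- permutation_null(adjusted, n_permutations = n_permutations,
                           seed = seed)
  screen <- select_significant_components(screen, null)
  assoc_comps <- if (length(screen$significant_components) > 0)
    screen$significant_components else seq_len(min(5L, nrow(screen$sample_scores)))
  assoc <- associate_components(screen, qc$samples,
                                factor_spec = factor_spec,
                                components = assoc_comps)

  ewas <- run_ewas(adjusted, qc$samples, covariates = covariates,
                   ties_method = ties_method,
                   predictor_scaling = predictor_scaling,
                   pi0_method = pi0_method)
  pairs <- if (!is.null(manifest))
    combine_proximal_pairs(adjusted, manifest, qc$samples,
                           max_dist = max_pair_dist,
                           covariates = covariates,
                           ties_method = ties_method,
                           pi0_method = pi0_method)
  else NULL

  hits <- lapply(fdr_thresholds, function(th) count_directional(ewas, th))
  names(hits) <- sprintf("fdr_%g", fdr_thresholds)
  summary <- list(
    n_samples_in = ncol(beta$values),
    n_samples_retained = length(qc$report$retained),
    n_probes_in = nrow(beta$values),
    n_probes_retained = length(qc$report$retained_probes),
    global_coverage = qc$report$global_coverage,
    removed_variance_fraction = adjusted$removed_fraction,
    significant_components = screen$significant_components,
    pi0 = ewas$pi0,
    hits = lapply(hits, as.list),
    n_pairs = if (is.null(pairs)) NA_integer_ else nrow(pairs),
    seed = seed)

  run <- structure(list(qc = qc$report, samples = qc$samples,
                        normalized = norm, adjusted = adjusted,
                        screen = screen, null = null, assoc = assoc,
                        ewas = ewas, pairs = pairs, manifest = manifest,
                        summary = summary),
                   class = "methsurv_run")
  if (!is.null(out_dir)) write_run_artifacts(run, out_dir)
  run
}

#' @export
print.methsurv_run <- function(x, ...) {
  s <- x$summary
  cat("methylation survival-EWAS run\n")
  cat(sprintf("  samples: %d in, %d retained; probes: %d in, %d retained\n",
              s$n_samples_in, s$n_samples_retained,
              s$n_probes_in, s$n_probes_retained))
  cat(sprintf("  top component removed: %.1f%% of variation\n",
              100 * s$removed_variance_fraction))
  cat(sprintf("  significant components: %s\n",
              if (length(s$significant_components) == 0) "none"
              else paste(s$significant_components, collapse = ", ")))
  for (nm in names(s$hits))
    cat(sprintf("  %s: %d increased, %d decreased risk\n", nm,
                s$hits[[nm]]$increased, s$hits[[nm]]$decreased))
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_ewas_table(run$ewas, file.path(out_dir, "ewas.tsv"),
                   manifest = run$manifest)
  if (!is.null(run$pairs)) {
    pt <- as.data.frame(run$pairs)
    num <- vapply(pt, is.numeric, logical(1))
    pt[num] <- lapply(pt[num], function(v) signif(v, 6))
    write.table(pt, file.path(out_dir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(
    data.frame(component = rownames(run$assoc$p_values),
               signif(run$assoc$p_values, 4), check.names = FALSE),
    file.path(out_dir, "component_factor_pvalues.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(
    data.frame(component = rownames(run$assoc$bins), run$assoc$bins,
               check.names = FALSE),
    file.path(out_dir, "component_factor_bins.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$summary,
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_lines <- c(
    sprintf("survewas %s", as.character(utils::packageVersion("survewas"))),
    sprintf("seed: %d", run$summary$seed),
    sprintf("samples retained: %d/%d", run$summary$n_samples_retained,
            run$summary$n_samples_in),
    sprintf("probes retained: %d/%d", run$summary$n_probes_retained,
            run$summary$n_probes_in))
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' Export machine-readable figure data
#'
#' Writes plain data files corresponding to the pipeline's diagnostic
#' views: per-group beta histograms, the observed-versus-null
#' variance-fraction table, the component-by-factor p-value/bin matrices,
#' the EWAS p-value histogram, and per-probe case/control Z-score
#' summaries for named probes.
#'
#' @param run A [run_pipeline()] result.
#' @param directory Output directory (created if needed).
#' @param probes Probe ids for the Z-score summary (default: top EWAS hit).
#' @return The directory, invisibly.
#' @export
export_figure_data <- function(run, directory, probes = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  ## (a) per-group beta histograms
  v <- run$normalized$values
  grp <- as.character(run$samples$group)[
    match(colnames(v), run$samples$sample_id)]
  brk <- seq(0, 1, 0.02)
  hg <- lapply(c("control", "case"), function(g) {
    vals <- v[, grp == g, drop = FALSE]
    hist(vals[!is.na(vals)], breaks = brk, plot = FALSE)$counts
  })
  write.table(data.frame(bin_low = head(brk, -1), bin_high = brk[-1],
                         controls = hg[[1]], cases = hg[[2]]),
              file.path(directory, "beta_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## (b) observed vs null variance fractions
  k <- run$screen$n_components_evaluated
  nf <- run$null$null_fractions[, seq_len(k), drop = FALSE]
  write.table(data.frame(component = seq_len(k),
                         observed = signif(run$screen$variance_fractions[seq_len(k)], 6),
                         null_mean = signif(colMeans(nf), 6),
                         null_max = signif(apply(nf, 2, max), 6)),
              file.path(directory, "variance_fractions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## (c) component x factor p-values and bins
  write.table(data.frame(component = rownames(run$assoc$p_values),
                         signif(run$assoc$p_values, 4), check.names = FALSE),
              file.path(directory, "component_factor_pvalues.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(component = rownames(run$assoc$bins),
                         run$assoc$bins, check.names = FALSE),
              file.path(directory, "component_factor_bins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## (d) EWAS p-value histogram
  pb <- seq(0, 1, 0.05)
  pc <- hist(run$ewas$table$p, breaks = pb, plot = FALSE)$counts
  write.table(data.frame(bin_low = head(pb, -1), bin_high = pb[-1],
                         count = pc),
              file.path(directory, "ewas_pvalue_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ## (e) per-probe case/control Z-score summaries
  if (is.null(probes))
    probes <- run$ewas$table$probe_id[which.min(run$ewas$table$p)]
  av <- run$adjusted$values
  missing_probes <- setdiff(probes, rownames(av))
  if (length(missing_probes) > 0)
    stop("probe(s) not in the adjusted matrix: ",
         paste(missing_probes, collapse = ", "),
         "; available ids are the rownames of the adjusted matrix (",
         nrow(av), " probes, e.g. ", rownames(av)[1L], ")")
  zsum <- do.call(rbind, lapply(probes, function(pr) {
    z <- as.numeric(scale(av[pr, ]))
    data.frame(probe_id = pr,
               mean_z_cases = mean(z[grp == "case"]),
               mean_z_controls = mean(z[grp == "control"]))
  }))
  write.table(zsum, file.path(directory, "probe_zscore_groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}
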