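#' Configuration for the Infinium-27K-style simulator
#'
#' Bundles every generative parameter of [simulate_dataset()]. Defaults
#' describe a desk-scale stand-in for a 27K nephropathy cohort:
#' 200 samples x 2,000 probes, a bimodal beta distribution with a large
#' hypomethylated and a small hypermethylated class, chip/cohort/sex/age/
#' BSCE-linked components of technical and biological variation, and a
#' proportional-hazards link between a small planted CpG subset and time
#' from diabetes diagnosis to nephropathy onset.
#'
#' @param n_samples,n_probes Matrix dimensions (default 200 x 2000).
#' @param case_fraction Target fraction of samples with an observed event
#'   (default 0.5, mirroring a matched case/control design).
#' @param seed Integer root seed; all randomness derives from it.
#' @param mixture_weights Probe-class weights (hypo, mid, hyper); must sum
#'   to 1. Default c(0.70, 0.15, 0.15).
#' @param mixture_centers Class mean beta levels, default c(0.10, 0.50,
#'   0.85).
#' @param probe_logit_sd SD of probe baselines around their class centre on
#'   the logit scale (default 0.5).
#' @param batch_effect_sd SD of per-chip logit shifts on the chip-affected
#'   probe subset (default 0.3); `batch_probe_fraction` sets that subset's
#'   size (default 0.2).
#' @param cohort_effect_sd,cohort_probe_fraction Analogous recruitment-site
#'   effect (defaults 0.2, 0.1); `cohort_count` sites (default 2).
#' @param sex_effect_sd Logit shift added for females on the X-linked
#'   probe subset (default 1.0); `x_probe_fraction` default 0.04.
#' @param age_effect_sd SD of per-probe slopes on standardised age at draw
#'   over the age-affected subset (defaults 0.2, fraction 0.1).
#' @param bsce_artifact_sd Magnitude of the conversion-efficiency artifact:
#'   a per-sample continuous score shifts a random 10% probe subset
#'   (default 0.3).
#' @param noise_sd Logit-scale measurement noise SD (default 0.5).
#' @param n_causal Number of CpGs with a planted survival effect (default
#'   10); `causal_coef` is the true log hazard ratio per SD of methylation
#'   (default 0.6).
#' @param baseline_hazard_scale Exponential baseline scale in years
#'   (default 15; recalibrated to hit `case_fraction`, see
#'   [simulate_survival()]).
#' @param censor_time_range Administrative censoring window in years,
#'   default c(5, 40).
#' @param detection_dropout_rate Per-entry probability that a probe is not
#'   detected above background (value missing), default 0.005.
#' @param n_fail_bsce,n_low_coverage Number of planted QC-failure samples
#'   (defaults 0): BSCE failures get conversion metrics ~0.7; low-coverage
#'   samples get ~35% dropout and marginal BSCE, mimicking arrays a QC
#'   step should remove.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_probes = 2000,
                       case_fraction = 0.5, seed = 1,
                       mixture_weights = c(hypo = 0.70, mid = 0.15,
                                           hyper = 0.15),
                       mixture_centers = c(hypo = 0.10, mid = 0.50,
                                           hyper = 0.85),
                       probe_logit_sd = 0.5,
                       batch_effect_sd = 0.3, batch_probe_fraction = 0.2,
                       cohort_count = 2, cohort_effect_sd = 0.2,
                       cohort_probe_fraction = 0.1,
                       sex_effect_sd = 1.0, x_probe_fraction = 0.04,
                       age_effect_sd = 0.2, age_probe_fraction = 0.1,
                       bsce_artifact_sd = 0.3, bsce_probe_fraction = 0.1,
                       noise_sd = 0.5,
                       n_causal = 10, causal_coef = 0.6,
                       baseline_hazard_scale = 15,
                       censor_time_range = c(5, 40),
                       detection_dropout_rate = 0.005,
                       n_fail_bsce = 0, n_low_coverage = 0) {
  stopifnot(n_samples > 0, n_probes > 0,
            case_fraction >= 0, case_fraction <= 1,
            abs(sum(mixture_weights) - 1) < 1e-9,
            n_causal <= n_probes,
            detection_dropout_rate >= 0, detection_dropout_rate <= 1,
            length(censor_time_range) == 2,
            censor_time_range[1] > 0,
            censor_time_range[2] >= censor_time_range[1])
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

#' Simulate an Infinium-27K-style methylation survival dataset
#'
#' Draws probe baselines from a three-class (hypo/mid/hyper) mixture on the
#' logit scale, adds biological effects (sex on X-linked probes, age
#' slopes, the planted survival signal carrier probes' noise) and
#' logit-normal measurement noise, generates time-to-nephropathy from a
#' proportional-hazards model on the standardised values of the causal
#' probes, then overlays technical structure: chips assigned in blocks of
#' 12 samples with cases and controls interleaved ~50:50 per chip,
#' per-chip shifts on a probe subset, cohort shifts, and a continuous
#' conversion-efficiency artifact. Values are mapped back to (0, 1) with
#' the logistic function, so no clipping is ever needed; a detection mask
#' with the configured dropout marks missing entries.
#'
#' @param config A [sim_config()].
#' @return List of class `meth_sim` with `beta` ([beta_matrix()]),
#'   `samples` (sample table), `manifest` (probe manifest) and `truth`
#'   (class `sim_truth`: causal probe ids and coefficients, per-factor
#'   effect maps, latent event times, clipping count — structurally 0 —
#'   and the seed).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  np <- cfg$n_probes; ns <- cfg$n_samples
  pid <- sprintf("cg%08d", seq_len(np))
  sid <- sprintf("S%03d", seq_len(ns))

  ## probe baselines: three-class mixture on the logit scale
  cls <- sample(names(cfg$mixture_weights), np, replace = TRUE,
                prob = cfg$mixture_weights)
  mu <- qlogis(cfg$mixture_centers[cls]) + rnorm(np, 0, cfg$probe_logit_sd)

  ## sample phenotypes
  sex <- sample(c("F", "M"), ns, replace = TRUE)
  cohort <- paste0("site", sample.int(cfg$cohort_count, ns, replace = TRUE))
  age_dx <- runif(ns, 5, 30)

  ## effect carrier probe subsets
  x_probes <- sample.int(np, round(cfg$x_probe_fraction * np))
  age_probes <- sample.int(np, round(cfg$age_probe_fraction * np))
  age_slopes <- rnorm(length(age_probes), 0, cfg$age_effect_sd)
  batch_probes <- sample.int(np, round(cfg$batch_probe_fraction * np))
  cohort_probes <- sample.int(np, round(cfg$cohort_probe_fraction * np))
  bsce_probes <- sample.int(np, round(cfg$bsce_probe_fraction * np))
  causal <- sample.int(np, cfg$n_causal)

  ## biology: baseline + sex + noise (age added after ages are final)
  L <- matrix(mu, np, ns) + matrix(rnorm(np * ns, 0, cfg$noise_sd), np, ns)
  if (length(x_probes) > 0)
    L[x_probes, sex == "F"] <- L[x_probes, sex == "F"] + cfg$sex_effect_sd

  ## survival from standardised causal-probe biology
  zc <- t(scale(t(L[causal, , drop = FALSE])))
  surv <- simulate_survival(zc, rep(cfg$causal_coef, cfg$n_causal), cfg)

  duration <- ifelse(surv$event == 1L,
                     surv$time + runif(ns, 0, 5), surv$time)
  age_draw <- age_dx + duration
  z_age <- as.numeric(scale(age_draw))
  if (length(age_probes) > 0)
    L[age_probes, ] <- L[age_probes, ] + outer(age_slopes, z_age)

  ## chip assignment: interleave cases/controls, 12 samples per chip
  ord <- interleave_groups(which(surv$event == 1L), which(surv$event == 0L))
  chip <- integer(ns)
  chip[ord] <- (seq_len(ns) - 1L) %/% 12L + 1L
  n_chips <- max(chip)
  batch <- paste0("plate", (chip - 1L) %/% 8L + 1L)
  chip_lab <- paste0("chip", formatC(chip, width = 2, flag = "0"))

  ## technical overlays
  if (length(batch_probes) > 0 && cfg$batch_effect_sd > 0) {
    shifts <- matrix(rnorm(length(batch_probes) * n_chips, 0,
                           cfg$batch_effect_sd),
                     length(batch_probes), n_chips)
    L[batch_probes, ] <- L[batch_probes, ] + shifts[, chip]
  }
  if (length(cohort_probes) > 0 && cfg$cohort_effect_sd > 0) {
    co_lev <- sort(unique(cohort))
    co_shift <- matrix(rnorm(length(cohort_probes) * length(co_lev), 0,
                             cfg$cohort_effect_sd),
                       length(cohort_probes), length(co_lev))
    L[cohort_probes, ] <- L[cohort_probes, ] +
      co_shift[, match(cohort, co_lev)]
  }
  bsce_c1 <- pmin(rnorm(ns, 0.98, 0.015), 1)
  bsce_c2 <- pmin(rnorm(ns, 0.98, 0.015), 1)
  fail_bsce <- integer(0); low_cov <- integer(0)
  if (cfg$n_fail_bsce + cfg$n_low_coverage > 0) {
    bad <- sample.int(ns, cfg$n_fail_bsce + cfg$n_low_coverage)
    fail_bsce <- bad[seq_len(cfg$n_fail_bsce)]
    low_cov <- setdiff(bad, fail_bsce)
    bsce_c1[fail_bsce] <- runif(length(fail_bsce), 0.65, 0.75)
    bsce_c2[fail_bsce] <- runif(length(fail_bsce), 0.65, 0.75)
    bsce_c1[low_cov] <- runif(length(low_cov), 0.85, 0.89)
    bsce_c2[low_cov] <- runif(length(low_cov), 0.85, 0.89)
  }
  if (length(bsce_probes) > 0 && cfg$bsce_artifact_sd > 0) {
    z_bsce <- as.numeric(scale(bsce_c1))
    L[bsce_probes, ] <- L[bsce_probes, ] +
      cfg$bsce_artifact_sd * matrix(z_bsce, length(bsce_probes), ns,
                                    byrow = TRUE)
  }

  beta_vals <- plogis(L)
  dimnames(beta_vals) <- list(pid, sid)

  ## detection mask / missingness
  drop_prob <- matrix(cfg$detection_dropout_rate, np, ns)
  if (length(low_cov) > 0) drop_prob[, low_cov] <- 0.35
  detected <- matrix(runif(np * ns) >= drop_prob, np, ns)
  beta_vals[!detected] <- NA_real_

  samples <- data.frame(
    sample_id = sid,
    group = ifelse(surv$event == 1L, "case", "control"),
    sex = sex, cohort = cohort, chip = chip_lab, batch = batch,
    bsce_c1 = bsce_c1, bsce_c2 = bsce_c2,
    age_at_draw = age_draw, age_at_diagnosis = age_dx,
    duration_t1d = duration, time_to_event = surv$time,
    event = surv$event, stringsAsFactors = FALSE)
  samples <- validate_samples(samples)

  manifest <- simulate_manifest(pid)

  truth <- structure(list(
    causal_probe_ids = pid[causal],
    causal_coefs = setNames(rep(cfg$causal_coef, cfg$n_causal), pid[causal]),
    x_probes = pid[x_probes], age_probes = pid[age_probes],
    age_slopes = setNames(age_slopes, pid[age_probes]),
    batch_probes = pid[batch_probes], cohort_probes = pid[cohort_probes],
    bsce_probes = pid[bsce_probes],
    latent_event_times = surv$latent_time,
    calibrated_hazard_scale = surv$scale,
    planted_fail_bsce = sid[fail_bsce],
    planted_low_coverage = sid[low_cov],
    n_clipped = 0L,
    seed = cfg$seed), class = "sim_truth")

  structure(list(beta = beta_matrix(beta_vals, detected),
                 samples = samples, manifest = manifest, truth = truth,
                 config = cfg),
            class = "meth_sim")
}

#' @export
print.meth_sim <- function(x, ...) {
  cat(sprintf("meth_sim: %d probes x %d samples, %d events, %d causal CpGs (seed %d)\n",
              nrow(x$beta$values), ncol(x$beta$values),
              sum(x$samples$event), length(x$truth$causal_probe_ids),
              x$truth$seed))
  invisible(x)
}

# alternate members of two index sets: a1 b1 a2 b2 ... then leftovers
interleave_groups <- function(a, b) {
  k <- min(length(a), length(b))
  head_part <- as.vector(rbind(a[seq_len(k)], b[seq_len(k)]))
  c(head_part, a[-seq_len(k)], b[-seq_len(k)])
}

simulate_manifest <- function(pid) {
  np <- length(pid)
  chrom <- as.character(sample.int(22L, np, replace = TRUE))
  position <- sample.int(2e8L, np, replace = TRUE)
  # place ~5% of probes within 1 kb of their predecessor to guarantee
  # proximal pairs for the pair analysis
  partner <- which(runif(np) < 0.05 & seq_len(np) > 1L)
  chrom[partner] <- chrom[partner - 1L]
  position[partner] <- position[partner - 1L] +
    sample(50:999, length(partner), replace = TRUE)
  data.frame(probe_id = pid, chromosome = chrom, position = position,
             gene_symbol = sprintf("GENE%05d", seq_len(np)),
             tss_distance = round(runif(np, -1500, 1000)),
             cgi_member = runif(np) < 0.7,
             stringsAsFactors = FALSE)
}

#' Generate proportional-hazards survival times from causal methylation
#'
#' Event times follow an exponential baseline scaled by
#' \eqn{\exp(\sum_k \beta_k z_{ks})} over the standardised causal-probe
#' scores; administrative censoring is uniform over `censor_time_range`,
#' and `event = 1` iff the latent event time precedes the censoring time.
#' The baseline scale is calibrated so the realised event fraction matches
#' `case_fraction`: holding the exponential draws and censoring times
#' fixed, a deterministic bisection over the log scale finds the root of
#' (event fraction - target).
#'
#' @param scores Causal-probes x samples matrix of standardised
#'   methylation scores (or NULL/zero-row for a fully null cohort).
#' @param coefs True log hazard ratios, one per causal probe.
#' @param config A [sim_config()] (uses `baseline_hazard_scale`,
#'   `censor_time_range`, `case_fraction`).
#' @return List with `time`, `event`, `latent_time` and the calibrated
#'   `scale`. Times are floored at 0.01 years so censored-at-zero
#'   durations cannot occur.
#' @export
simulate_survival <- function(scores, coefs, config) {
  ns <- if (is.null(scores)) config$n_samples else ncol(scores)
  eta <- if (is.null(scores) || nrow(scores) == 0) rep(0, ns)
         else as.numeric(crossprod(scores, coefs))
  u <- runif(ns)
  cens <- runif(ns, config$censor_time_range[1], config$censor_time_range[2])
  latent <- function(scale) pmax(-scale * log(u) * exp(-eta), 0.01)
  event_frac <- function(log_scale) mean(latent(exp(log_scale)) <= cens)
  target <- config$case_fraction
  scale <- config$baseline_hazard_scale
  if (target > 0 && target < 1) {
    f_lo <- event_frac(-8); f_hi <- event_frac(12)
    # event fraction decreases in scale: -8 -> ~1, 12 -> ~0
    if (f_lo >= target && f_hi <= target) {
      root <- tryCatch(
        uniroot(function(ls) event_frac(ls) - target, c(-8, 12),
                tol = 1e-4)$root,
        error = function(e) log(config$baseline_hazard_scale))
      scale <- exp(root)
    } else {
      warning("case_fraction ", target,
              " unreachable by hazard-scale calibration; using configured scale")
    }
  }
  lt <- latent(scale)
  list(time = pmin(lt, cens), event = as.integer(lt <= cens),
       latent_time = lt, scale = scale)
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Writes `beta.tsv` (beta matrix), `samples.csv`, `manifest.csv` and
#' `truth.json` into a directory, in the formats the package's readers
#' consume.
#'
#' @param sim A [simulate_dataset()] result.
#' @param directory Target directory; refuses to write into an existing
#'   non-empty directory unless `overwrite = TRUE`.
#' @param overwrite Allow writing into a non-empty directory.
#' @return The directory, invisibly.
#' @export
write_fixture_bundle <- function(sim, directory, overwrite = FALSE) {
  if (dir.exists(directory) &&
      length(list.files(directory)) > 0 && !overwrite)
    stop("directory exists and is not empty: ", directory,
         " (use overwrite = TRUE)")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(sim$beta, file.path(directory, "beta.tsv"))
  samp <- sim$samples
  for (col in c("group", "sex", "cohort", "chip", "batch"))
    samp[[col]] <- as.character(samp[[col]])
  write.csv(samp, file.path(directory, "samples.csv"), row.names = FALSE)
  write.csv(sim$manifest, file.path(directory, "manifest.csv"),
            row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(causal_probe_ids = tr$causal_probe_ids,
         causal_coefs = as.list(tr$causal_coefs),
         x_probes = tr$x_probes, age_probes = tr$age_probes,
         batch_probes = tr$batch_probes, cohort_probes = tr$cohort_probes,
         bsce_probes = tr$bsce_probes,
         planted_fail_bsce = tr$planted_fail_bsce,
         planted_low_coverage = tr$planted_low_coverage,
         n_clipped = tr$n_clipped, seed = tr$seed),
    file.path(directory, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(directory)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param directory Bundle directory.
#' @return List with `beta`, `samples`, `manifest`, `truth`.
#' @export
read_fixture_bundle <- function(directory) {
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = TRUE)
  truth$causal_coefs <- unlist(truth$causal_coefs)
  list(beta = read_beta_matrix(file.path(directory, "beta.tsv")),
       samples = read_sample_sheet(file.path(directory, "samples.csv")),
       manifest = read_probe_manifest(file.path(directory, "manifest.csv")),
       truth = truth)
}
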