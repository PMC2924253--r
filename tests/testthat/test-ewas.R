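test_that("a lone causal CpG is recovered with correct sign and coverage", {
  # single planted probe: the per-CpG model is the true model, so the
  # conditional and marginal log hazard ratios coincide
  hits <- 0; covered <- 0; sign_err <- 0
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(n_samples = 150, n_probes = 400,
                                       n_causal = 1, causal_coef = 0.6,
                                       seed = s))
    scan <- run_ewas(sim$beta, sim$samples, covariates = NULL)
    tab <- scan$table
    i <- match(sim$truth$causal_probe_ids, tab$probe_id)
    hits <- hits + (tab$q[i] < 0.05)
    covered <- covered + (abs(tab$coef[i] - 0.6) <= 1.96 * tab$se[i])
    sign_err <- sign_err + sum(tab$q < 0.05 & tab$coef < 0 &
                                 tab$probe_id %in% sim$truth$causal_probe_ids)
  }
  expect_gte(hits, 4)
  expect_gte(covered, 3)
  expect_equal(sign_err, 0)
})

test_that("the scan output carries the full Cox row schema in probe order", {
  sim <- simulate_dataset(sim_config(n_samples = 60, n_probes = 80,
                                     seed = 3))
  scan <- run_ewas(sim$beta, sim$samples,
                   covariates = c("sex", "age_at_draw"))
  tab <- scan$table
  expect_equal(names(tab), c("probe_id", "coef", "hazard_ratio", "se", "z",
                             "p", "q", "n_used", "converged", "degenerate"))
  expect_equal(tab$probe_id, rownames(sim$beta$values))
  expect_equal(tab$hazard_ratio, exp(tab$coef))
  expect_equal(tab$z[!tab$degenerate],
               (tab$coef / tab$se)[!tab$degenerate], tolerance = 1e-12)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  expect_true(all(tab$q >= 0 & tab$q <= 1))
  expect_equal(sort(coef(scan)), sort(setNames(tab$coef, tab$probe_id)))
  expect_s3_class(summary(scan), "summary.ewas_scan")
})

test_that("null scans give uniform p-values", {
  set.seed(50)
  sim <- simulate_dataset(sim_config(n_samples = 120, n_probes = 500,
                                     n_causal = 0, seed = 77,
                                     batch_effect_sd = 0,
                                     cohort_effect_sd = 0,
                                     sex_effect_sd = 0, age_effect_sd = 0,
                                     bsce_artifact_sd = 0))
  scan <- run_ewas(sim$beta, sim$samples, covariates = NULL)
  expect_gt(ks.test(scan$table$p, "punif")$p.value, 0.01)
})

test_that("raw and z-score predictor scalings agree on z up to sign", {
  sim <- simulate_dataset(sim_config(n_samples = 60, n_probes = 40,
                                     seed = 5))
  sz <- run_ewas(sim$beta, sim$samples, covariates = NULL,
                 predictor_scaling = "zscore")
  sr <- run_ewas(sim$beta, sim$samples, covariates = NULL,
                 predictor_scaling = "raw")
  # the Wald statistic is invariant to linear predictor rescaling
  expect_equal(sz$table$z, sr$table$z, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(sz$table$coef, sr$table$coef)))
})

test_that("proximal pairs respect the distance and chromosome rules", {
  man <- data.frame(
    probe_id = c("a", "b", "c", "d", "e"),
    chromosome = c("9", "9", "9", "1", "1"),
    position = c(102830780L, 102830899L, 102832500L, 500L, 500000L),
    gene_symbol = "G", tss_distance = 0L, cgi_member = TRUE)
  pairs <- survewas:::enumerate_pairs(man, max_dist = 1000)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$probe_id_a, "a")
  expect_equal(pairs$probe_id_b, "b")
  expect_equal(pairs$distance, 119L)

  # same position, different chromosome -> never paired
  man2 <- data.frame(probe_id = c("x", "y"), chromosome = c("1", "2"),
                     position = c(100L, 100L), gene_symbol = "G",
                     tss_distance = 0L, cgi_member = TRUE)
  expect_equal(nrow(survewas:::enumerate_pairs(man2, 1000)), 0)

  # 1 kb is inclusive; 1,500 bp is out
  man3 <- data.frame(probe_id = c("u", "v", "w"), chromosome = "3",
                     position = c(1000L, 2000L, 3500L), gene_symbol = "G",
                     tss_distance = 0L, cgi_member = TRUE)
  p3 <- survewas:::enumerate_pairs(man3, 1000)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$distance, 1000L)
})

test_that("pair combination fits the same Cox model on the mean z-score", {
  sim <- simulate_dataset(sim_config(n_samples = 80, n_probes = 200,
                                     seed = 6, detection_dropout_rate = 0))
  pr <- combine_proximal_pairs(sim$beta, sim$manifest, sim$samples,
                               covariates = NULL)
  expect_s3_class(pr, "ewas_pairs")
  expect_true(nrow(pr) > 0)
  expect_true(all(pr$distance <= 1000))
  expect_true(all(pr$p > 0 & pr$p <= 1))

  # recompute one pair by hand through fit_cox_single
  k <- 1
  za <- as.numeric(scale(sim$beta$values[pr$probe_id_a[k], ]))
  zb <- as.numeric(scale(sim$beta$values[pr$probe_id_b[k], ]))
  manual <- fit_cox_single((za + zb) / 2, sim$samples$time_to_event,
                           sim$samples$event)
  expect_equal(pr$coef[k], manual$coef, tolerance = 1e-8)

  # probes absent from the manifest are excluded with a warning
  expect_warning(
    pr2 <- combine_proximal_pairs(sim$beta, sim$manifest[-1, ],
                                  sim$samples, covariates = NULL),
    "absent from manifest")

  st <- combine_proximal_pairs(sim$beta, sim$manifest, sim$samples,
                               covariates = NULL, combine = "stouffer")
  expect_true(all(is.na(st$coef)))
  expect_true(all(st$p > 0 & st$p <= 1))
})
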