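# Independent oracles and small fixture builders shared across tests.

# Explicit Cox log partial likelihood for untied event times, single
# predictor vector x. Independent of the fitting code under test.
log_partial_lik <- function(beta, x, time, event) {
  eta <- beta * x
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}

# Brute-force maximiser of the partial likelihood on a grid.
grid_search_cox <- function(x, time, event, grid = seq(-4, 4, 5e-4)) {
  ll <- vapply(grid, log_partial_lik, numeric(1),
               x = x, time = time, event = event)
  grid[which.max(ll)]
}

# Standard error from the numerical curvature of the log partial
# likelihood at the optimum (second central difference).
curvature_se <- function(beta_hat, x, time, event, h = 1e-4) {
  d2 <- (log_partial_lik(beta_hat + h, x, time, event) -
           2 * log_partial_lik(beta_hat, x, time, event) +
           log_partial_lik(beta_hat - h, x, time, event)) / h^2
  sqrt(-1 / d2)
}

# 8-sample, no-ties toy survival dataset with one binary predictor.
toy_cox_data <- function() {
  list(x = c(1, 1, 1, 1, 0, 0, 0, 0),
       time = c(1.1, 2.3, 3.2, 4.8, 1.7, 2.9, 4.1, 5.5),
       event = c(1, 1, 0, 1, 1, 0, 1, 1))
}

# Tiny labelled beta matrix from a numeric matrix (adds ids if absent).
make_beta <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  beta_matrix(m)
}

# Minimal valid sample table for n samples with given survival encoding.
make_samples <- function(n, time, event, seed = 99) {
  withr::with_seed(seed, {
    dur <- ifelse(event == 1, time + runif(n, 0, 4), time)
    age_dx <- runif(n, 5, 30)
    data.frame(
      sample_id = sprintf("s%03d", seq_len(n)),
      group = ifelse(event == 1, "case", "control"),
      sex = sample(c("F", "M"), n, TRUE),
      cohort = sample(c("site1", "site2"), n, TRUE),
      chip = paste0("chip", (seq_len(n) - 1) %/% 12 + 1),
      batch = "plate1",
      bsce_c1 = runif(n, 0.95, 1), bsce_c2 = runif(n, 0.95, 1),
      age_at_draw = age_dx + dur, age_at_diagnosis = age_dx,
      duration_t1d = dur, time_to_event = time, event = event,
      stringsAsFactors = FALSE)
  })
}

# No-ties survival draw for property tests.
random_survival <- function(n, rate = 0.1, cens = 25) {
  t_lat <- rexp(n, rate)
  cen <- runif(n, 5, cens + 15)
  list(time = pmin(t_lat, cen), event = as.integer(t_lat <= cen))
}
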