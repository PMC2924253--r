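test_that("variance fractions follow the singular values", {
  set.seed(20)
  u <- qr.Q(qr(matrix(rnorm(36), 6)))
  v <- qr.Q(qr(matrix(rnorm(36), 6)))
  x <- 2 * tcrossprod(u[, 1], v[, 1]) + 1 * tcrossprod(u[, 2], v[, 2])
  dimnames(x) <- list(sprintf("p%d", 1:6), sprintf("s%d", 1:6))
  res <- svd_decompose(x, n_components = 2)
  expect_equal(res$variance_fractions[1:2], c(0.8, 0.2), tolerance = 1e-9)
  expect_equal(sum(res$variance_fractions), 1, tolerance = 1e-9)
  expect_true(all(diff(res$singular_values) <= 1e-12))
  expect_error(svd_decompose(x, n_components = 10), "n_components")
})

test_that("SVD reconstruction recovers the matrix", {
  set.seed(21)
  x <- matrix(runif(30 * 8), 30, 8,
              dimnames = list(sprintf("p%d", 1:30), sprintf("s%d", 1:8)))
  s <- svd(x)
  recon <- s$u %*% diag(s$d) %*% t(s$v)
  expect_lt(norm(x - recon, "F") / norm(x, "F"), 1e-9)
  res <- svd_decompose(x, n_components = 8)
  # scores are d_k * v_k: their norms are the singular values
  expect_equal(unname(sqrt(rowSums(res$sample_scores^2))),
               res$singular_values[1:8], tolerance = 1e-9)
})

test_that("the permutation null is reproducible and tight", {
  set.seed(22)
  x <- matrix(rnorm(400 * 50), 400, 50,
              dimnames = list(sprintf("p%d", 1:400), sprintf("s%d", 1:50)))
  n1 <- permutation_null(x, n_permutations = 10, seed = 31)
  n2 <- permutation_null(x, n_permutations = 10, seed = 31)
  expect_identical(n1$null_fractions, n2$null_fractions)
  expect_false(identical(
    n1$null_fractions,
    permutation_null(x, n_permutations = 10, seed = 32)$null_fractions))

  # each replicate's fractions sum to 1; per-rank spread << mean
  expect_equal(unname(rowSums(n1$null_fractions)), rep(1, 10),
               tolerance = 1e-9)
  spread <- apply(n1$null_fractions, 2, sd)
  centre <- colMeans(n1$null_fractions)
  expect_true(all(spread[1:20] < 0.05 * centre[1:20]))
})

test_that("false component calls on pure noise stay at the max-rule rate", {
  # with B null replicates, P(observed fraction > max of B) = 1/(B+1) per
  # rank under exchangeability; calls across ranks are positively
  # correlated, so seeds with any call are rarer still
  n_seeds <- 20; n_ranks <- 10
  calls <- 0; empty <- 0
  for (s in seq_len(n_seeds)) {
    x <- survewas:::local_seed(400 + s,
      matrix(rnorm(500 * 40), 500, 40,
             dimnames = list(sprintf("p%d", 1:500), sprintf("s%d", 1:40))))
    adj <- adjust_top_component(x)
    res <- select_significant_components(
      svd_decompose(adj, n_components = n_ranks),
      permutation_null(adj, n_permutations = 10, seed = s))
    calls <- calls + length(res$significant_components)
    empty <- empty + (length(res$significant_components) == 0)
  }
  expect_lte(calls, 2 * n_seeds * n_ranks / 11)
  expect_gte(empty, 0.6 * n_seeds)
})

test_that("a planted batch factor yields a significant, batch-linked component", {
  set.seed(24)
  n <- 100; p <- 1000
  batch <- rep(c("b1", "b2"), each = n / 2)
  # mean methylation profile dominates (as in beta data); batch rides on it
  x <- outer(rnorm(p, 0, 4), rep(1, n)) +
    matrix(rnorm(p * n), p, n,
           dimnames = list(sprintf("p%d", 1:p), sprintf("s%d", 1:n)))
  affected <- 1:(p / 5)
  x[affected, batch == "b2"] <- x[affected, batch == "b2"] + 0.8
  adj <- adjust_top_component(x)
  res <- svd_decompose(adj, n_components = 10)
  null <- permutation_null(adj, n_permutations = 10, seed = 51)
  res <- select_significant_components(res, null)
  expect_true(1 %in% res$significant_components)

  kw <- kruskal.test(res$sample_scores[1, ], factor(batch))$p.value
  expect_lt(kw, 1e-5)
})

test_that("enlarging a planted effect never drops its component", {
  set.seed(25)
  n <- 60; p <- 400
  batch <- rep(c("b1", "b2"), each = n / 2)
  base <- outer(rnorm(p, 0, 4), rep(1, n)) +
    matrix(rnorm(p * n), p, n,
           dimnames = list(sprintf("p%d", 1:p), sprintf("s%d", 1:n)))
  found <- logical(0)
  for (eff in c(0.5, 1, 2, 4)) {
    x <- base
    x[1:80, batch == "b2"] <- x[1:80, batch == "b2"] + eff
    adj <- adjust_top_component(x)
    res <- select_significant_components(
      svd_decompose(adj, n_components = 5),
      permutation_null(adj, n_permutations = 10, seed = 61))
    found <- c(found, 1 %in% res$significant_components)
  }
  expect_true(all(found[-1] >= found[-length(found)]))
  expect_true(found[length(found)])
})

test_that("component-factor associations use the declared test per type", {
  set.seed(26)
  n <- 60
  scores <- matrix(rnorm(2 * n), 2, n,
                   dimnames = list(c("PC1", "PC2"), sprintf("s%03d", 1:n)))
  samples <- make_samples(n, time = runif(n, 2, 30),
                          event = rep(c(1L, 0L), n / 2))
  # continuous factor equal to the scores (plus tiny noise) -> p < 1e-10
  samples$age_at_draw <- scores[1, ] + rnorm(n, 0, 1e-4)
  samples$age_at_diagnosis <- pmin(samples$age_at_diagnosis,
                                   samples$age_at_draw)
  res <- svd_decompose(
    matrix(rnorm(300 * n), 300, n,
           dimnames = list(sprintf("p%d", 1:300), colnames(scores))), 2)
  res$sample_scores <- scores
  assoc <- associate_components(
    res, samples,
    factor_spec = c(age_at_draw = "continuous", sex = "categorical",
                    cc = "survival"))
  expect_lt(assoc$p_values["PC1", "age_at_draw"], 1e-10)
  expect_equal(assoc$bins["PC1", "age_at_draw"], "p<1e-10")
  expect_true(all(assoc$p_values > 0 & assoc$p_values <= 1))

  # single-level categorical: NA cell with a warning, not a crash
  samples$sex <- "F"
  expect_warning(
    a2 <- associate_components(res, samples,
                               factor_spec = c(sex = "categorical")),
    "single level")
  expect_true(all(is.na(a2$p_values[, "sex"])))
})

test_that("complete separation reproduces the closed-form rank statistic", {
  # two groups of 3 with fully separated scores: H = 12/(n(n+1)) * sum
  # n_i (Rbar_i - (n+1)/2)^2 = 3.857..., p = P(chi2_1 > H)
  scores <- matrix(c(1, 2, 3, 10, 11, 12), 1, 6,
                   dimnames = list("PC1", sprintf("s%03d", 1:6)))
  samples <- make_samples(6, time = rep(c(5, 9), 3),
                          event = rep(c(1L, 0L), 3))
  samples$cohort <- rep(c("g1", "g2"), each = 3)
  res <- list(sample_scores = scores, n_components_evaluated = 1L)
  class(res) <- "svd_screen"
  assoc <- associate_components(res, samples,
                                factor_spec = c(cohort = "categorical"))
  H <- 12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2)
  expect_equal(assoc$p_values["PC1", "cohort"],
               pchisq(H, df = 1, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("a shuffled factor shows no association on average", {
  set.seed(27)
  n <- 80
  ps <- replicate(40, {
    scores <- matrix(rnorm(n), 1, n,
                     dimnames = list("PC1", sprintf("s%03d", 1:n)))
    samples <- make_samples(n, time = runif(n, 2, 30),
                            event = rbinom(n, 1, 0.5))
    samples$age_at_draw <- sample(samples$age_at_draw)
    res <- structure(list(sample_scores = scores,
                          n_components_evaluated = 1L),
                     class = "svd_screen")
    associate_components(res, samples,
      factor_spec = c(age_at_draw = "continuous"))$p_values[1, 1]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})
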