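test_that("beta computation matches the signal-ratio definition", {
  expect_equal(compute_beta(500, 500), 0.5)
  expect_equal(compute_beta(0, 800), 0)
  expect_equal(compute_beta(300, 100, offset = 100), 0.6)
  expect_error(compute_beta(0, 0, 0), "degenerate")
  expect_error(compute_beta(-1, 5), "nonnegative")
})

test_that("beta is monotone in each channel and stays in [0,1]", {
  g <- seq(0, 2000, by = 125)
  for (u in c(0, 250, 1000)) {
    b <- compute_beta(g, u, offset = 10)
    expect_true(all(diff(b) > 0))
    expect_true(all(b >= 0 & b <= 1))
  }
  for (m in c(0, 250, 1000)) {
    b <- compute_beta(m, g, offset = 10)
    expect_true(all(diff(b) <= 0))
  }
})

test_that("beta_matrix enforces range, uniqueness and mask invariants", {
  m <- matrix(c(0.1, 0.5, NA, 0.9, 0.2, 0.3), 3, 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  bm <- beta_matrix(m)
  expect_false(bm$detected["c", "s1"])
  expect_true(all(bm$detected[!is.na(m)]))

  m_bad <- m; m_bad[1, 1] <- 1.2
  expect_error(beta_matrix(m_bad), "probe 'a', sample 's1'")
  m_dup <- m; rownames(m_dup) <- c("a", "a", "c")
  expect_error(beta_matrix(m_dup), "duplicate probe id")
})

test_that("beta matrix TSV round trip preserves ids, values and mask", {
  set.seed(42)
  m <- matrix(round(runif(6), 6), 3, 2,
              dimnames = list(c("cg1", "cg2", "cg3"), c("A", "B")))
  m[2, 1] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  write_beta_matrix(beta_matrix(m), path)
  back <- read_beta_matrix(path)
  expect_equal(back$values, m)
  expect_false(back$detected[2, 1])

  writeLines(c("probe_id\tA", "cg1\t1.2"), path)
  expect_error(read_beta_matrix(path), "out of \\[0,1\\]")
})

test_that("sample sheet reader validates the survival encoding", {
  s <- make_samples(4, time = c(8, 10, 12, 20), event = c(1, 1, 0, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(s, path, row.names = FALSE)
  df <- read_sample_sheet(path)
  expect_equal(nrow(df), 4)
  expect_s3_class(df$chip, "factor")

  s_bad <- s; s_bad$event[1] <- 0
  write.csv(s_bad, path, row.names = FALSE)
  expect_error(read_sample_sheet(path), "case with event = 0")

  s_bad <- s; s_bad$time_to_event[3] <- s_bad$duration_t1d[3] + 2
  write.csv(s_bad, path, row.names = FALSE)
  expect_error(read_sample_sheet(path), "censored at its T1D duration")

  s_extra <- s; s_extra$clinic_notes <- "x"
  write.csv(s_extra, path, row.names = FALSE)
  expect_warning(df2 <- read_sample_sheet(path), "extra sample-sheet column")
  expect_false("clinic_notes" %in% names(df2))

  write.csv(s[, -match("sex", names(s))], path, row.names = FALSE)
  expect_error(read_sample_sheet(path), "missing required column")
})

test_that("EWAS table writer prints consistent columns and round trips", {
  tab <- data.frame(probe_id = c("cgA", "cgB"),
                    coef = c(0.606, -0.485), se = c(0.145, 0.117),
                    z = c(0.606 / 0.145, -0.485 / 0.117),
                    p = c(3.056e-05, 3.441e-05), q = c(0.048, 0.048))
  man <- data.frame(probe_id = c("cgA", "cgB"), chromosome = c("9", "9"),
                    position = c(35151971L, 37455023L),
                    gene_symbol = c("G1", "G2"),
                    tss_distance = c(-18L, 100L),
                    cgi_member = c(TRUE, TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ewas_table(tab, path, manifest = man)
  back <- read_ewas_table(path)

  expect_equal(names(back), c("probe_id", "gene", "location", "coef",
                              "exp_coef", "se_coef", "z", "p", "q"))
  expect_equal(back$location[1], "9:35151971")
  # exp(coef) column is the exponential of the printed coef, e.g. 1.833
  expect_equal(back$exp_coef, round(exp(back$coef), 3))
  expect_equal(back$exp_coef[1], 1.833)
  expect_equal(back$coef, tab$coef, tolerance = 5e-4)
  expect_equal(back$p, tab$p, tolerance = 1e-3)

  # empty table -> header-only file
  write_ewas_table(tab[0, ], path)
  expect_equal(nrow(read_ewas_table(path)), 0)
})
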