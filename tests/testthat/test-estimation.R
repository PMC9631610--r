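# Rate estimation from SNP GC-content observations, the synthetic-data
# generator, and the sequence-composition utilities.

test_that("the SNP model curve matches its closed form and limits", {
  expect_identical(predict_snp_gc(-2, 1, 0), 0)
  # frozen from independent evaluation of (1 - e^{-1.5}) / 3
  expect_equal(predict_snp_gc(-2, 1, 0.5), 0.25895661328385666,
               tolerance = 1e-12)
  # a -> b limit: f(x) = b x
  expect_equal(predict_snp_gc(1 - 1e-12, 1, 0.4), 0.4, tolerance = 1e-9)
  # monotone increasing in x for b > 0, a < b
  xx <- seq(0.001, 0.999, length.out = 500)
  expect_true(all(diff(predict_snp_gc(-2, 1, xx)) > 0))
  expect_true(all(diff(predict_snp_gc(-0.3, 0.8, xx)) > 0))
  expect_error(predict_snp_gc(-2, 1, 1.5), "\\[0, 1\\]")
})

test_that("noise-free data are recovered to high precision", {
  for (truth in list(c(-2, 1), c(-0.5, 0.3), c(-3, 0.5))) {
    obs <- generate_snp_data(truth[1], truth[2], n = 50, noise_sd = 0,
                             seed = 23)
    fit <- fit_rates(obs, init = c(-1, 0.5))
    expect_lt(abs(fit$a_hat - truth[1]), 1e-6)
    expect_lt(abs(fit$b_hat - truth[2]), 1e-6)
    expect_lt(fit$rss, 1e-12)
    expect_true(fit$converged)
  }
})

test_that("noisy data recover the rates within 10 percent", {
  obs <- generate_snp_data(-2, 1, n = 200, noise_sd = 0.01, seed = 24)
  fit <- fit_rates(obs)
  expect_lt(abs(fit$a_hat - (-2)) / 2, 0.1)
  expect_lt(abs(fit$b_hat - 1) / 1, 0.1)
  # the regime constraint holds
  expect_lt(fit$a_hat, fit$b_hat)
  # standard errors are finite and meaningful
  expect_true(all(is.finite(fit$stderr)))
  expect_lt(abs(fit$a_hat + 2), 4 * fit$stderr["a"] + 0.05)
})

test_that("estimates are unbiased across replicate synthetic datasets", {
  reps <- purrr::map(1:200, function(i) {
    obs <- generate_snp_data(-2, 1, n = 200, noise_sd = 0.01,
                             seed = 1000 + i)
    fit <- fit_rates(obs)
    c(a = fit$a_hat, b = fit$b_hat)
  })
  a_hats <- purrr::map_dbl(reps, "a")
  b_hats <- purrr::map_dbl(reps, "b")
  expect_lt(abs(mean(a_hats) + 2), 2 * stats::sd(a_hats) / sqrt(200))
  expect_lt(abs(mean(b_hats) - 1), 2 * stats::sd(b_hats) / sqrt(200))
})

test_that("data from the a = b regime fit without numerical failure", {
  xx <- seq(0.1, 0.9, length.out = 60)
  obs <- tibble::tibble(core_gc = xx, snp_gc = 1 * xx)  # f = b x, b = 1
  fit <- fit_rates(obs)
  expect_true(fit$converged)
  expect_lt(fit$b_hat - fit$a_hat, 1e-3)   # a_hat -> b_hat from below
  expect_lt(fit$a_hat, fit$b_hat)          # never crosses the boundary
  expect_equal(fit$b_hat, 1, tolerance = 1e-3)
})

test_that("the refit recovers the injected noise level", {
  obs <- generate_snp_data(-2, 1, n = 1e4, noise_sd = 0.05,
                           x_range = c(0.3, 0.95), seed = 25)
  fit <- fit_rates(obs)
  expect_lt(abs(stats::sd(fit$residuals) / 0.05 - 1), 0.05)
})

test_that("the generator is seeded, truncated and on-curve at zero noise", {
  o1 <- generate_snp_data(-2, 1, n = 200, noise_sd = 0.01, seed = 7)
  o2 <- generate_snp_data(-2, 1, n = 200, noise_sd = 0.01, seed = 7)
  expect_identical(o1, o2)
  o0 <- generate_snp_data(-2, 1, n = 100, noise_sd = 0, seed = 8)
  expect_equal(o0$snp_gc, predict_snp_gc(-2, 1, o0$core_gc),
               tolerance = 1e-12)
  o3 <- generate_snp_data(-2, 1, n = 500, noise_sd = 0.5, seed = 9)
  expect_true(all(o3$snp_gc >= 0 & o3$snp_gc <= 1))
  expect_error(generate_snp_data(-2, 1, 10, 0.01, x_range = c(0.9, 0.1)),
               "increasing")
})

test_that("degenerate observations are rejected with clear errors", {
  expect_error(fit_rates(tibble::tibble(core_gc = c(0.5, 0.5, 0.5),
                                        snp_gc = c(0.1, 0.2, 0.3))),
               "degenerate")
  expect_error(fit_rates(tibble::tibble(core_gc = c(0.2, 0.4),
                                        snp_gc = c(0.1, 0.2))),
               "at least 3")
  expect_error(fit_rates(tibble::tibble(core_gc = c(0.2, 1.4, 0.5),
                                        snp_gc = c(0.1, 0.2, 0.3))),
               "inside \\(0, 1\\)")
})

test_that("weighted fits honour the weight column", {
  obs <- generate_snp_data(-2, 1, n = 100, noise_sd = 0, seed = 26)
  # corrupt half the points but give them zero weight
  obs$weight <- rep(c(1, 0), 50)
  obs$snp_gc[obs$weight == 0] <- 0.9
  fit <- fit_rates(obs)
  expect_lt(abs(fit$a_hat + 2), 1e-6)
  expect_lt(abs(fit$b_hat - 1), 1e-6)
})

test_that("tidy, glance and the observation round-trip work", {
  obs <- generate_snp_data(-2, 1, n = 50, noise_sd = 0.01, seed = 27)
  fit <- fit_rates(obs)
  td <- tidy(fit)
  expect_identical(td$term, c("a", "b"))
  expect_identical(td$estimate, c(fit$a_hat, fit$b_hat))
  gl <- glance(fit)
  expect_identical(gl$n_obs, 50L)
  expect_true(gl$converged)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_snp_obs(obs, path)
  back <- read_snp_obs(path)
  expect_equal(back$core_gc, obs$core_gc, tolerance = 1e-15)
  expect_equal(back$snp_gc, obs$snp_gc, tolerance = 1e-15)
})

test_that("GC content and Chargaff parity are computed per sequence", {
  tab <- gc_content(c(a = "GCGC", b = "ATAT", c = "ATGC"))
  expect_equal(tab$gc, c(1, 0, 0.5))
  expect_equal(tab$at_parity_dev[3], 0)
  expect_equal(tab$gc_parity_dev[3], 0)
  # U counts as T; ambiguity codes drop out of the denominator
  rna <- gc_content("AUGCN")
  expect_identical(rna$length_used, 4L)
  expect_equal(rna$gc, 0.5)
  # case-insensitive
  expect_equal(gc_content("gcat")$gc, 0.5)
  # parity deviations in percentage points
  skew <- gc_content("AAAT")  # 3 A, 1 T
  expect_equal(skew$at_parity_dev, 50)
  expect_error(gc_content("NNN"), "unambiguous")
  expect_error(gc_content(character(0)), "non-empty")
})

test_that("FASTA files are read record-by-record", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rec1 a genome", "GCGC", "ATAT",
               ">rec2", "GGGG"), fa)
  tab <- gc_content_fasta(fa)
  expect_identical(tab$seq_id, c("rec1", "rec2"))
  expect_equal(tab$gc, c(0.5, 1))
  expect_identical(tab$length_used, c(8L, 4L))
  expect_error(gc_content_fasta(tempfile()), "not found")
})
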