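test_that("occurrence frequency counts detections and logs mean abundance", {
  m <- matrix(0L, 2, 10)
  m[1, 1:3] <- 50L
  m[2, ] <- 10L
  tbl <- make_table(m)
  prof <- occurrence_frequency(tbl, colnames(tbl))
  expect_equal(prof$f_obs[prof$asv_id == "ASV_1"], 0.3)
  expect_equal(prof$f_obs[prof$asv_id == "ASV_2"], 1)
  expect_identical(attr(prof, "n_samples"), 10L)
  # two-sample hand example: relative abundances 0.01 and 0.001
  m2 <- rbind(c(10L, 1L), c(990L, 999L))
  tbl2 <- make_table(m2)
  prof2 <- occurrence_frequency(tbl2, colnames(tbl2))
  expect_equal(prof2$mean_log_abund[prof2$asv_id == "ASV_1"],
               -2.259637310505756, tolerance = 1e-12)
  # absent-from-group ASVs are excluded
  m3 <- rbind(c(5L, 5L), c(0L, 0L))
  prof3 <- occurrence_frequency(make_table(m3), c("S1", "S2"))
  expect_identical(prof3$asv_id, "ASV_1")
  expect_error(occurrence_frequency(tbl, character(0)), "empty")
})

test_that("migration rate implements the occupancy-variance ratio literally", {
  f <- c(0.2, 0.5, 0.8)
  expect_equal(migration_rate(f, f), 1)
  expect_equal(migration_rate(c(0, 1, 1), c(0.5, 0.5, 0.5)), 0)
  expect_equal(migration_rate(c(0.3, 0.6), c(0.4, 0.5)),
               0.9183673469387754, tolerance = 1e-12)
  expect_error(migration_rate(c(0.5), c(1)), "degenerate")
  expect_error(migration_rate(c(0.5, 0.2), c(0.5)), "length")
  expect_error(migration_rate(c(1.2, 0.5), c(0.5, 0.5)), "0, 1")
})

test_that("migration rate matches a brute-force loop and is permutation-invariant", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(5:50, 1)
    f_obs <- stats::runif(n)
    f_pred <- stats::runif(n, 0.05, 0.95)
    expect_equal(migration_rate(f_obs, f_pred),
                 migration_loop(f_obs, f_pred), tolerance = 1e-12)
    perm <- sample(n)
    expect_equal(migration_rate(f_obs[perm], f_pred[perm]),
                 migration_rate(f_obs, f_pred), tolerance = 1e-12)
  }
})

test_that("the occupancy smoother recovers a noise-free logistic curve", {
  # occupancy generated exactly from a monotone logistic of abundance,
  # with a huge per-ASV sample count so binomial noise vanishes
  n_samples <- 10000L
  x <- seq(-5, -1, length.out = 60)
  f_true <- stats::plogis(3 * (x + 3))
  prof <- data.frame(asv_id = paste0("a", seq_along(x)),
                     f_obs = round(f_true * n_samples) / n_samples,
                     mean_log_abund = x)
  attr(prof, "n_samples") <- n_samples
  fit <- fit_gam_occupancy(prof)
  expect_gte(fit$pseudo_r2, 0.99)
  expect_true(all(fit$profile$f_pred >= 0 & fit$profile$f_pred <= 1))
  expect_true(all(fit$band$lower <= fit$band$upper))
})

test_that("flat occupancy yields near-zero pseudo-R2", {
  prof <- data.frame(asv_id = paste0("a", 1:40),
                     f_obs = rep(0.5, 40),
                     mean_log_abund = seq(-4, -1, length.out = 40))
  attr(prof, "n_samples") <- 10L
  fit <- fit_gam_occupancy(prof)
  expect_lte(abs(fit$pseudo_r2), 0.02)
  expect_equal(fit$m, 1, tolerance = 1e-6)
})

test_that("fitted occupancies stay within [0, 1] on rough random inputs", {
  set.seed(8)
  for (i in 1:5) {
    n <- 30
    prof <- data.frame(asv_id = paste0("a", 1:n),
                       f_obs = sample(0:10, n, replace = TRUE) / 10,
                       mean_log_abund = stats::rnorm(n, -3, 1))
    attr(prof, "n_samples") <- 10L
    fit <- fit_gam_occupancy(prof)
    expect_true(all(fit$profile$f_pred >= 0 & fit$profile$f_pred <= 1))
    expect_lte(fit$pseudo_r2, 1)
  }
})

test_that("small or degenerate profiles are handled per contract", {
  prof <- data.frame(asv_id = letters[1:5], f_obs = runif(5),
                     mean_log_abund = rnorm(5))
  attr(prof, "n_samples") <- 10L
  expect_error(fit_gam_occupancy(prof), "insufficient")
  # few unique abundances -> basis reduced with warning
  prof2 <- data.frame(asv_id = paste0("a", 1:20),
                      f_obs = rep(c(0.2, 0.4, 0.6, 0.8), 5),
                      mean_log_abund = rep(c(-4, -3, -2, -1.5, -1), each = 4))
  attr(prof2, "n_samples") <- 10L
  expect_warning(fit <- fit_gam_occupancy(prof2), "basis dimension")
  expect_true(is.finite(fit$pseudo_r2))
})

test_that("per-group fitting returns four keyed fits and isolates failures", {
  study <- generate_study(synthetic_config(seed = 13, depth = 3000L))
  pre <- preprocess_asv_table(study$counts, study$taxonomy,
                              depth = 3000L, seed = 13)
  md <- study$metadata[study$metadata$sample_id %in% colnames(pre$counts), ]
  fits <- fit_all_groups(pre$counts, md)
  expect_setequal(names(fits),
                  c("conifer.juvenile", "conifer.adult",
                    "broadleaf.juvenile", "broadleaf.adult"))
  expect_true(all(vapply(fits, inherits, TRUE, "neutral_fit")))
  # identical smoother spec => deterministic refit
  refit <- fit_all_groups(pre$counts, md)
  expect_equal(vapply(fits, `[[`, 0, "pseudo_r2"),
               vapply(refit, `[[`, 0, "pseudo_r2"), tolerance = 1e-12)
  tab <- neutral_fit_table(fits)
  expect_true(all(c("group", "asv_id", "f_obs", "f_pred") %in% names(tab)))
})
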