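planted_table <- function(n_asvs = 60, n_per_group = 10, fold = 8,
                          planted = 1, seed = 1) {
  set.seed(seed)
  base <- matrix(stats::rpois(n_asvs * 2 * n_per_group, 30),
                 n_asvs, 2 * n_per_group)
  base[planted, seq_len(n_per_group)] <-
    stats::rpois(length(planted) * n_per_group, 30 * fold)
  make_table(base)
}

test_that("a perfectly separating ASV ranks first in importance", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    noise <- stats::rgamma(39, 2)
    noise <- noise / sum(noise)
    pa <- c(0.05, noise * 0.95)   # signal taxon present in group a
    pb <- c(0.001, noise * 0.999) # nearly absent in group b
    cnt <- cbind(stats::rmultinom(10, 3000, pa),
                 stats::rmultinom(10, 3000, pb))
    tbl <- make_table(cnt)
    rf <- rf_classify(relative_abundance(tbl),
                      rep(c("a", "b"), each = 10),
                      n_trees = 300, seed = s)
    if (rf$importance$asv_id[1] == "ASV_1") hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("shuffled labels give chance-level out-of-bag accuracy", {
  tbl <- random_table(50, 30, seed = 77, lambda = 20)
  rel <- relative_abundance(tbl)
  set.seed(1)
  labels <- sample(rep(c("a", "b"), each = 15))
  rf <- rf_classify(rel, labels, n_trees = 500, seed = 2)
  # binomial 95% bounds around 0.5 for n = 30
  expect_gte(rf$oob_accuracy, 0.5 - 1.96 * sqrt(0.25 / 30) - 0.1)
  expect_lte(rf$oob_accuracy, 0.5 + 1.96 * sqrt(0.25 / 30) + 0.1)
})

test_that("random-forest ranking is reproducible under a fixed seed", {
  tbl <- planted_table(seed = 5)
  rel <- relative_abundance(tbl)
  labels <- rep(c("a", "b"), each = 10)
  r1 <- rf_classify(rel, labels, n_trees = 200, seed = 9)
  r2 <- rf_classify(rel, labels, n_trees = 200, seed = 9)
  expect_identical(r1$importance, r2$importance)
  expect_error(rf_classify(rel, rep("a", 20)), "2 classes")
})

test_that("log response ratios reproduce group-mean arithmetic", {
  # two ASVs with exactly equal vs unequal group means
  m <- rbind(c(10, 10, 10, 20, 20, 20),
             c(40, 40, 40, 10, 10, 10))
  m <- rbind(m, 100 - colSums(m))
  tbl <- make_table(m)
  labels <- rep(c("a", "b"), each = 3)
  res <- lnrr_effects(tbl, labels, c("ASV_1", "ASV_2"), n_boot = 200,
                      seed = 1)
  expect_equal(res$lnrr[res$asv_id == "ASV_1"], log(0.1 / 0.2))
  expect_equal(res$lnrr[res$asv_id == "ASV_2"], log(4))
  expect_true(all(res$ci_lower <= res$lnrr & res$lnrr <= res$ci_upper))
  # Table-style means: 3.069% vs 0.1417% -> lnRR ~ 3.075
  expect_equal(log(3.069 / 0.1417), 3.075394907923101, tolerance = 1e-12)
})

test_that("zero group means are flagged as one-sided effects", {
  m <- rbind(c(0, 0, 0, 30, 25, 35),
             c(100, 100, 100, 70, 75, 65))
  tbl <- make_table(m)
  labels <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  res <- lnrr_effects(tbl, labels, "ASV_1", n_boot = 100, seed = 1)
  expect_true(res$one_sided)
  expect_identical(res$lnrr, -Inf)
  expect_equal(res$mean_a, 0)
  # both means zero -> skipped with warning
  m2 <- rbind(c(0, 0, 0, 0, 0, 0), m)
  tbl2 <- make_table(m2)
  expect_warning(res2 <- lnrr_effects(tbl2, labels, "ASV_1",
                                      n_boot = 50, seed = 1), "zero mean")
  expect_identical(nrow(res2), 0L)
})

test_that("lnRR is antisymmetric under label swap", {
  tbl <- planted_table(seed = 31)
  labels <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
  flipped <- factor(labels, levels = c("b", "a"))
  r1 <- lnrr_effects(tbl, labels, paste0("ASV_", 1:5), n_boot = 400,
                     seed = 3)
  r2 <- lnrr_effects(tbl, flipped, paste0("ASV_", 1:5), n_boot = 400,
                     seed = 3)
  expect_equal(r1$lnrr, -r2$lnrr, tolerance = 1e-12)
  expect_equal(r1$mean_a, r2$mean_b, tolerance = 1e-12)
  # CI endpoints swap and negate within bootstrap noise
  expect_equal(r1$ci_lower, -r2$ci_upper, tolerance = 0.15)
})

test_that("group means and SEs match brute-force computation", {
  tbl <- planted_table(seed = 41)
  rel <- relative_abundance(tbl)
  labels <- rep(c("a", "b"), each = 10)
  res <- lnrr_effects(tbl, labels, rownames(tbl)[1:8], n_boot = 50,
                      seed = 1)
  for (k in 1:8) {
    xa <- rel[res$asv_id[k], labels == "a"]
    xb <- rel[res$asv_id[k], labels == "b"]
    expect_equal(res$mean_a[k], 100 * mean(xa), tolerance = 1e-12)
    expect_equal(res$se_a[k], 100 * sd(xa) / sqrt(10), tolerance = 1e-12)
    expect_equal(res$mean_b[k], 100 * mean(xb), tolerance = 1e-12)
  }
})

test_that("per-ASV tests flag planted shifts and skip zero rows", {
  tbl <- planted_table(fold = 10, seed = 51)
  labels <- rep(c("a", "b"), each = 10)
  res <- per_asv_tests(tbl, labels)
  expect_lt(res$p_value[res$asv_id == "ASV_1"], 0.01)
  expect_true(all(res$p_adjust >= res$p_value - 1e-12))
  # identical groups: p near 1
  m <- rbind(rep(c(10, 20), 5), rep(c(30, 40), 5))
  m <- cbind(m, m)
  tbl2 <- make_table(m)
  res2 <- suppressWarnings(per_asv_tests(tbl2, rep(c("a", "b"), each = 10)))
  expect_true(all(res2$p_value > 0.9))
})

test_that("indicator analysis assembles ranking, effects, tests and labels", {
  study <- generate_study(synthetic_config(seed = 61, n_replicates = 5L,
                                           depth = 2000L))
  pre <- preprocess_asv_table(study$counts, study$taxonomy,
                              depth = 2000L, seed = 61)
  md <- study$metadata[study$metadata$sample_id %in% colnames(pre$counts), ]
  res <- indicator_analysis(pre$counts, md, contrast = "stage",
                            taxonomy = study$taxonomy, top_n = 15,
                            n_trees = 300, n_boot = 100, seed = 1)
  expect_identical(res$numerator_group, "juvenile")
  expect_lte(nrow(res$indicators), 15L)
  expect_true(all(c("lnrr", "ci_lower", "mean_a", "p_value", "p_adjust",
                    "genus", "rank") %in% names(res$indicators)))
  expect_identical(res$indicators$rank, sort(res$indicators$rank))
})
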