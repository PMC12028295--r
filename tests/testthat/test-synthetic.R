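test_that("metacommunity proportions are normalized and long-tailed", {
  p <- simulate_metacommunity(2, seed = 1)
  expect_length(p, 2)
  expect_equal(sum(p), 1)
  # degenerate lognormal collapses to uniform
  p0 <- simulate_metacommunity(50, sdlog = 1e-8, seed = 2)
  expect_true(max(p0) / min(p0) < 1.001)
  # rank-abundance curves are monotone non-increasing after sorting
  for (s in 1:100) {
    p <- simulate_metacommunity(30, seed = s)
    expect_true(all(diff(sort(p, decreasing = TRUE)) <= 0))
  }
  ls <- simulate_metacommunity(100, "logseries", seed = 3)
  expect_equal(sum(ls), 1)
  expect_error(simulate_metacommunity(1), "n_asvs")
  expect_error(simulate_metacommunity(10, "logseries", ls_theta = 1.2),
               "ls_theta")
})

test_that("neutral groups track the metacommunity at full coupling", {
  p <- simulate_metacommunity(30, sdlog = 1, seed = 7)
  tbl <- simulate_neutral_group(p, n_samples = 50, depth = 5000,
                                m_sim = 1, seed = 7)
  expect_true(all(colSums(tbl) == 5000))
  rel <- sweep(tbl, 2, colSums(tbl), "/")
  se <- apply(rel, 1, stats::sd) / sqrt(ncol(rel))
  expect_true(mean(abs(rowMeans(rel) - p) <= 3 * se + 1e-4) > 0.9)
})

test_that("higher migration tightens coupling to the metacommunity", {
  p <- simulate_metacommunity(40, sdlog = 1, seed = 5)
  var_at <- function(m_sim) {
    v <- vapply(1:20, function(s) {
      tbl <- simulate_neutral_group(p, 15, 2000, m_sim, seed = s)
      rel <- sweep(tbl, 2, colSums(tbl), "/")
      mean(apply(rel, 1, stats::var))
    }, numeric(1))
    mean(v)
  }
  v <- vapply(c(0.1, 0.5, 0.9), var_at, numeric(1))
  expect_true(v[1] > v[2] && v[2] > v[3])
})

test_that("niche sampling honors affinities and degenerates to neutral", {
  p <- simulate_metacommunity(20, sdlog = 1, seed = 9)
  aff <- matrix(1, 20, 2, dimnames = list(names(p), c("ha", "hb")))
  aff[1:5, "ha"] <- 0
  tbl <- simulate_niche_group(p, aff, hosts = rep("ha", 8),
                              filter_strength = 2, depth = 1000, seed = 2)
  expect_true(all(tbl[1:5, ] == 0))
  expect_true(all(colSums(tbl) == 1000))
  # filter_strength 0 with no individual effects = multinomial from p:
  # compare mean abundance against binomial SE
  t0 <- simulate_niche_group(p, aff, hosts = rep("ha", 40),
                             filter_strength = 0, depth = 2000, seed = 3)
  rel <- sweep(t0, 2, colSums(t0), "/")
  se <- sqrt(p * (1 - p) / 2000 / 40)
  expect_true(mean(abs(rowMeans(rel) - p) <= 4 * se) > 0.9)
})

test_that("stronger host filtering increases between-host dissimilarity", {
  p <- simulate_metacommunity(60, sdlog = 1, seed = 11)
  set.seed(11)
  aff <- matrix(stats::rlnorm(120), 60, 2,
                dimnames = list(names(p), c("ha", "hb")))
  mean_bc <- function(fs) {
    v <- vapply(1:15, function(s) {
      tbl <- simulate_niche_group(p, aff, hosts = rep(c("ha", "hb"), 5),
                                  filter_strength = fs, depth = 2000,
                                  seed = s)
      rel <- sweep(tbl, 2, colSums(tbl), "/")
      d <- as.matrix(bray_curtis(rel))
      ha <- seq(1, 10, 2); hb <- seq(2, 10, 2)
      mean(d[ha, hb])
    }, numeric(1))
    mean(v)
  }
  bc <- vapply(c(0, 1, 2), mean_bc, numeric(1))
  expect_true(bc[1] < bc[2] && bc[2] < bc[3])
})

test_that("generate_study reproduces the study design and its ground truth", {
  study <- generate_study(synthetic_config(seed = 1, depth = 1500L))
  expect_identical(ncol(study$counts), 120L)
  expect_identical(nrow(study$metadata), 120L)
  expect_setequal(study$metadata$sample_id, colnames(study$counts))
  expect_identical(sort(unique(study$metadata$host_type)),
                   c("broadleaf", "conifer"))
  # every sample resolves to host_type and stage
  md <- study$metadata[match(colnames(study$counts),
                             study$metadata$sample_id), ]
  expect_false(anyNA(md$host_type) || anyNA(md$stage))
  # regimes assigned juvenile = niche, adult = neutral
  regimes <- vapply(study$truth$groups, `[[`, "", "regime")
  expect_true(all(regimes[grepl("juvenile", names(regimes))] == "niche"))
  expect_true(all(regimes[grepl("adult", names(regimes))] == "neutral"))
  # taxonomy covers the table, with both guilds present
  expect_setequal(study$taxonomy$asv_id, rownames(study$counts))
  expect_true(any(study$taxonomy$is_ecm) && any(!study$taxonomy$is_ecm))
  # replicate arithmetic
  small <- generate_study(synthetic_config(n_replicates = 1L, seed = 2,
                                           depth = 800L))
  expect_identical(ncol(small$counts), 12L)
})

test_that("a fixed seed reproduces the study bitwise", {
  a <- generate_study(synthetic_config(seed = 33, depth = 1200L))
  b <- generate_study(synthetic_config(seed = 33, depth = 1200L))
  expect_identical(a$counts, b$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$taxonomy, b$taxonomy)
  expect_identical(a$truth$affinity, b$truth$affinity)
})

test_that("generated tables satisfy the ASV-table invariants untouched", {
  study <- generate_study(synthetic_config(seed = 5, n_replicates = 2L,
                                           depth = 1000L))
  expect_silent(validate_asv_table(study$counts))
  expect_silent(validate_sample_metadata(study$metadata, study$counts))
})
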