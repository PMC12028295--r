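# fixtures and independent brute-force oracles used across test files

make_table <- function(counts, asv_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(asv_ids)) asv_ids <- paste0("ASV_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  asv_table(counts, asv_ids, sample_ids)
}

random_table <- function(n_asvs, n_samples, seed, lambda = 20) {
  set.seed(seed)
  m <- matrix(stats::rpois(n_asvs * n_samples, lambda), n_asvs, n_samples)
  # guarantee no all-zero samples
  for (j in which(colSums(m) == 0)) m[1L, j] <- 1L
  make_table(m)
}

toy_metadata <- function(sample_ids, host_type, stage,
                         host_species = NULL) {
  data.frame(sample_id = sample_ids,
             host_species = host_species %||%
               paste0(host_type, "_sp"),
             host_type = host_type, stage = stage,
             replicate = seq_along(sample_ids),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles (deliberately naive loops, independent of vegan/mgcv) ---

shannon_loop <- function(x) {
  p <- x[x > 0] / sum(x)
  s <- 0
  for (pi in p) s <- s - pi * log(pi)
  s
}

simpson_loop <- function(x) {
  p <- x / sum(x)
  s <- 0
  for (pi in p) s <- s + pi^2
  1 - s
}

sobs_loop <- function(x) {
  n <- 0L
  for (xi in x) if (xi > 0) n <- n + 1L
  n
}

bray_loop <- function(x, y) {
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  as.numeric(num / den)
}

migration_loop <- function(f_obs, f_pred) {
  num <- 0; den <- 0
  for (i in seq_along(f_obs)) {
    num <- num + f_obs[i] * (1 - f_obs[i])
    den <- den + f_pred[i] * (1 - f_pred[i])
  }
  as.numeric(num / den)
}

# direct sum-of-squares PERMANOVA R2 for a one-factor design, computed
# from squared distances (Anderson's identity: SS_total = sum d^2 / N,
# SS_within = per-group sum d^2 / n_g)
permanova_r2_direct <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  ss_total <- sum(dm[lower.tri(dm)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- dm[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  (ss_total - ss_within) / ss_total
}

# ANOSIM R from hand-ranked dissimilarities
anosim_r_manual <- function(d, groups) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  pairs <- which(lower.tri(dm), arr.ind = TRUE)
  dv <- dm[lower.tri(dm)]
  rk <- rank(dv)
  between <- groups[pairs[, 1]] != groups[pairs[, 2]]
  (mean(rk[between]) - mean(rk[!between])) / (n * (n - 1) / 4)
}
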