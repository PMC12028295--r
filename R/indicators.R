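#' Random-forest classification of samples from ASV abundances
#'
#' Trains a random-forest classifier (default 1000 trees) on per-sample
#' ASV relative abundances against a binary factor (e.g. stage or host
#' type) and returns both impurity-based (mean decrease in Gini) and
#' permutation (mean decrease in accuracy) importances per ASV, plus the
#' out-of-bag accuracy. Ranking uses permutation importance by default,
#' which is less biased for correlated compositional features.
#'
#' @param rel_abund Taxa x samples matrix of relative abundances.
#' @param labels Factor of class labels, one per sample; >= 2 classes
#'   with >= 2 samples each.
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer RNG seed.
#' @param rank_by `"permutation"` or `"impurity"`.
#' @return List with `importance` (data frame `asv_id`,
#'   `mean_decrease_accuracy`, `mean_decrease_gini`, `rank`, sorted by
#'   rank) and `oob_accuracy`.
#' @export
rf_classify <- function(rel_abund, labels, n_trees = 1000L, seed = 1L,
                        rank_by = c("permutation", "impurity")) {
  rank_by <- match.arg(rank_by)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop("labels must have >= 2 classes")
  if (any(table(labels) < 2L)) stop("each class needs >= 2 samples")
  if (ncol(rel_abund) != length(labels))
    stop("labels length must match the number of samples")
  x <- t(rel_abund)
  colnames(x) <- rownames(rel_abund)
  set.seed(seed)
  fit <- randomForest::randomForest(x = x, y = labels, ntree = n_trees,
                                    importance = TRUE)
  imp <- randomForest::importance(fit)
  df <- data.frame(asv_id = rownames(imp),
                   mean_decrease_accuracy = imp[, "MeanDecreaseAccuracy"],
                   mean_decrease_gini = imp[, "MeanDecreaseGini"],
                   row.names = NULL, stringsAsFactors = FALSE)
  score <- if (rank_by == "permutation") df$mean_decrease_accuracy
           else df$mean_decrease_gini
  df <- df[order(-score), ]
  df$rank <- seq_len(nrow(df))
  oob <- sum(diag(fit$confusion[, levels(labels)])) / length(labels)
  list(importance = df, oob_accuracy = oob, n_trees = n_trees,
       rank_by = rank_by, seed = seed)
}

#' Log response ratios with bootstrap confidence intervals
#'
#' For each requested ASV, computes the log response ratio
#' `lnRR = ln(mean_A / mean_B)` of mean relative abundance between the
#' two label groups, with a 95% nonparametric bootstrap CI over samples
#' within each group. When one group's mean is exactly zero the ratio is
#' reported as `+Inf`/`-Inf` with `one_sided = TRUE` (the taxon is
#' absent from one group; a finite ratio would require a pseudo-count).
#'
#' @param counts Validated ASV count matrix.
#' @param labels Two-level factor over samples; the first level is the
#'   numerator group A.
#' @param top_asvs Character vector of ASV IDs to evaluate.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer RNG seed.
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame with one row per ASV: `asv_id`, `lnrr`,
#'   `ci_lower`, `ci_upper`, `mean_a`, `se_a`, `mean_b`, `se_b` (group
#'   means and SEs in % relative abundance), `one_sided`. ASVs with both
#'   group means zero are dropped with a warning.
#' @export
lnrr_effects <- function(counts, labels, top_asvs, n_boot = 1000L,
                         seed = 1L, conf_level = 0.95) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("labels must have exactly 2 levels")
  if (!length(top_asvs)) stop("top_asvs must be nonempty")
  missing <- setdiff(top_asvs, rownames(counts))
  if (length(missing))
    stop("ASVs not in table: ", paste(missing, collapse = ", "))
  rel <- relative_abundance(counts)
  a_idx <- which(labels == levels(labels)[1L])
  b_idx <- which(labels == levels(labels)[2L])
  probs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  set.seed(seed)
  rows <- lapply(top_asvs, function(id) {
    xa <- rel[id, a_idx]
    xb <- rel[id, b_idx]
    ma <- mean(xa); mb <- mean(xb)
    if (ma == 0 && mb == 0) {
      warning("skipping ", id, ": zero mean abundance in both groups")
      return(NULL)
    }
    se <- function(x) stats::sd(x) / sqrt(length(x))
    boot_means <- function(x) {
      idx <- matrix(sample.int(length(x), length(x) * n_boot,
                               replace = TRUE), nrow = n_boot)
      rowMeans(matrix(x[idx], nrow = n_boot))
    }
    if (ma > 0 && mb > 0) {
      lr <- log(ma / mb)
      bl <- log(pmax(boot_means(xa), .Machine$double.xmin) /
                pmax(boot_means(xb), .Machine$double.xmin))
      ci <- stats::quantile(bl, probs, names = FALSE)
      one_sided <- FALSE
    } else {
      # taxon absent from one group: one-sided effect, CI from the
      # bootstrap of the nonzero side's mean (on the log scale)
      nz <- if (ma > 0) xa else xb
      bm <- boot_means(nz)
      bm <- bm[bm > 0]
      ci <- if (length(bm)) stats::quantile(log(bm), probs, names = FALSE)
            else c(NA_real_, NA_real_)
      lr <- if (ma > 0) Inf else -Inf
      one_sided <- TRUE
    }
    data.frame(asv_id = id, lnrr = lr, ci_lower = ci[1L],
               ci_upper = ci[2L], mean_a = 100 * ma, se_a = 100 * se(xa),
               mean_b = 100 * mb, se_b = 100 * se(xb),
               one_sided = one_sided, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(asv_id = character(0), lnrr = numeric(0),
                      ci_lower = numeric(0), ci_upper = numeric(0),
                      mean_a = numeric(0), se_a = numeric(0),
                      mean_b = numeric(0), se_b = numeric(0),
                      one_sided = logical(0))
  rownames(out) <- NULL
  out
}

#' Per-ASV univariate group tests
#'
#' Applies the assumption-driven ANOVA / Kruskal-Wallis selection of
#' [compare_groups()] to each ASV's relative abundances, and reports raw
#' and Benjamini-Hochberg-adjusted p-values. All-zero ASVs are skipped.
#'
#' @param counts Validated ASV count matrix.
#' @param labels Factor over samples.
#' @param asv_ids ASVs to test (default: all).
#' @return Data frame `asv_id`, `test_used`, `statistic`, `p_value`,
#'   `p_adjust` (BH).
#' @export
per_asv_tests <- function(counts, labels, asv_ids = rownames(counts)) {
  rel <- relative_abundance(counts)
  rows <- lapply(asv_ids, function(id) {
    x <- rel[id, ]
    res <- tryCatch(compare_groups(x, labels), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(asv_id = id, test_used = res$test_used,
               statistic = res$statistic, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(asv_id = character(0), test_used = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_adjust = numeric(0)))
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Full indicator-taxon analysis for one contrast
#'
#' Random-forest ranking of all ASVs, short-listing of the top `top_n`
#' by importance, then log response ratios with bootstrap CIs and
#' univariate tests on the short list; taxonomy labels are attached when
#' provided. The lnRR orientation (numerator group) is the first factor
#' level and is recorded in the result.
#'
#' @param counts Validated ASV count matrix.
#' @param metadata Sample metadata.
#' @param contrast Metadata column defining the binary contrast
#'   (`"stage"` or `"host_type"`).
#' @param taxonomy Optional taxonomy data frame for genus labels.
#' @param top_n Short-list size (default 30).
#' @param n_trees,n_boot,seed Passed to [rf_classify()] and
#'   [lnrr_effects()].
#' @return List with `rf` (full ranking + OOB accuracy), `indicators`
#'   (short-list data frame with lnRR, CIs, group means +/- SE in %,
#'   tests), `contrast`, `numerator_group`.
#' @export
indicator_analysis <- function(counts, metadata, contrast = "stage",
                               taxonomy = NULL, top_n = 30L,
                               n_trees = 1000L, n_boot = 1000L,
                               seed = 1L) {
  counts <- validate_asv_table(counts)
  metadata <- validate_sample_metadata(metadata, counts)
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  # orientation: juvenile/adult -> ln(juvenile/adult);
  # conifer/broadleaf -> ln(conifer/broadleaf)
  lv <- switch(contrast,
               stage = c("juvenile", "adult"),
               host_type = c("conifer", "broadleaf"),
               sort(unique(md[[contrast]])))
  labels <- factor(md[[contrast]], levels = lv)
  rel <- relative_abundance(counts)
  rf <- rf_classify(rel, labels, n_trees = n_trees, seed = seed)
  top <- utils::head(rf$importance$asv_id, top_n)
  eff <- lnrr_effects(counts, labels, top, n_boot = n_boot, seed = seed)
  tests <- per_asv_tests(counts, labels, asv_ids = eff$asv_id)
  out <- merge(eff, tests, by = "asv_id", sort = FALSE)
  out <- merge(out, rf$importance[, c("asv_id", "mean_decrease_accuracy",
                                      "rank")], by = "asv_id",
               sort = FALSE)
  if (!is.null(taxonomy))
    out <- merge(out, taxonomy[, c("asv_id", "genus")], by = "asv_id",
                 all.x = TRUE, sort = FALSE)
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  list(rf = rf, indicators = out, contrast = contrast,
       numerator_group = lv[1L])
}
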