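#' Per-sample alpha diversity
#'
#' Shannon diversity (natural log), Gini-Simpson diversity
#' (1 - sum p^2), Pielou's evenness (Shannon / ln richness) and observed
#' richness, computed per sample with \pkg{vegan}. Pielou's evenness is
#' undefined for single-taxon samples and reported as `NA` there.
#'
#' @param counts Validated ASV count matrix; no all-zero samples.
#' @return Data frame with columns `sample_id`, `shannon`, `simpson`,
#'   `pielou`, `sobs`.
#' @export
alpha_diversity <- function(counts) {
  counts <- validate_asv_table(counts)
  if (any(colSums(counts) <= 0))
    stop("all-zero sample(s): ",
         paste(colnames(counts)[colSums(counts) <= 0], collapse = ", "))
  comm <- t(counts)
  shannon <- vegan::diversity(comm, index = "shannon")
  simpson <- vegan::diversity(comm, index = "simpson")
  sobs <- vegan::specnumber(comm)
  pielou <- ifelse(sobs > 1L, shannon / log(sobs), NA_real_)
  data.frame(sample_id = colnames(counts), shannon = unname(shannon),
             simpson = unname(simpson), pielou = unname(pielou),
             sobs = unname(sobs), stringsAsFactors = FALSE)
}

#' Compare a metric across groups with assumption-driven test selection
#'
#' Runs Shapiro-Wilk normality checks per group and Levene and Bartlett
#' homogeneity-of-variance tests, then applies one-way ANOVA when
#' normality and homoscedasticity hold (all assumption p-values > alpha)
#' and the Kruskal-Wallis rank test otherwise. The full assumption
#' record is returned so the choice can be audited.
#'
#' @param values Numeric vector of per-sample metric values.
#' @param groups Factor (or coercible) of group labels, same length.
#' @param alpha Assumption-test significance level (default 0.05).
#' @return List with `test_used` ("ANOVA" or "Kruskal-Wallis"),
#'   `statistic`, `p_value`, and `assumptions` (shapiro_p per group,
#'   levene_p, bartlett_p).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  keep <- !is.na(values)
  values <- values[keep]
  groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 3L)) stop("each group needs >= 3 samples")
  if (stats::var(values) == 0) stop("values are constant across all groups")
  shapiro_p <- vapply(levels(groups), function(g) {
    x <- values[groups == g]
    if (length(unique(x)) < 3L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }, numeric(1L))
  levene_p <- tryCatch(
    car::leveneTest(values ~ groups)[1L, "Pr(>F)"],
    error = function(e) NA_real_)
  bartlett_p <- tryCatch(
    stats::bartlett.test(values, groups)$p.value,
    error = function(e) NA_real_)
  normal_ok <- all(!is.na(shapiro_p)) && all(shapiro_p > alpha)
  var_ok <- !is.na(levene_p) && levene_p > alpha &&
    !is.na(bartlett_p) && bartlett_p > alpha
  if (normal_ok && var_ok) {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    res <- list(test_used = "ANOVA", statistic = tab[1L, "F value"],
                p_value = tab[1L, "Pr(>F)"])
  } else {
    kw <- stats::kruskal.test(values, groups)
    res <- list(test_used = "Kruskal-Wallis",
                statistic = unname(kw$statistic), p_value = kw$p.value)
  }
  res$assumptions <- list(shapiro_p = shapiro_p, levene_p = levene_p,
                          bartlett_p = bartlett_p)
  res
}

#' Group means and standard errors of diversity indices
#'
#' @param results Per-sample data frame from [alpha_diversity()].
#' @param metadata Sample metadata covering all samples.
#' @param grouping Metadata columns to cross (default
#'   `c("host_type", "stage")`).
#' @return Data frame with one row per group x index: `group`, `index`,
#'   `n`, `mean`, `se`.
#' @export
summarize_by_group <- function(results, metadata,
                               grouping = c("host_type", "stage")) {
  md <- metadata[match(results$sample_id, metadata$sample_id), ]
  if (anyNA(md$sample_id))
    stop("metadata does not cover all samples")
  key <- interaction(md[grouping], drop = TRUE, sep = ".")
  indices <- c("shannon", "simpson", "pielou", "sobs")
  out <- do.call(rbind, lapply(levels(key), function(g) {
    do.call(rbind, lapply(indices, function(ix) {
      x <- results[[ix]][key == g]
      x <- x[!is.na(x)]
      data.frame(group = g, index = ix, n = length(x), mean = mean(x),
                 se = if (length(x) > 1L)
                        stats::sd(x) / sqrt(length(x)) else 0,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
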