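#' Bray-Curtis dissimilarity between samples
#'
#' Computes `d(x, y) = sum(|x - y|) / sum(x + y)` over all sample pairs
#' of an abundance matrix (typically Hellinger-transformed relative
#' abundances; see [hellinger_transform()]).
#'
#' @param abund Non-negative matrix, taxa x samples.
#' @return A `dist` object over samples with entries in \[0, 1\].
#' @export
bray_curtis <- function(abund) {
  if (any(abund < 0)) stop("abundances must be non-negative")
  zero <- colSums(abund) == 0
  if (sum(zero) >= 2L)
    stop("Bray-Curtis undefined between all-zero samples: ",
         paste(colnames(abund)[zero], collapse = ", "))
  vegan::vegdist(t(abund), method = "bray")
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Minimizes Kruskal stress-1 over random restarts via
#' [vegan::metaMDS()]. The seed fixes the restarts, so identical seeds
#' give identical configurations and stress.
#'
#' @param d `dist` object (e.g. from [bray_curtis()]).
#' @param k Ordination dimension (default 2).
#' @param seed Integer RNG seed.
#' @param n_starts Random restarts (default 20).
#' @return List with `points` (samples x k coordinates) and `stress`.
#' @export
nmds_ordination <- function(d, k = 2L, seed = 1L, n_starts = 20L) {
  if (attr(d, "Size") < 4L) stop("NMDS needs >= 4 samples")
  set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, trymax = n_starts, trace = 0,
                        autotransform = FALSE, wascores = FALSE)
  list(points = fit$points, stress = fit$stress)
}

#' Normal-theory 95% confidence ellipses for ordination groups
#'
#' For each group of samples, returns the mean coordinate and the
#' covariance matrix of the group's ordination coordinates together with
#' the chi-squared scaling radius of the requested confidence level --
#' the parameters of the usual bivariate-normal confidence ellipse drawn
#' around ordination clusters.
#'
#' @param points Samples x 2 coordinate matrix.
#' @param groups Group labels, one per sample.
#' @param level Confidence level (default 0.95).
#' @return Named list per group: `center`, `cov`, `radius`, `n`.
#' @export
group_ellipses <- function(points, groups, level = 0.95) {
  groups <- droplevels(as.factor(groups))
  r <- sqrt(stats::qchisq(level, df = 2L))
  out <- lapply(levels(groups), function(g) {
    xy <- points[groups == g, , drop = FALSE]
    list(center = colMeans(xy),
         cov = if (nrow(xy) > 1L) stats::cov(xy)
               else matrix(0, 2L, 2L),
         radius = r, n = nrow(xy))
  })
  names(out) <- levels(groups)
  out
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Single-factor PERMANOVA on a distance matrix via [vegan::adonis2()]:
#' pseudo-F and R-squared from the Gower-centered partition of summed
#' squared distances, with a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d `dist` object.
#' @param groups Factor of group labels, one per sample, >= 2 levels.
#' @param n_permutations Number of permutations (default 999).
#' @param seed Integer RNG seed.
#' @return List with `factor_name`, `r2`, `f`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_permutations = 999L, seed = 1L) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("PERMANOVA needs >= 2 group levels")
  if (length(groups) != attr(d, "Size"))
    stop("groups length must match the distance matrix")
  set.seed(seed)
  dat <- data.frame(g = groups)
  fit <- vegan::adonis2(d ~ g, data = dat,
                        permutations = n_permutations)
  list(factor_name = deparse(substitute(groups)),
       r2 = fit$R2[1L], f = fit$F[1L], p_value = fit$`Pr(>F)`[1L],
       n_permutations = n_permutations, seed = seed)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based test of between- versus within-group dissimilarity via
#' [vegan::anosim()]; R = (mean between-group rank - mean within-group
#' rank) / (N(N-1)/4), with a permutation p-value.
#'
#' @inheritParams permanova
#' @return List with `factor_name`, `r`, `p_value`, `n_permutations`,
#'   `seed`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999L, seed = 1L) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("ANOSIM needs >= 2 group levels")
  if (length(groups) != attr(d, "Size"))
    stop("groups length must match the distance matrix")
  set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_permutations)
  list(factor_name = deparse(substitute(groups)),
       r = unname(fit$statistic), p_value = fit$signif,
       n_permutations = n_permutations, seed = seed)
}
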