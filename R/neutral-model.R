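#' Per-ASV occurrence frequency and mean abundance within a group
#'
#' For one host group (a set of samples), computes each ASV's occurrence
#' frequency (fraction of the group's samples where it is detected) and
#' the log10 of its mean relative abundance across the group's samples.
#' ASVs absent from the whole group are excluded so the log is defined.
#'
#' @param counts Validated ASV count matrix.
#' @param group_samples Character vector of sample IDs forming the group.
#' @return Data frame with columns `asv_id`, `f_obs`, `mean_log_abund`,
#'   and attribute `n_samples`.
#' @export
occurrence_frequency <- function(counts, group_samples) {
  counts <- validate_asv_table(counts)
  missing <- setdiff(group_samples, colnames(counts))
  if (length(missing))
    stop("group samples not in table: ", paste(missing, collapse = ", "))
  if (length(group_samples) == 0L) stop("empty sample group")
  sub <- counts[, group_samples, drop = FALSE]
  rel <- relative_abundance(sub)
  n <- ncol(sub)
  f_obs <- rowSums(sub > 0L) / n
  mean_ab <- rowMeans(rel)
  keep <- mean_ab > 0
  out <- data.frame(asv_id = rownames(sub)[keep],
                    f_obs = f_obs[keep],
                    mean_log_abund = log10(mean_ab[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_samples") <- n
  out
}

#' Migration rate from observed and predicted occupancies
#'
#' The dispersal-dynamics statistic is the ratio of summed occupancy
#' variance terms,
#' `m = sum(f_obs * (1 - f_obs)) / sum(f_pred * (1 - f_pred))`,
#' computed exactly in this form. It equals 1 when observed and fitted
#' occupancies coincide elementwise.
#'
#' @param f_obs,f_pred Numeric vectors of equal length with entries in
#'   \[0, 1\].
#' @return The ratio `m` (a single non-negative number).
#' @export
migration_rate <- function(f_obs, f_pred) {
  if (length(f_obs) != length(f_pred))
    stop("f_obs and f_pred must have the same length")
  if (any(f_obs < 0 | f_obs > 1) || any(f_pred < 0 | f_pred > 1))
    stop("occupancies must lie in [0, 1]")
  denom <- sum(f_pred * (1 - f_pred))
  if (denom == 0)
    stop("degenerate predicted occupancies: all f_pred in {0, 1}")
  sum(f_obs * (1 - f_obs)) / denom
}

#' Fit the abundance-occupancy neutral model for one group
#'
#' Fits a binomial generalized additive model (logit link) of occupancy
#' (occupied samples out of `n_samples`) on log10 mean relative
#' abundance, with a penalized regression spline smoother. Fitted
#' occupancies are mapped through the inverse link and therefore lie in
#' \[0, 1\]. Model fit is summarized by the pseudo-R-squared
#' `1 - residual deviance / null deviance`, and dispersal dynamics by the
#' migration rate of [migration_rate()]. A pointwise 95% confidence band
#' (fit +/- 1.96 SE on the link scale, back-transformed) is evaluated on
#' an abundance grid.
#'
#' @param profile Group profile from [occurrence_frequency()].
#' @param k Spline basis dimension (default 10); reduced with a warning
#'   when there are fewer unique abundance values.
#' @param bs Smoother basis (default `"cr"`, penalized cubic regression
#'   spline).
#' @param n_grid Number of grid points for the confidence band.
#' @return List of class `"neutral_fit"`: `profile` (with an added
#'   `f_pred` column), `pseudo_r2`, `m`, `band` (data frame with
#'   `mean_log_abund`, `fit`, `lower`, `upper`), `n_samples`, `n_asvs`
#'   and `smoother_spec`.
#' @export
fit_gam_occupancy <- function(profile, k = 10L, bs = "cr",
                              n_grid = 200L) {
  if (nrow(profile) < 10L)
    stop("insufficient data: need >= 10 ASVs to fit the occupancy smoother, got ",
         nrow(profile))
  n <- attr(profile, "n_samples")
  if (is.null(n)) stop("profile lacks the n_samples attribute")
  n_unique <- length(unique(profile$mean_log_abund))
  k_use <- k
  if (n_unique <= k) {
    k_use <- max(3L, n_unique - 1L)
    warning("reducing basis dimension from ", k, " to ", k_use,
            " (only ", n_unique, " unique abundance values)")
  }
  occupied <- round(profile$f_obs * n)
  dat <- data.frame(x = profile$mean_log_abund, succ = occupied,
                    fail = n - occupied)
  fit <- mgcv::gam(cbind(succ, fail) ~ s(x, k = k_use, bs = bs),
                   family = stats::binomial(link = "logit"), data = dat,
                   method = "GCV.Cp")
  if (!fit$converged)
    stop("occupancy smoother failed to converge (", nrow(profile),
         " ASVs, k = ", k_use, ")")
  f_pred <- as.numeric(stats::fitted(fit))
  # a saturated-by-the-intercept fit (all occupancies equal) has zero
  # null deviance; the smoother then explains nothing beyond the null
  pseudo_r2 <- if (fit$null.deviance <= 1e-10) 0 else
    1 - fit$deviance / fit$null.deviance
  m <- migration_rate(profile$f_obs, f_pred)
  grid <- data.frame(x = seq(min(dat$x), max(dat$x), length.out = n_grid))
  pr <- mgcv::predict.gam(fit, newdata = grid, se.fit = TRUE)
  inv <- stats::binomial()$linkinv
  band <- data.frame(mean_log_abund = grid$x,
                     fit = inv(pr$fit),
                     lower = inv(pr$fit - 1.96 * pr$se.fit),
                     upper = inv(pr$fit + 1.96 * pr$se.fit))
  profile$f_pred <- f_pred
  structure(list(profile = profile, pseudo_r2 = pseudo_r2, m = m,
                 band = band, n_samples = n, n_asvs = nrow(profile),
                 smoother_spec = list(basis = bs, k = k_use,
                                      link = "logit",
                                      family = "binomial",
                                      method = "GCV.Cp")),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Abundance-occupancy neutral model fit\n")
  cat(sprintf("  ASVs: %d over %d samples\n", x$n_asvs, x$n_samples))
  cat(sprintf("  pseudo-R2 = %.3f, migration rate m = %.3f\n",
              x$pseudo_r2, x$m))
  invisible(x)
}

#' Fit the neutral model for every host group
#'
#' Splits samples by the given metadata factors (default host type x
#' developmental stage, yielding conifer/broadleaf x juvenile/adult) and
#' fits [fit_gam_occupancy()] per group. A group whose fit fails is
#' returned as a failure record; the other groups are still fitted.
#'
#' @param counts Validated ASV count matrix.
#' @param metadata Sample metadata covering all samples.
#' @param grouping Metadata column names to cross (default
#'   `c("host_type", "stage")`).
#' @param ... Passed to [fit_gam_occupancy()].
#' @return Named list of `"neutral_fit"` objects (or
#'   `list(failed = TRUE, error = <message>)` entries), keyed
#'   "level1.level2".
#' @export
fit_all_groups <- function(counts, metadata,
                           grouping = c("host_type", "stage"), ...) {
  counts <- validate_asv_table(counts)
  metadata <- validate_sample_metadata(metadata, counts)
  md <- metadata[match(colnames(counts), metadata$sample_id), ]
  key <- interaction(md[grouping], drop = TRUE, sep = ".")
  out <- lapply(levels(key), function(g) {
    ids <- colnames(counts)[key == g]
    tryCatch(
      fit_gam_occupancy(occurrence_frequency(counts, ids), ...),
      error = function(e) list(failed = TRUE, error = conditionMessage(e)))
  })
  names(out) <- levels(key)
  out
}

#' Flatten per-group neutral fits into one per-ASV table
#'
#' Convenience export for plotting abundance-occupancy clouds and fitted
#' curves: one row per ASV per successfully fitted group.
#'
#' @param fits Result of [fit_all_groups()].
#' @return Data frame with columns `group`, `asv_id`, `mean_log_abund`,
#'   `f_obs`, `f_pred`.
#' @export
neutral_fit_table <- function(fits) {
  ok <- Filter(function(f) inherits(f, "neutral_fit"), fits)
  do.call(rbind, lapply(names(ok), function(g) {
    cbind(group = g, ok[[g]]$profile)
  }))
}
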