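#' Remove ASVs detected in only one sample
#'
#' ASVs whose non-zero counts are confined to a single sample are likely
#' artifactual and are removed. The sample set is unchanged.
#'
#' @param counts Validated ASV count matrix.
#' @return Count matrix restricted to ASVs present in >= 2 samples.
#' @export
filter_single_sample_asvs <- function(counts) {
  counts <- validate_asv_table(counts)
  keep <- rowSums(counts > 0L) >= 2L
  counts[keep, , drop = FALSE]
}

#' Zero out low-count presences
#'
#' Any cell with fewer than `min_count` reads (but more than zero) is set
#' to zero, treating such presences as likely false positives (tag
#' switching, index bleed). ASVs left with no reads anywhere are dropped.
#'
#' @param counts Validated ASV count matrix.
#' @param min_count Minimum reads for a presence to be kept (default 10).
#' @return Filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 10L) {
  counts <- validate_asv_table(counts)
  if (min_count < 1L) stop("min_count must be >= 1")
  counts[counts > 0L & counts < min_count] <- 0L
  counts[rowSums(counts) > 0L, , drop = FALSE]
}

#' Restrict an ASV table to ectomycorrhizal taxa
#'
#' Keeps exactly the ASVs whose genus-level guild annotation marks them as
#' ectomycorrhizal (`is_ecm` in the taxonomy table).
#'
#' @param counts Validated ASV count matrix.
#' @param taxonomy Taxonomy data frame with `asv_id` and `is_ecm` columns;
#'   must cover every ASV in `counts`.
#' @return Count matrix restricted to EcM ASVs.
#' @export
filter_ecm <- function(counts, taxonomy) {
  counts <- validate_asv_table(counts)
  idx <- match(rownames(counts), taxonomy$asv_id)
  if (anyNA(idx))
    stop("ASVs missing from taxonomy: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "))
  counts[taxonomy$is_ecm[idx] %in% TRUE, , drop = FALSE]
}

#' Rarefy samples to a common sequencing depth
#'
#' Each sample's reads are subsampled without replacement to exactly
#' `depth` reads. Samples whose total is below `depth` are dropped with a
#' warning. Subsampling uses [vegan::rrarefy()] under the given seed, so
#' identical seeds give identical tables.
#'
#' @param counts Validated ASV count matrix.
#' @param depth Target reads per sample (default 23167).
#' @param seed Integer RNG seed; required for reproducibility.
#' @return Rarefied count matrix; every column sums to `depth`. ASVs that
#'   lose all reads are retained as all-zero rows so downstream code can
#'   decide whether to drop them.
#' @export
rarefy_table <- function(counts, depth = 23167L, seed) {
  counts <- validate_asv_table(counts)
  if (depth <= 0L) stop("depth must be a positive integer")
  if (missing(seed)) stop("a seed is required for rarefaction")
  totals <- colSums(counts)
  shallow <- totals < depth
  if (any(shallow)) {
    warning("dropping ", sum(shallow), " sample(s) below depth ", depth,
            ": ", paste(colnames(counts)[shallow], collapse = ", "))
    counts <- counts[, !shallow, drop = FALSE]
  }
  if (ncol(counts) == 0L) stop("no samples at or above depth ", depth)
  set.seed(seed)
  out <- withCallingHandlers(
    t(vegan::rrarefy(t(counts), depth)),
    # rrarefy nags whenever the smallest count exceeds 1; harmless here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(out) <- "integer"
  out
}

#' Convert counts to within-sample relative abundances
#'
#' @param counts ASV count matrix; every sample column sum must be > 0.
#' @return Numeric matrix of proportions; each column sums to 1.
#' @export
relative_abundance <- function(counts) {
  totals <- colSums(counts)
  if (any(totals <= 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  }
  sweep(counts, 2L, totals, "/")
}

#' Hellinger transformation
#'
#' Square root of relative abundances; a variance-stabilising transform
#' commonly applied before Bray-Curtis and ordination so that abundant
#' taxa do not dominate community distances.
#'
#' @param rel_abund Matrix of proportions in \[0, 1\].
#' @return Matrix of square-rooted proportions.
#' @export
hellinger_transform <- function(rel_abund) {
  if (any(rel_abund < 0)) stop("negative relative abundances")
  sqrt(rel_abund)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: low-count zeroing ([filter_low_counts()]),
#' single-sample ASV removal ([filter_single_sample_asvs()]), the EcM
#' guild filter ([filter_ecm()]) and rarefaction ([rarefy_table()]).
#' Presence corrections come first so the single-sample rule acts on
#' corrected presences.
#'
#' @param counts Validated ASV count matrix.
#' @param taxonomy Taxonomy data frame (required unless
#'   `ecm_filter = FALSE`).
#' @param min_count Per-cell presence threshold (default 10).
#' @param depth Rarefaction depth (default 23167); `NULL` skips
#'   rarefaction.
#' @param seed RNG seed for rarefaction.
#' @param ecm_filter Apply the EcM guild filter? Default `TRUE`.
#' @return List with `counts` (the analysis-ready table) and `provenance`
#'   (parameters, seed, dropped ASVs/samples).
#' @export
preprocess_asv_table <- function(counts, taxonomy = NULL, min_count = 10L,
                                 depth = 23167L, seed = 1L,
                                 ecm_filter = TRUE) {
  counts <- validate_asv_table(counts)
  asv0 <- rownames(counts)
  smp0 <- colnames(counts)
  out <- filter_low_counts(counts, min_count)
  out <- filter_single_sample_asvs(out)
  if (ecm_filter) {
    if (is.null(taxonomy)) stop("taxonomy is required when ecm_filter = TRUE")
    out <- filter_ecm(out, taxonomy)
  }
  dropped_samples <- character(0)
  if (!is.null(depth)) {
    out <- withCallingHandlers(
      rarefy_table(out, depth, seed),
      warning = function(w) {
        dropped_samples <<- setdiff(smp0, character(0))
        invokeRestart("muffleWarning")
      })
    dropped_samples <- setdiff(smp0, colnames(out))
    out <- out[rowSums(out) > 0L, , drop = FALSE]
  }
  list(
    counts = out,
    provenance = list(
      min_count = min_count,
      ecm_filter = ecm_filter,
      depth = if (is.null(depth)) NA_integer_ else depth,
      seed = seed,
      n_asvs_in = length(asv0),
      n_asvs_out = nrow(out),
      dropped_asvs = setdiff(asv0, rownames(out)),
      dropped_samples = dropped_samples
    )
  )
}

#' Write preprocessing provenance as JSON
#'
#' @param provenance Provenance list from [preprocess_asv_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  jsonlite::write_json(provenance, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
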