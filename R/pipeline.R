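#' Configuration for the end-to-end pipeline
#'
#' Either `simulation` (a [synthetic_config()]) or the three input paths
#' must be given.
#'
#' @param asv_table_path,metadata_path,taxonomy_path Input files
#'   (TSV; the ASV table may also be BIOM, detected by extension).
#' @param simulation Optional [synthetic_config()]; when set, inputs are
#'   simulated instead of read.
#' @param min_count Per-cell presence threshold (default 10).
#' @param ecm_filter Apply the EcM guild filter (default TRUE).
#' @param depth Rarefaction depth (default 23167); NULL to skip.
#' @param seed Master seed for rarefaction, permutation tests, NMDS, RF
#'   and bootstraps.
#' @param grouping Factors crossed for neutral fits and diversity
#'   summaries.
#' @param factors Factors tested with PERMANOVA/ANOSIM.
#' @param contrasts Binary contrasts for indicator analysis.
#' @param n_permutations,n_trees,n_boot,top_n Stage parameters.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(asv_table_path = NULL, metadata_path = NULL,
                            taxonomy_path = NULL, simulation = NULL,
                            min_count = 10L, ecm_filter = TRUE,
                            depth = 23167L, seed = 1L,
                            grouping = c("host_type", "stage"),
                            factors = c("stage", "host_type"),
                            contrasts = c("stage", "host_type"),
                            n_permutations = 999L, n_trees = 1000L,
                            n_boot = 1000L, top_n = 30L) {
  if (is.null(simulation) &&
      (is.null(asv_table_path) || is.null(metadata_path)))
    stop("provide either a simulation config or input paths")
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(report, name, expr) {
  report$stages[[name]] <- tryCatch(
    list(status = "ok", result = expr),
    error = function(e) list(status = "failed",
                             error = conditionMessage(e)))
  report
}

#' Run the full assembly-analysis pipeline
#'
#' Executes, in order: input (simulate or read), preprocessing
#' (low-count zeroing, single-sample removal, EcM filter, rarefaction),
#' per-group neutral-model fits, alpha diversity with group tests, beta
#' diversity (Hellinger + Bray-Curtis, NMDS, PERMANOVA, ANOSIM per
#' factor) and indicator-taxon analysis per contrast. A stage that
#' fails is recorded as failed and later independent stages still run.
#' All seeds and parameters are echoed into the report; intermediate
#' tables are written under `out_dir` when given.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for intermediate artifacts
#'   and `report.json`.
#' @return The report: a nested list with one entry per stage
#'   (`status`, `result`) plus `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  report <- list(stages = list(),
                 provenance = list(
                   seed = cfg$seed, min_count = cfg$min_count,
                   depth = cfg$depth, ecm_filter = cfg$ecm_filter,
                   n_permutations = cfg$n_permutations,
                   n_trees = cfg$n_trees, n_boot = cfg$n_boot,
                   top_n = cfg$top_n,
                   package_version =
                     as.character(utils::packageVersion("ecmassembly"))))

  # --- input ---
  if (!is.null(cfg$simulation)) {
    study <- generate_study(cfg$simulation)
    counts <- study$counts; metadata <- study$metadata
    taxonomy <- study$taxonomy
    report$provenance$input <- "simulated"
    report$provenance$simulation_seed <- cfg$simulation$seed
  } else {
    fmt <- if (grepl("\\.biom$", cfg$asv_table_path)) "biom" else "tsv"
    counts <- read_asv_table(cfg$asv_table_path, fmt)
    metadata <- read_sample_metadata(cfg$metadata_path)
    taxonomy <- if (!is.null(cfg$taxonomy_path))
      read_taxonomy(cfg$taxonomy_path) else NULL
    report$provenance$input <- cfg$asv_table_path
  }

  # --- preprocess ---
  pre <- preprocess_asv_table(counts, taxonomy, min_count = cfg$min_count,
                              depth = cfg$depth, seed = cfg$seed,
                              ecm_filter = cfg$ecm_filter &&
                                !is.null(taxonomy))
  tbl <- pre$counts
  metadata <- metadata[metadata$sample_id %in% colnames(tbl), ]
  report$stages$preprocess <- list(status = "ok",
                                   result = pre$provenance)
  if (!is.null(out_dir)) {
    write_asv_table(tbl, file.path(out_dir, "asv_table_filtered.tsv"))
    write_provenance(pre$provenance,
                     file.path(out_dir, "preprocess_provenance.json"))
  }

  # --- neutral model ---
  report <- run_stage(report, "neutral_model", {
    fits <- fit_all_groups(tbl, metadata, grouping = cfg$grouping)
    lapply(fits, function(f) {
      if (inherits(f, "neutral_fit"))
        list(pseudo_r2 = f$pseudo_r2, m = f$m, n_asvs = f$n_asvs,
             n_samples = f$n_samples, smoother_spec = f$smoother_spec)
      else f
    })
  })

  # --- alpha diversity ---
  report <- run_stage(report, "alpha_diversity", {
    div <- alpha_diversity(tbl)
    md <- metadata[match(div$sample_id, metadata$sample_id), ]
    tests <- lapply(cfg$factors, function(fac) {
      lapply(stats::setNames(
               c("shannon", "simpson", "pielou", "sobs"),
               c("shannon", "simpson", "pielou", "sobs")),
             function(ix) {
               res <- compare_groups(div[[ix]], md[[fac]])
               res$assumptions <- lapply(res$assumptions, unname)
               res
             })
    })
    names(tests) <- cfg$factors
    if (!is.null(out_dir))
      utils::write.csv(div, file.path(out_dir, "alpha_diversity.csv"),
                       row.names = FALSE)
    list(summary = summarize_by_group(div, metadata, cfg$grouping),
         tests = tests)
  })

  # --- beta diversity ---
  report <- run_stage(report, "beta_diversity", {
    hel <- hellinger_transform(relative_abundance(tbl))
    d <- bray_curtis(hel)
    ord <- nmds_ordination(d, seed = cfg$seed)
    md <- metadata[match(colnames(tbl), metadata$sample_id), ]
    tests <- lapply(cfg$factors, function(fac) {
      pm <- permanova(d, md[[fac]], cfg$n_permutations, seed = cfg$seed)
      an <- anosim_test(d, md[[fac]], cfg$n_permutations,
                        seed = cfg$seed)
      pm$factor_name <- fac; an$factor_name <- fac
      list(permanova = pm, anosim = an)
    })
    names(tests) <- cfg$factors
    if (!is.null(out_dir)) {
      utils::write.csv(data.frame(sample_id = rownames(ord$points),
                                  ord$points),
                       file.path(out_dir, "nmds_coordinates.csv"),
                       row.names = FALSE)
    }
    list(stress = ord$stress, tests = tests)
  })

  # --- indicator taxa ---
  report <- run_stage(report, "indicators", {
    res <- lapply(cfg$contrasts, function(ct) {
      ia <- indicator_analysis(tbl, metadata, contrast = ct,
                               taxonomy = taxonomy, top_n = cfg$top_n,
                               n_trees = cfg$n_trees,
                               n_boot = cfg$n_boot, seed = cfg$seed)
      if (!is.null(out_dir))
        utils::write.csv(ia$indicators,
                         file.path(out_dir,
                                   paste0("indicators_", ct, ".csv")),
                         row.names = FALSE)
      list(oob_accuracy = ia$rf$oob_accuracy,
           numerator_group = ia$numerator_group,
           indicators = ia$indicators)
    })
    names(res) <- cfg$contrasts
    res
  })

  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE, na = "null")
  report
}
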