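#' Simulate a long-tailed metacommunity abundance distribution
#'
#' Draws relative abundances for a regional species pool. The default is
#' a lognormal species-abundance distribution, the classic long-tailed
#' shape of fungal metacommunities; a log-series option is provided.
#'
#' @param n_asvs Number of taxa in the pool (>= 2).
#' @param distribution `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog Lognormal parameters (defaults 0 and 1.5).
#' @param ls_theta Log-series parameter in (0, 1) (default 0.999).
#' @param seed Integer RNG seed.
#' @return Numeric vector of proportions summing to 1, named ASV_1..ASV_n.
#' @export
simulate_metacommunity <- function(n_asvs, distribution = c("lognormal",
                                   "logseries"), meanlog = 0, sdlog = 1.5,
                                   ls_theta = 0.999, seed = 1L) {
  distribution <- match.arg(distribution)
  if (n_asvs < 2L) stop("n_asvs must be >= 2")
  set.seed(seed)
  w <- switch(distribution,
    lognormal = {
      if (sdlog < 0) stop("sdlog must be >= 0")
      stats::rlnorm(n_asvs, meanlog = meanlog, sdlog = sdlog)
    },
    logseries = {
      if (ls_theta <= 0 || ls_theta >= 1)
        stop("ls_theta must be in (0, 1)")
      # inverse-CDF draw from the logarithmic series distribution
      u <- stats::runif(n_asvs)
      vapply(u, function(ui) {
        k <- 1
        cdf <- -ls_theta / log(1 - ls_theta)
        pk <- cdf
        while (cdf < ui && k < 1e6) {
          k <- k + 1
          pk <- pk * ls_theta * (k - 1) / k
          cdf <- cdf + pk
        }
        as.numeric(k)
      }, numeric(1L))
    })
  p <- w / sum(w)
  names(p) <- paste0("ASV_", seq_len(n_asvs))
  p
}

#' Draw one Dirichlet-distributed proportion vector
#' @noRd
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a dispersal-structured (neutral) group of samples
#'
#' Each sample is a compound Dirichlet-multinomial draw around the
#' metacommunity: sample-level proportions come from
#' Dirichlet(alpha_i = depth * m_sim * p_i) and counts from a
#' multinomial of size `depth`. Larger `m_sim` means tighter coupling to
#' the metacommunity (less between-sample drift), mirroring the migration
#' parameter of neutral community models.
#'
#' @param p Metacommunity proportions (named).
#' @param n_samples Number of samples to draw.
#' @param depth Reads per sample.
#' @param m_sim Migration/coupling parameter in (0, 1].
#' @param seed Integer RNG seed.
#' @param sample_ids Optional sample names.
#' @return ASV count matrix (taxa x samples); columns sum to `depth`.
#' @export
simulate_neutral_group <- function(p, n_samples, depth, m_sim, seed = 1L,
                                   sample_ids = NULL) {
  if (m_sim <= 0 || m_sim > 1) stop("m_sim must be in (0, 1]")
  set.seed(seed)
  alpha <- depth * m_sim * p
  counts <- vapply(seq_len(n_samples), function(j) {
    q <- rdirichlet1(alpha)
    stats::rmultinom(1L, size = depth, prob = q)[, 1L]
  }, numeric(length(p)))
  dimnames(counts) <- list(names(p),
                           sample_ids %||% paste0("S", seq_len(n_samples)))
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a host-filtered (niche) group of samples
#'
#' Expected proportions for a sample on host h are proportional to
#' p_i * affinity\[i, h\]^filter_strength (host-level filtering), and
#' each individual sample additionally retains each taxon with
#' probability `colonization_prob` (an individual-level microsite /
#' priority-effect filter: each root system is colonized by an
#' idiosyncratic subset of the host-compatible pool). Counts are then
#' multinomial of size `depth` on the renormalized weights. With
#' `filter_strength = 0` and `colonization_prob = 1` this reduces to
#' plain multinomial sampling from the metacommunity.
#'
#' @param p Metacommunity proportions (named).
#' @param affinity Non-negative ASV x host matrix of host-affinity
#'   weights (rows match `p`; columns named by host), or a single vector
#'   for a one-host group.
#' @param hosts Character vector, one host per sample, matching
#'   `colnames(affinity)`.
#' @param filter_strength Selection intensity >= 0.
#' @param depth Reads per sample.
#' @param colonization_prob Probability in (0, 1] that a taxon passing
#'   the host filter establishes on a given individual sample
#'   (default 1 = no individual-level filtering).
#' @param micro_sdlog Standard deviation (natural-log scale) of
#'   per-sample multiplicative lognormal noise on the established taxa's
#'   weights (default 0 = none). This models microsite and
#'   priority-effect stochasticity: a taxon can bloom in one root
#'   sample while staying rare in another.
#' @param dominance Exponent in (0, 1] compressing the established
#'   taxa's weights within a sample (default 1 = none). Values below 1
#'   emulate local density regulation on a finite pool of root tips:
#'   which taxa establish is set by the host filter and the
#'   colonization lottery, but established taxa converge toward more
#'   comparable biomass shares than their metacommunity weights imply.
#' @param seed Integer RNG seed.
#' @param sample_ids Optional sample names.
#' @return ASV count matrix (taxa x samples); columns sum to `depth`.
#' @export
simulate_niche_group <- function(p, affinity, hosts, filter_strength,
                                 depth, colonization_prob = 1,
                                 micro_sdlog = 0, dominance = 1,
                                 seed = 1L, sample_ids = NULL) {
  if (micro_sdlog < 0) stop("micro_sdlog must be >= 0")
  if (filter_strength < 0) stop("filter_strength must be >= 0")
  if (dominance <= 0 || dominance > 1)
    stop("dominance must be in (0, 1]")
  if (colonization_prob <= 0 || colonization_prob > 1)
    stop("colonization_prob must be in (0, 1]")
  if (is.null(dim(affinity))) {
    affinity <- matrix(affinity, ncol = 1L,
                       dimnames = list(names(p), hosts[1L]))
  }
  if (nrow(affinity) != length(p))
    stop("affinity must have one row per ASV")
  if (any(affinity < 0)) stop("affinity weights must be >= 0")
  bad <- setdiff(unique(hosts), colnames(affinity))
  if (length(bad))
    stop("hosts without an affinity column: ", paste(bad, collapse = ", "))
  set.seed(seed)
  counts <- vapply(seq_along(hosts), function(j) {
    w <- p * affinity[, hosts[j]]^filter_strength
    if (sum(w) <= 0) stop("all-zero sampling weights for host ", hosts[j])
    keep <- stats::rbinom(length(w), 1L,
                          ifelse(w > 0, colonization_prob, 0)) == 1L
    # never empty a sample: keep the best-adapted taxon
    keep[which.max(w)] <- TRUE
    wl <- ifelse(keep & w > 0, w^dominance, 0)
    if (micro_sdlog > 0)
      wl <- wl * stats::rlnorm(length(wl), 0, micro_sdlog)
    stats::rmultinom(1L, size = depth, prob = wl / sum(wl))[, 1L]
  }, numeric(length(p)))
  dimnames(counts) <- list(names(p),
                           sample_ids %||% paste0("S", seq_along(hosts)))
  storage.mode(counts) <- "integer"
  counts
}

#' Configuration for a synthetic study
#'
#' Bundles and validates the parameters of [generate_study()]. Defaults
#' reproduce the study design the simulator emulates: 6 tree species
#' (3 conifer, 3 broadleaf) x 2 developmental stages x 10 replicates =
#' 120 root samples at 23167 reads each, over a lognormal metacommunity
#' of 300 taxa, with juvenile communities assembled under host filtering
#' (niche regime) and adult communities under dispersal-structured
#' neutral sampling.
#'
#' @param n_species_per_type Tree species per host type (default 3).
#' @param n_replicates Replicates per species x stage (default 10).
#' @param depth Reads per sample (default 23167).
#' @param n_asvs Metacommunity richness (default 300).
#' @param meta_distribution `"lognormal"` or `"logseries"`.
#' @param meanlog,sdlog Lognormal shape (defaults 0, 2.5).
#' @param regime_by_stage Named character vector mapping each stage to
#'   `"neutral"` or `"niche"` (default: juvenile niche, adult neutral).
#' @param m_sim Migration parameter for neutral groups (default 0.5).
#' @param filter_strength Selection intensity for niche groups
#'   (default 2).
#' @param raw_depth Reads actually drawn per simulated sample; defaults
#'   to `ceiling(2 * depth)` so that samples still clear the
#'   rarefaction target `depth` after guild and low-count filtering, as
#'   raw sequencing depth exceeds the rarefaction depth in a real study.
#' @param host_compat_prob Probability an ASV is compatible with a given
#'   host species at all (default 0.25); incompatible pairs get affinity
#'   0, making host filtering heterogeneous across species.
#' @param affinity_sdlog Lognormal spread of affinity weights among
#'   compatible pairs (default 1).
#' @param colonization_prob Individual-level establishment probability
#'   for niche-regime samples (default 0.6): each root sample hosts an
#'   idiosyncratic subset of the host-compatible pool.
#' @param micro_sdlog Per-sample microsite noise for niche-regime
#'   samples (default 2.5; natural-log sd); see [simulate_niche_group()].
#' @param dominance Within-sample weight-compression exponent for
#'   niche-regime samples (default 0.15); see [simulate_niche_group()].
#' @param decoy_fraction Fraction of additional non-EcM taxa added to the
#'   pool so the guild filter is exercised (default 0.2).
#' @param decoy_mass_fraction Total metacommunity mass assigned to the
#'   non-EcM decoys (default 0.1): washed root-tip communities are
#'   dominated by the EcM guild, with saprotrophs and moulds present as
#'   a minor fraction of reads.
#' @param seed Integer RNG seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_species_per_type = 3L, n_replicates = 10L,
                             depth = 23167L, n_asvs = 300L,
                             meta_distribution = "lognormal",
                             meanlog = 0, sdlog = 2.5,
                             regime_by_stage = c(juvenile = "niche",
                                                 adult = "neutral"),
                             raw_depth = NULL,
                             m_sim = 0.5, filter_strength = 2,
                             host_compat_prob = 0.25,
                             affinity_sdlog = 1,
                             colonization_prob = 0.6,
                             micro_sdlog = 2.5, dominance = 0.15,
                             decoy_fraction = 0.2,
                             decoy_mass_fraction = 0.1, seed = 1L) {
  stopifnot(depth >= 1L, n_asvs >= 2L, n_species_per_type >= 1L,
            n_replicates >= 1L, m_sim > 0, m_sim <= 1,
            filter_strength >= 0, host_compat_prob > 0,
            host_compat_prob <= 1, decoy_fraction >= 0,
            decoy_fraction < 1)
  stopifnot(colonization_prob > 0, colonization_prob <= 1,
            micro_sdlog >= 0, dominance > 0, dominance <= 1,
            decoy_mass_fraction >= 0, decoy_mass_fraction < 1)
  if (is.null(raw_depth)) raw_depth <- as.integer(ceiling(2 * depth))
  if (raw_depth < depth) stop("raw_depth must be >= depth")
  if (!all(sort(names(regime_by_stage)) == c("adult", "juvenile")) ||
      !all(regime_by_stage %in% c("neutral", "niche")))
    stop("regime_by_stage must map 'juvenile' and 'adult' to 'neutral' or 'niche'")
  structure(as.list(environment()), class = "synthetic_config")
}

# genus pools used to label simulated taxa
.ecm_genera <- c("Russula", "Inocybe", "Tomentella", "Sebacina",
                 "Amphinema", "Cenococcum", "Tylospora", "Rhodoscypha",
                 "Lactarius", "Cortinarius", "Piloderma", "Wilcoxina")
.decoy_genera <- c("Mortierella", "Penicillium", "Trichoderma",
                   "Cladosporium", "Fusarium", "Umbelopsis")

#' Generate a complete synthetic study
#'
#' Produces an ASV table, sample metadata, taxonomy with guild
#' annotations, and a ground-truth ledger under the configured study
#' design. By default juvenile groups are assembled under the niche
#' regime (host-filtered) and adult groups under the neutral regime
#' (Dirichlet-multinomial dispersal coupling), so downstream model fits
#' have a known answer. A fraction of non-ectomycorrhizal decoy taxa is
#' mixed into the pool to exercise the guild filter.
#'
#' @param config A [synthetic_config()] object (defaults used if missing).
#' @return List with `counts` (ASV x sample matrix), `metadata`,
#'   `taxonomy` and `truth` (regime and parameters per group, the
#'   affinity matrix, metacommunity proportions, seed).
#' @export
generate_study <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n_total <- ceiling(cfg$n_asvs / (1 - cfg$decoy_fraction))
  p <- simulate_metacommunity(n_total, cfg$meta_distribution,
                              meanlog = cfg$meanlog, sdlog = cfg$sdlog,
                              seed = cfg$seed)
  conifers <- c("Abies_nephrolepis", "Picea_jezoensis",
                "Pinus_koraiensis")[seq_len(min(3L, cfg$n_species_per_type))]
  broadleaves <- c("Acer_mono", "Betula_platyphylla",
                   "Quercus_mongolica")[seq_len(min(3L, cfg$n_species_per_type))]
  if (cfg$n_species_per_type > 3L) {
    conifers <- c(conifers,
                  paste0("Conifer_sp", seq_len(cfg$n_species_per_type - 3L)))
    broadleaves <- c(broadleaves,
                     paste0("Broadleaf_sp", seq_len(cfg$n_species_per_type - 3L)))
  }
  species <- c(conifers, broadleaves)
  host_type <- rep(c("conifer", "broadleaf"), each = cfg$n_species_per_type)
  names(host_type) <- species

  set.seed(cfg$seed + 1L)
  # host-affinity weights: compatibility indicator x lognormal intensity
  affinity <- matrix(
    stats::rbinom(n_total * length(species), 1L, cfg$host_compat_prob) *
      stats::rlnorm(n_total * length(species), 0, cfg$affinity_sdlog),
    nrow = n_total, ncol = length(species),
    dimnames = list(names(p), species))
  # every taxon must be compatible with at least one host
  orphan <- rowSums(affinity) == 0
  if (any(orphan)) {
    j <- sample.int(length(species), sum(orphan), replace = TRUE)
    affinity[cbind(which(orphan), j)] <-
      stats::rlnorm(sum(orphan), 0, cfg$affinity_sdlog)
  }

  # taxonomy: EcM labels plus non-EcM decoys
  n_decoy <- n_total - cfg$n_asvs
  is_ecm <- rep(TRUE, n_total)
  if (n_decoy > 0L) {
    is_ecm[sample.int(n_total, n_decoy)] <- FALSE
    # pin the decoy guild's share of metacommunity mass
    p[!is_ecm] <- p[!is_ecm] / sum(p[!is_ecm]) * cfg$decoy_mass_fraction
    p[is_ecm] <- p[is_ecm] / sum(p[is_ecm]) * (1 - cfg$decoy_mass_fraction)
  }
  genus <- ifelse(is_ecm,
                  sample(.ecm_genera, n_total, replace = TRUE),
                  sample(.decoy_genera, n_total, replace = TRUE))
  taxonomy <- data.frame(
    asv_id = names(p),
    lineage = paste0("k__Fungi;p__;c__;o__;f__;g__", genus, ";s__"),
    genus = genus,
    is_ecm = is_ecm,
    stringsAsFactors = FALSE)

  stages <- c("juvenile", "adult")
  blocks <- list()
  meta <- list()
  truth_groups <- list()
  gseed <- cfg$seed
  for (st in stages) {
    for (sp in species) {
      gseed <- gseed + 1L
      ids <- sprintf("%s_%s_r%02d", abbreviate(sp, 6L), substr(st, 1L, 3L),
                     seq_len(cfg$n_replicates))
      regime <- cfg$regime_by_stage[[st]]
      counts <- if (regime == "neutral") {
        simulate_neutral_group(p, cfg$n_replicates, cfg$raw_depth,
                               cfg$m_sim, seed = gseed, sample_ids = ids)
      } else {
        simulate_niche_group(p, affinity, hosts = rep(sp, cfg$n_replicates),
                             filter_strength = cfg$filter_strength,
                             depth = cfg$raw_depth,
                             colonization_prob = cfg$colonization_prob,
                             micro_sdlog = cfg$micro_sdlog,
                             dominance = cfg$dominance,
                             seed = gseed, sample_ids = ids)
      }
      blocks[[length(blocks) + 1L]] <- counts
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = ids, host_species = sp,
        host_type = host_type[[sp]], stage = st,
        replicate = seq_len(cfg$n_replicates),
        stringsAsFactors = FALSE)
      truth_groups[[paste(host_type[[sp]], st, sp, sep = ".")]] <- list(
        regime = regime,
        m_sim = if (regime == "neutral") cfg$m_sim else NA_real_,
        filter_strength = if (regime == "niche") cfg$filter_strength
                          else NA_real_)
    }
  }
  counts <- do.call(cbind, blocks)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  list(
    counts = validate_asv_table(counts),
    metadata = metadata,
    taxonomy = taxonomy,
    truth = list(groups = truth_groups, affinity = affinity,
                 metacommunity = p, config = unclass(cfg)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
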