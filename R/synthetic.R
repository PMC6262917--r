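#' Default trait vocabulary for the synthetic species pool
#'
#' Levels for the three categorical functional traits: larval host-plant
#' preference, larval specialism (single vs multiple host families) and
#' overwintering stage (`"N/A"` covering species without a fixed
#' overwintering stage, e.g. migrants).
#'
#' @return named list of character level vectors.
#' @export
default_trait_vocab <- function() {
  list(
    host_plant = c("grasses", "herbs", "trees", "shrubs",
                   "lichens_detritus", "mixed"),
    larval_specialism = c("single_family", "multi_family"),
    overwintering_stage = c("egg", "larva", "pupa/cocoon", "adult", "N/A"))
}

#' Configuration of a synthetic paired-community study
#'
#' Defines the study conditions emulated by the generator: 13 pairs of
#' broadleaf / plantation sites surveyed across 2 years and 3 months, a
#' regional species pool with a long-tailed (log-series) abundance
#' distribution, per-site richness around 63 species in broadleaf and 27 in
#' plantation, plantation communities drawn as common-species-biased subsets
#' of their broadleaf pair, and (`trait_sharing`) rare species whose trait
#' profiles duplicate those of common species - so that naive richness
#' differs strongly between habitats while functionally constrained
#' diversity does not.
#'
#' @param n_pairs number of site pairs (default 13; 26 sites).
#' @param pool_size regional species pool size.
#' @param mean_richness_broadleaf,mean_richness_plantation target mean
#'   per-site species richness (defaults 63 and 27).
#' @param sd_richness_broadleaf,sd_richness_plantation site-level SD of
#'   richness around the pair expectation (defaults 3 and 5).
#' @param pair_effect_sd SD (log scale) of a pair-level richness effect
#'   shared by both sites of a pair, emulating between-pair landscape
#'   variation; this is what the pair-within-year / pair-within-month
#'   random intercepts of the habitat models absorb. Mean-corrected so
#'   realized mean richness stays on target.
#' @param abundance_model `"log-series"` (classic for light-trap moth
#'   samples) or `"lognormal"`.
#' @param trait_sharing probability in \[0,1\] that a rare species duplicates
#'   the trait profile of a randomly chosen common species (default 1).
#' @param habitat_effect_on_traits filter strength in \[0, 1\]; the
#'   selection weight of species in the filtered host-plant class
#'   (`"lichens_detritus"`) is multiplied by `1 - strength` when drawing
#'   plantation communities, so 0 means no trait filtering and 1 complete
#'   exclusion (a positive control for environmental-filtering detection).
#' @param common_bias exponent applied to pool abundance when drawing
#'   plantation subsets; larger values bias harder toward common species.
#' @param mean_site_total expected number of individuals caught per site
#'   beyond the one-per-present-species minimum.
#' @param n_families,n_genera taxonomy dimensions.
#' @param seed integer RNG seed for the whole study.
#' @return a `study_config` list.
#' @export
study_config <- function(n_pairs = 13, pool_size = 150,
                         mean_richness_broadleaf = 63,
                         mean_richness_plantation = 27,
                         sd_richness_broadleaf = 3,
                         sd_richness_plantation = 5,
                         pair_effect_sd = 0.15,
                         abundance_model = c("log-series", "lognormal"),
                         trait_sharing = 1,
                         habitat_effect_on_traits = 0,
                         common_bias = 4,
                         mean_site_total = 350,
                         n_families = 18, n_genera = 60,
                         seed = 1) {
  abundance_model <- match.arg(abundance_model)
  cfg <- list(n_pairs = n_pairs, pool_size = pool_size,
              mean_richness_broadleaf = mean_richness_broadleaf,
              mean_richness_plantation = mean_richness_plantation,
              sd_richness_broadleaf = sd_richness_broadleaf,
              sd_richness_plantation = sd_richness_plantation,
              pair_effect_sd = pair_effect_sd,
              abundance_model = abundance_model,
              trait_sharing = trait_sharing,
              habitat_effect_on_traits = habitat_effect_on_traits,
              common_bias = common_bias,
              mean_site_total = mean_site_total,
              n_families = n_families, n_genera = n_genera, seed = seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_pairs < 0) stop("n_pairs must be >= 0")
  if (cfg$mean_richness_broadleaf > cfg$pool_size ||
      cfg$mean_richness_plantation > cfg$pool_size)
    stop("mean richness cannot exceed pool size")
  if (cfg$trait_sharing < 0 || cfg$trait_sharing > 1)
    stop("trait_sharing must be a probability in [0, 1]")
  if (cfg$habitat_effect_on_traits < 0)
    stop("habitat_effect_on_traits must be >= 0")
  invisible(cfg)
}

# Fisher log-series abundance sample: P(k) proportional to x^k / k.
rlogseries <- function(n, x = 0.995, kmax = 100000L) {
  k <- seq_len(kmax)
  pk <- x^k / k
  sample.int(kmax, n, replace = TRUE, prob = pk)
}

#' Generate a synthetic species pool
#'
#' Samples a hierarchical taxonomy (species within genera within families,
#' every family and genus guaranteed non-empty), categorical trait values
#' from the trait vocabulary, wingspans from a log-normal, and a global
#' abundance rank for every species from the configured abundance model.
#'
#' @param pool_size number of species.
#' @param n_families,n_genera taxonomy dimensions
#'   (`n_families <= n_genera <= pool_size`).
#' @param trait_vocab named list of categorical trait levels; default
#'   [default_trait_vocab()].
#' @param wingspan_meanlog,wingspan_sdlog log-normal wingspan parameters
#'   (mm; defaults give a median of about 32 mm).
#' @param abundance_model `"log-series"` or `"lognormal"`.
#' @param core_size when positive, the `core_size` most abundant species
#'   receive a balanced allocation of the categorical trait levels (each
#'   level equally represented, order randomized) instead of a uniform
#'   draw. This emulates a regional pool whose common core spans the whole
#'   functional-role space - the structure under which species loss removes
#'   redundancy rather than roles. The rarer tail is always sampled
#'   uniformly.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return list with `traits`, `taxonomy` and `abundance` (global pool
#'   abundances, unsorted, named by species).
#' @export
generate_species_pool <- function(pool_size, n_families = 18, n_genera = 60,
                                  trait_vocab = default_trait_vocab(),
                                  wingspan_meanlog = log(32),
                                  wingspan_sdlog = 0.3,
                                  abundance_model = "log-series",
                                  core_size = 0, seed = NULL) {
  if (!(n_families <= n_genera && n_genera <= pool_size))
    stop("need n_families <= n_genera <= pool_size")
  if (!is.null(seed)) set.seed(seed)
  sp <- sprintf("sp%03d", seq_len(pool_size))
  fam <- sprintf("Fam%02d", seq_len(n_families))
  gen <- sprintf("Gen%03d", seq_len(n_genera))
  # guarantee coverage: first assignments cycle through all parents
  gen_fam <- fam[c(seq_len(n_families),
                   sample.int(n_families, n_genera - n_families, replace = TRUE))]
  sp_gen <- gen[c(seq_len(n_genera),
                  sample.int(n_genera, pool_size - n_genera, replace = TRUE))]
  taxonomy <- data.frame(species = sp, genus = sp_gen,
                         family = gen_fam[match(sp_gen, gen)])
  traits <- data.frame(
    species = sp,
    host_plant = sample(trait_vocab$host_plant, pool_size, replace = TRUE),
    larval_specialism = sample(trait_vocab$larval_specialism, pool_size,
                               replace = TRUE),
    overwintering_stage = sample(trait_vocab$overwintering_stage, pool_size,
                                 replace = TRUE),
    wingspan = round(stats::rlnorm(pool_size, wingspan_meanlog, wingspan_sdlog), 1))
  a <- if (abundance_model == "lognormal")
    ceiling(stats::rlnorm(pool_size, meanlog = 2, sdlog = 1.3))
  else rlogseries(pool_size)
  # most abundant species first, so low indices are the "common" species
  ord <- order(a, decreasing = TRUE)
  traits <- traits[ord, , drop = FALSE]
  taxonomy <- taxonomy[ord, , drop = FALSE]
  rownames(traits) <- rownames(taxonomy) <- NULL
  core <- min(core_size, pool_size)
  if (core > 0) {
    for (tn in names(trait_vocab))
      traits[[tn]][seq_len(core)] <-
        sample(rep(trait_vocab[[tn]], length.out = core))
  }
  list(traits = traits, taxonomy = taxonomy,
       abundance = stats::setNames(a[ord], sp[ord]))
}

apply_trait_sharing <- function(pool, n_common, trait_sharing) {
  if (trait_sharing <= 0) return(pool)
  tr <- pool$traits
  n <- nrow(tr)
  if (n_common >= n) return(pool)
  rare <- seq.int(n_common + 1L, n)
  copy <- rare[stats::runif(length(rare)) < trait_sharing]
  donors <- sample.int(n_common, length(copy), replace = TRUE)
  tr[copy, c("host_plant", "larval_specialism", "overwintering_stage")] <-
    tr[donors, c("host_plant", "larval_specialism", "overwintering_stage")]
  # wingspan duplicated with slight measurement-scale jitter to stay realistic
  tr$wingspan[copy] <- round(tr$wingspan[donors] *
                               exp(stats::rnorm(length(copy), 0, 0.03)), 1)
  pool$traits <- tr
  pool
}

#' Generate the paired broadleaf / plantation communities
#'
#' For each pair, the broadleaf site draws its richness from
#' `Normal(mean_richness_broadleaf, sd)` and selects that many species from
#' the pool with probability proportional to global abundance; the
#' plantation site draws a smaller richness and selects a subset of the
#' broadleaf site's species with probability proportional to
#' `abundance^common_bias`, so plantations are rarity-depleted subsets.
#' With `habitat_effect_on_traits > 0`, species of the filtered host-plant
#' class (`"lichens"`) are additionally down-weighted in plantations,
#' creating a genuine environmental-filtering signal. Counts are one
#' individual per present species plus a multinomial draw of the site total
#' with abundance-proportional expectations. Pairs are spread over 2 years
#' and 3 months.
#'
#' @param config a [study_config()].
#' @param pool a species pool from [generate_species_pool()].
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return abundance table (see [validate_abundance()]); zero rows when
#'   `n_pairs = 0`.
#' @export
generate_paired_communities <- function(config, pool, seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) set.seed(seed)
  sp <- pool$traits$species
  S <- length(sp)
  if (config$mean_richness_broadleaf > S)
    stop("requested richness exceeds pool size")
  a <- as.numeric(pool$abundance[sp])
  filtered <- pool$traits$host_plant == "lichens_detritus"
  rows <- list()
  n <- config$n_pairs
  years <- rep(c(2014L, 2015L), length.out = max(n, 1))
  months <- rep(6:8, length.out = max(n, 1))
  draw_richness <- function(mu, sd, lo, hi) {
    r <- round(stats::rnorm(1, mu, sd))
    min(max(r, lo), hi)
  }
  pe_sd <- if (is.null(config$pair_effect_sd)) 0 else config$pair_effect_sd
  for (k in seq_len(n)) {
    # pair-level landscape effect, shared by both sites of the pair
    u <- exp(stats::rnorm(1, 0, pe_sd) - pe_sd^2 / 2)
    Rb <- draw_richness(u * config$mean_richness_broadleaf,
                        config$sd_richness_broadleaf, 5, S)
    sel_b <- sample.int(S, Rb, prob = a)
    # filter strength scales the selection weight of the filtered
    # host-plant class directly (1 = complete exclusion): a bounded
    # multiplier on top of the common-bias power would otherwise be
    # swamped by the abundance spread
    w_p <- a[sel_b]^config$common_bias *
      pmax(0, 1 - config$habitat_effect_on_traits * filtered[sel_b])
    Rp <- draw_richness(u * config$mean_richness_plantation,
                        config$sd_richness_plantation, 2, Rb)
    Rp <- min(Rp, sum(w_p > 0))
    sel_p <- sel_b[sample.int(Rb, Rp, prob = w_p)]
    make_counts <- function(sel) {
      extra <- stats::rmultinom(1, stats::rpois(1, config$mean_site_total),
                                prob = a[sel])[, 1]
      counts <- integer(S)
      counts[sel] <- 1L + extra
      counts
    }
    for (hab in c("broadleaf", "plantation")) {
      sel <- if (hab == "broadleaf") sel_b else sel_p
      cts <- make_counts(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sprintf("pair%02d_%s", k, substr(hab, 1, 1)),
        pair_id = sprintf("pair%02d", k), habitat = hab,
        year = years[k], month = months[k],
        as.list(stats::setNames(cts, sp)), check.names = FALSE)
    }
  }
  if (!length(rows)) {
    out <- data.frame(site_id = character(0), pair_id = character(0),
                      habitat = character(0), year = integer(0),
                      month = integer(0))
    for (s in sp) out[[s]] <- integer(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_abundance(out)
  out
}

#' Generate a complete synthetic study
#'
#' One call produces the abundance, trait and taxonomy tables for the
#' configured paired study, ready for the full pipeline. All randomness
#' flows from `config$seed`: the pool is generated first, trait sharing
#' applied (rare species duplicating common species' trait profiles), then
#' the paired communities, all on one seeded RNG stream, so identical
#' configurations give identical data.
#'
#' @param config a [study_config()].
#' @return list of class `synthetic_study`: `abundance`, `traits`,
#'   `taxonomy`, `pool_abundance`, `config`.
#' @export
generate_study <- function(config = study_config()) {
  validate_config(config)
  set.seed(config$seed)
  pool <- generate_species_pool(config$pool_size, config$n_families,
                                config$n_genera,
                                abundance_model = config$abundance_model,
                                core_size = config$mean_richness_plantation)
  pool <- apply_trait_sharing(pool, config$mean_richness_plantation,
                              config$trait_sharing)
  abundance <- generate_paired_communities(config, pool)
  out <- list(abundance = abundance, traits = pool$traits,
              taxonomy = pool$taxonomy, pool_abundance = pool$abundance,
              config = config)
  class(out) <- "synthetic_study"
  out
}

#' Write a synthetic study's tables to a directory
#'
#' Writes `abundance.csv`, `traits.csv`, `taxonomy.csv` and a
#' `provenance.json` record of the generating configuration.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(study$abundance, file.path(dir, "abundance.csv"))
  write_traits(study$traits, file.path(dir, "traits.csv"))
  write_taxonomy(study$taxonomy, file.path(dir, "taxonomy.csv"))
  prov <- c(list(generator = "simdiv", version = "0.1.0"), study$config)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    writeLines(paste(names(prov), vapply(prov, as.character, ""), sep = "="),
               file.path(dir, "provenance.json"))
  }
  invisible(dir)
}
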