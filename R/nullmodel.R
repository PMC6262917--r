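#' Permute abundances within each site
#'
#' The null model shuffles the abundance values across species independently
#' within each site (row), which breaks the association between abundance
#' and species identity - and hence between abundance and traits - while
#' preserving each site's total catch, its richness, and the multiset of its
#' counts. Trait and taxonomy tables are untouched.
#'
#' The alternative reading of the randomisation, shuffling entire trait
#' profiles across the species pool, is available as
#' `scheme = "shuffle_traits"` applied to a trait table via
#' [shuffle_trait_rows()].
#'
#' @param abundance abundance table.
#' @param seed optional integer; when given, seeds the RNG before
#'   permuting. When `NULL` the current RNG stream is used.
#' @return abundance table with each site's counts shuffled across species.
#' @export
permute_site_abundances <- function(abundance, seed = NULL) {
  validate_abundance(abundance)
  if (!is.null(seed)) set.seed(seed)
  counts <- abundance_matrix(abundance)
  sp_cols <- colnames(counts)
  for (i in seq_len(nrow(counts)))
    counts[i, ] <- counts[i, sample.int(ncol(counts))]
  out <- abundance
  out[, sp_cols] <- counts
  out
}

#' Shuffle trait profiles across the species pool
#'
#' @param traits trait table.
#' @param seed optional RNG seed.
#' @return trait table with rows of trait values reassigned to species.
#' @export
shuffle_trait_rows <- function(traits, seed = NULL) {
  validate_traits(traits)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample(nrow(traits))
  out <- traits
  out[, FUNCTIONAL_TRAITS] <- traits[idx, FUNCTIONAL_TRAITS]
  out
}

#' Standardized effect size against a null distribution
#'
#' `SES = (observed - mean(null)) / sd(null)`. Negative values mean the
#' observed diversity is lower than expected under random assembly
#' (environmental filtering); positive values suggest niche
#' complementarity.
#'
#' @param observed observed statistic.
#' @param null_values numeric vector of the statistic under the null model.
#' @return list: `observed`, `null_mean`, `null_sd`, `ses`, `n_perm`.
#' @export
ses <- function(observed, null_values) {
  if (length(null_values) < 2L)
    stop("need at least 2 null values")
  m <- mean(null_values)
  s <- stats::sd(null_values)
  # treat numerically-constant nulls as degenerate too
  if (s <= 1e-12 * (abs(m) + 1))
    stop("degenerate null distribution (sd = 0); SES undefined")
  list(observed = observed, null_mean = m, null_sd = s,
       ses = (observed - m) / s, n_perm = length(null_values))
}

# Vectorised similarity-sensitive diversity over the columns of a
# relative-abundance matrix P (species x n). Zero entries contribute nothing
# for q >= 0, so computing ordinariness over the full species set equals the
# subcommunity computation with Z subset to nonzero species.
diversity_columns <- function(P, Z, q) {
  M <- Z %*% P
  nz <- P > 0
  if (q == 1) {
    term <- ifelse(nz, P * log(ifelse(nz, M, 1)), 0)
    return(exp(-colSums(term)))
  }
  term <- ifelse(nz, P * ifelse(nz, M, 1)^(q - 1), 0)
  colSums(term)^(1 / (1 - q))
}

#' Permutation null-model test for similarity-constrained diversity
#'
#' For each site, computes the observed similarity-sensitive diversity of
#' order `q` under `Z` and its standardized effect size against `n_perm`
#' within-site abundance shuffles (see [permute_site_abundances()]). Each
#' permutation re-derives relative abundances from the shuffled counts, so
#' the set of species carrying nonzero abundance (and hence the effective
#' subcommunity) changes from draw to draw while richness is preserved.
#'
#' @param abundance abundance table.
#' @param Z similarity matrix covering all species columns.
#' @param q order of diversity (default 0, constrained richness).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed; the permutation stream is fully reproducible
#'   from it.
#' @param constraint label stored in the output (for bookkeeping).
#' @return data frame: `site_id`, `habitat`, `constraint`, `q`, `observed`,
#'   `null_mean`, `null_sd`, `ses`, `n_perm`.
#' @export
null_model_test <- function(abundance, Z, q = 0, n_perm = 999, seed = NULL,
                            constraint = "functional") {
  validate_abundance(abundance)
  check_order(q)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  counts <- abundance_matrix(abundance)
  Z <- Z[colnames(counts), colnames(counts), drop = FALSE]
  validate_similarity(Z)
  meta <- abundance_meta(abundance)
  res <- vector("list", nrow(counts))
  for (i in seq_len(nrow(counts))) {
    x <- counts[i, ]
    if (all(x == 0)) stop("site '", meta$site_id[i], "' has no individuals")
    p_obs <- x / sum(x)
    obs <- diversity_columns(matrix(p_obs, ncol = 1), Z, q)
    P <- vapply(seq_len(n_perm), function(k) x[sample.int(length(x))],
                numeric(length(x)))
    P <- sweep(P, 2, colSums(P), "/")
    nulls <- diversity_columns(P, Z, q)
    s <- ses(obs, nulls)
    res[[i]] <- data.frame(
      site_id = meta$site_id[i], habitat = meta$habitat[i],
      constraint = constraint, q = q, observed = s$observed,
      null_mean = s$null_mean, null_sd = s$null_sd, ses = s$ses,
      n_perm = s$n_perm)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Habitat-level test of mean SES against zero
#'
#' Within each habitat, fits the no-intercept linear model of the SES values
#' on a constant - equivalent to a one-sample t-test of mean SES = 0 with
#' `n - 1` degrees of freedom. A habitat whose SES values have zero spread
#' yields a degenerate (flagged) result rather than a p-value.
#'
#' @param ses_values numeric SES values, one per site.
#' @param habitat habitat label per value.
#' @return data frame: `habitat`, `n`, `mean_ses`, `se_ses`, `t`, `p_value`,
#'   `degenerate`.
#' @export
habitat_ses_test <- function(ses_values, habitat) {
  habitat <- as.character(habitat)
  if (length(ses_values) != length(habitat))
    stop("ses_values and habitat must have equal length")
  habs <- unique(habitat)
  out <- lapply(habs, function(h) {
    v <- ses_values[habitat == h]
    n <- length(v)
    if (n < 2L) stop("habitat '", h, "' has fewer than 2 sites")
    m <- mean(v)
    se <- stats::sd(v) / sqrt(n)
    if (se == 0) {
      return(data.frame(habitat = h, n = n, mean_ses = m, se_ses = 0,
                        t = NA_real_, p_value = if (m == 0) 1 else NA_real_,
                        degenerate = TRUE))
    }
    tval <- m / se
    data.frame(habitat = h, n = n, mean_ses = m, se_ses = se, t = tval,
               p_value = 2 * stats::pt(-abs(tval), df = n - 1),
               degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
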