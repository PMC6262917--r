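#' Weighted power mean
#'
#' Computes the weighted power mean of order `t`:
#' `(sum w_i x_i^t)^(1/t)` for `t != 0`, the weighted geometric mean
#' `prod x_i^(w_i)` at `t = 0` (its analytic limit), the weighted minimum at
#' `t = -Inf` and the weighted maximum at `t = +Inf`. Pairs with zero weight
#' are excluded before any check, so values paired with zero weight may be
#' arbitrary.
#'
#' @param values positive numeric vector.
#' @param order scalar order `t` (may be `-Inf` or `Inf`).
#' @param weights non-negative weights summing to 1.
#' @return scalar power mean.
#' @export
power_mean <- function(values, order, weights) {
  if (length(values) != length(weights))
    stop("values and weights must have equal length")
  if (any(weights < 0))
    stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1")
  keep <- weights > 0
  x <- values[keep]
  w <- weights[keep]
  if (any(!is.finite(x)) || any(x <= 0))
    stop("values must be positive and finite wherever weights are nonzero")
  w <- w / sum(w)
  if (is.infinite(order))
    return(if (order > 0) max(x) else min(x))
  if (order == 0)
    return(exp(sum(w * log(x))))
  sum(w * x^order)^(1 / order)
}

#' Relative abundance of a community
#'
#' Drops zero-count species and normalises the remainder to proportions
#' summing to 1, preserving species order. Species names are preserved when
#' present.
#'
#' @param counts non-negative numeric vector of abundances, at least one
#'   positive.
#' @return named numeric vector of proportions over the retained species.
#' @export
relative_abundance <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative and non-missing")
  if (all(counts == 0))
    stop("community has no individuals (all counts zero)")
  p <- counts[counts > 0]
  p / sum(p)
}

#' Naive Hill diversity
#'
#' Effective number of species of order `q` treating all species as
#' completely distinct: `(sum p_i^q)^(1/(1-q))` for `q != 1` and
#' `exp(-sum p_i log p_i)` at `q = 1` (the analytic limit). `q = 0, 1, 2`
#' give species richness, exponential Shannon and inverse Simpson diversity.
#'
#' @param p relative abundances (see [relative_abundance()]); zeros dropped.
#' @param q order, `q >= 0`.
#' @return effective number of species.
#' @export
naive_diversity <- function(p, q) {
  check_order(q)
  p <- drop_zeros(p)
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

check_order <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("order q must be a single number >= 0")
  invisible(q)
}

drop_zeros <- function(p) {
  if (anyNA(p) || any(p < 0)) stop("relative abundances must be non-negative")
  p <- p[p > 0]
  if (length(p) == 0L) stop("empty community")
  if (abs(sum(p) - 1) > 1e-9) stop("relative abundances must sum to 1")
  p
}

#' Similarity-sensitive diversity
#'
#' Effective number of species of order `q` under a similarity matrix `Z`:
#' the `(1-q)`th-order power mean of the species' ordinariness `(Zp)_i`
#' reciprocals, weighted by `p`. With `Z` the identity this reduces to the
#' naive Hill number; with `Z` all ones every community has diversity 1.
#'
#' Implemented through [power_mean()], so the `q = 1` case is the analytic
#' geometric-mean limit, never a numeric approximation.
#'
#' @param p relative abundances, named by species when `Z` is larger than
#'   the community (the matrix is subset to the species of `p`).
#' @param Z similarity matrix covering the species of `p`.
#' @param q order, `q >= 0`.
#' @return effective number of species, between 1 and `length(p)`.
#' @export
similarity_diversity <- function(p, Z, q) {
  check_order(q)
  p <- drop_zeros(p)
  Z <- align_similarity(Z, p)
  zp <- as.vector(Z %*% p)
  if (any(zp <= 0))
    stop("non-positive ordinariness (Zp) encountered")
  power_mean(1 / zp, 1 - q, p)
}

align_similarity <- function(Z, p) {
  validate_similarity(Z)
  ids <- names(p)
  if (is.null(ids)) {
    if (nrow(Z) != length(p))
      stop("similarity matrix dimension does not match community size")
    return(Z)
  }
  if (!all(ids %in% rownames(Z)))
    stop("similarity matrix is missing species present in the community")
  Z[ids, ids, drop = FALSE]
}

#' Diversity profile
#'
#' Evaluates (similarity-sensitive) diversity over a grid of orders `q`,
#' producing the profile whose shape shows how diversity shifts as weight
#' moves from rare to common species. Profiles are non-increasing in `q`.
#'
#' @param p relative abundances.
#' @param Z similarity matrix; defaults to naive (identity).
#' @param q_grid non-negative orders, sorted ascending; default `c(0, 1, 2)`.
#' @return data frame with columns `q` and `effective_number`.
#' @export
diversity_profile <- function(p, Z = NULL, q_grid = c(0, 1, 2)) {
  if (length(q_grid) == 0L)
    return(data.frame(q = numeric(0), effective_number = numeric(0)))
  if (is.unsorted(q_grid)) stop("q_grid must be sorted ascending")
  p <- drop_zeros(p)
  if (is.null(Z))
    Z <- identity_similarity(if (is.null(names(p))) paste0("sp", seq_along(p))
                             else names(p))
  d <- vapply(q_grid, function(q) similarity_diversity(p, Z, q), numeric(1))
  data.frame(q = q_grid, effective_number = d)
}

#' Functional (or taxonomic) redundancy
#'
#' Ratio of naive species richness (effective number at `q = 0` with the
#' identity matrix) to similarity-constrained richness (`q = 0` under `Z`).
#' Values of 1 mean every species occupies its own functional role; larger
#' values mean several species share each effective role.
#'
#' @param counts community abundances (zeros allowed and dropped).
#' @param Z similarity matrix covering the species of `counts`.
#' @return list with `naive_richness`, `constrained_richness`, `redundancy`.
#' @export
redundancy <- function(counts, Z) {
  p <- relative_abundance(counts)
  naive <- naive_diversity(p, 0)
  constrained <- similarity_diversity(p, Z, 0)
  list(naive_richness = naive,
       constrained_richness = constrained,
       redundancy = naive / constrained)
}

#' Per-site diversity table
#'
#' Computes the diversity of every site in an abundance table under every
#' requested constraint and order, using the site's subcommunity (species
#' with nonzero count there) with the similarity matrix subset accordingly.
#'
#' @param abundance abundance table (see [read_abundance()]).
#' @param Zs named list of similarity matrices, e.g. from [similarity_set()].
#' @param q_grid orders to evaluate; default `c(0, 1, 2)`.
#' @return long data frame: `site_id`, `pair_id`, `habitat`, `constraint`,
#'   `q`, `effective_number`.
#' @export
site_diversity <- function(abundance, Zs, q_grid = c(0, 1, 2)) {
  counts <- abundance_matrix(abundance)
  meta <- abundance_meta(abundance)
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    p <- relative_abundance(counts[i, ])
    for (cn in names(Zs)) {
      prof <- diversity_profile(p, Zs[[cn]], q_grid)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = meta$site_id[i], pair_id = meta$pair_id[i],
        habitat = meta$habitat[i], constraint = cn,
        q = prof$q, effective_number = prof$effective_number)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-site redundancy table
#'
#' @param abundance abundance table.
#' @param Zs named list of similarity matrices (the naive entry, if present,
#'   is skipped: its redundancy is identically 1).
#' @return data frame: `site_id`, `pair_id`, `habitat`, `constraint`,
#'   `naive_richness`, `constrained_richness`, `redundancy`.
#' @export
site_redundancy <- function(abundance, Zs) {
  counts <- abundance_matrix(abundance)
  meta <- abundance_meta(abundance)
  cons <- setdiff(names(Zs), "naive")
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    for (cn in cons) {
      r <- redundancy(counts[i, ], Zs[[cn]])
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = meta$site_id[i], pair_id = meta$pair_id[i],
        habitat = meta$habitat[i], constraint = cn,
        naive_richness = r$naive_richness,
        constrained_richness = r$constrained_richness,
        redundancy = r$redundancy)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
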