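#' Validate a species similarity matrix
#'
#' Checks the defining properties of a similarity matrix Z used by the
#' similarity-sensitive diversity measures: square, symmetric, all entries in
#' \[0, 1\], diagonal exactly 1, and row/column names present and matching.
#'
#' @param Z numeric matrix to validate.
#' @param tol numeric tolerance for symmetry and range checks.
#' @return `Z`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_similarity <- function(Z, tol = 1e-8) {
  if (!is.matrix(Z) || !is.numeric(Z))
    stop("similarity matrix must be a numeric matrix")
  if (nrow(Z) != ncol(Z))
    stop("similarity matrix must be square")
  ids <- rownames(Z)
  if (is.null(ids) || is.null(colnames(Z)) || !identical(ids, colnames(Z)))
    stop("similarity matrix must carry identical species ids as row and column names")
  if (anyDuplicated(ids))
    stop("duplicate species ids in similarity matrix")
  if (anyNA(Z))
    stop("similarity matrix contains NA")
  if (max(abs(Z - t(Z))) > tol)
    stop("similarity matrix is not symmetric")
  if (min(Z) < -tol || max(Z) > 1 + tol)
    stop("similarity entries must lie in [0, 1]")
  if (max(abs(diag(Z) - 1)) > tol)
    stop("similarity matrix diagonal must be 1")
  invisible(Z)
}

new_similarity <- function(Z, species_ids) {
  dimnames(Z) <- list(species_ids, species_ids)
  # clip tiny numeric excursions before validating
  Z[Z < 0] <- 0
  Z[Z > 1] <- 1
  Z <- (Z + t(Z)) / 2
  diag(Z) <- 1
  validate_similarity(Z)
  Z
}

check_species_ids <- function(species_ids) {
  if (length(species_ids) == 0L)
    stop("species_ids must be non-empty")
  species_ids <- as.character(species_ids)
  if (anyNA(species_ids) || anyDuplicated(species_ids))
    stop("species_ids must be unique and non-missing")
  species_ids
}

#' Naive (identity) similarity matrix
#'
#' All species are treated as completely distinct: the identity matrix.
#' Diversity computed against this matrix reduces to the classical Hill
#' numbers, i.e. the "naive" measures.
#'
#' @param species_ids character vector of unique species identifiers.
#' @return An S x S identity matrix with species ids as dimnames.
#' @export
#' @examples
#' identity_similarity(c("sp1", "sp2", "sp3"))
identity_similarity <- function(species_ids) {
  species_ids <- check_species_ids(species_ids)
  new_similarity(diag(length(species_ids)), species_ids)
}

mean_impute_pairs <- function(Z, miss) {
  # pairs involving a species with a missing trait value get the mean
  # similarity of all fully observed off-diagonal pairs
  ok <- !miss
  if (sum(ok) < 2L)
    stop("too few species with observed trait values to impute missing pairs")
  obs <- Z[ok, ok, drop = FALSE]
  fill <- mean(obs[upper.tri(obs)])
  if (is.nan(fill)) fill <- 1   # single observed pair edge case handled above
  Z[miss, ] <- fill
  Z[, miss] <- fill
  attr(Z, "imputed") <- sum(miss)
  Z
}

#' Similarity matrix for a single categorical trait
#'
#' Single-trait Gower similarity for a categorical trait: 1 when two species
#' share the trait value, 0 otherwise (similarity = 1 - Gower mismatch
#' distance). Pairs where either value is missing receive the mean similarity
#' of all fully observed pairs; the number of affected species is recorded in
#' the `"imputed"` attribute.
#'
#' @param values vector of trait values, one per species; `NA` allowed.
#' @param species_ids species identifiers; defaults to `names(values)` or
#'   `sp1..spS`.
#' @return An S x S similarity matrix.
#' @export
categorical_trait_similarity <- function(values, species_ids = NULL) {
  if (is.null(species_ids))
    species_ids <- if (!is.null(names(values))) names(values) else
      paste0("sp", seq_along(values))
  species_ids <- check_species_ids(species_ids)
  if (length(values) != length(species_ids))
    stop("one trait value required per species")
  values <- as.character(values)
  miss <- is.na(values) | values == ""
  if (all(miss))
    stop("all trait values are missing")
  v <- values
  v[miss] <- NA
  Z <- outer(v, v, function(a, b) as.numeric(a == b))
  imputed <- 0L
  if (any(miss)) {
    Z[is.na(Z)] <- 0
    Z <- mean_impute_pairs(Z, miss)
    imputed <- attr(Z, "imputed")
  }
  out <- new_similarity(Z, species_ids)
  if (imputed > 0) attr(out, "imputed") <- imputed
  out
}

#' Similarity matrix for a single continuous trait
#'
#' Single-trait Gower similarity for a continuous trait:
#' `Z_ij = 1 - |x_i - x_j| / (max - min)`. Requires at least two distinct
#' finite values (a zero range leaves the formula undefined). Missing values
#' are handled by the same mean-of-observed-pairs rule as categorical traits.
#'
#' @param values numeric trait values, one per species; `NA` allowed.
#' @param species_ids species identifiers; defaults as in
#'   [categorical_trait_similarity()].
#' @return An S x S similarity matrix.
#' @export
continuous_trait_similarity <- function(values, species_ids = NULL) {
  if (is.null(species_ids))
    species_ids <- if (!is.null(names(values))) names(values) else
      paste0("sp", seq_along(values))
  species_ids <- check_species_ids(species_ids)
  if (length(values) != length(species_ids))
    stop("one trait value required per species")
  values <- as.numeric(values)
  miss <- !is.finite(values)
  if (all(miss))
    stop("all trait values are missing")
  obs <- values[!miss]
  rng <- max(obs) - min(obs)
  if (rng <= 0)
    stop("zero trait range: similarity undefined for a constant continuous trait")
  Z <- 1 - abs(outer(values, values, "-")) / rng
  imputed <- 0L
  if (any(miss)) {
    Z[is.na(Z)] <- 0
    Z <- mean_impute_pairs(Z, miss)
    imputed <- attr(Z, "imputed")
  }
  out <- new_similarity(Z, species_ids)
  if (imputed > 0) attr(out, "imputed") <- imputed
  out
}

#' Taxonomic similarity matrix
#'
#' Builds pairwise similarity from a ranked lineage (species, genus, family)
#' with equal step lengths per rank, normalised so that the maximum distance
#' is 1: conspecifics 1, congeners 2/3, confamilials 1/3, different families
#' 0. Species sharing a genus or family are therefore more similar than
#' species in different families.
#'
#' @param taxonomy data frame with columns `species`, `genus`, `family`
#'   (one row per species, complete lineage).
#' @return An S x S similarity matrix over `taxonomy$species`.
#' @export
taxonomic_similarity <- function(taxonomy) {
  need <- c("species", "genus", "family")
  if (!all(need %in% names(taxonomy)))
    stop("taxonomy must have columns species, genus, family")
  tx <- as.data.frame(taxonomy)[, need]
  for (cc in need) tx[[cc]] <- as.character(tx[[cc]])
  if (anyNA(tx) || any(tx == ""))
    stop("every species must have a complete (species, genus, family) lineage")
  ids <- check_species_ids(tx$species)
  g2f <- unique(tx[, c("genus", "family")])
  if (anyDuplicated(g2f$genus))
    stop("a genus maps to more than one family")
  same_genus  <- outer(tx$genus,  tx$genus,  "==")
  same_family <- outer(tx$family, tx$family, "==")
  # equal-step distances over 3 ranks, scaled to [0, 1]
  d <- matrix(1, length(ids), length(ids))
  d[same_family] <- 2 / 3
  d[same_genus]  <- 1 / 3
  diag(d) <- 0
  new_similarity(1 - d, ids)
}

#' Collapse a published wingspan range to its midpoint
#'
#' Field guides report wingspan as a min-max range (e.g. `"32-38"`); the
#' diversity analysis uses a single value per species, taken as the range
#' midpoint. Plain numeric values pass through unchanged.
#'
#' @param x numeric vector, or character vector of numbers or `"min-max"`
#'   ranges (hyphen or en-dash separated).
#' @return numeric vector of wingspans (mm).
#' @export
wingspan_midpoint <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || x[i] == "") next
    parts <- strsplit(x[i], "[-–]")[[1]]
    parts <- suppressWarnings(as.numeric(trimws(parts)))
    if (anyNA(parts)) stop("unparseable wingspan value: ", x[i])
    out[i] <- mean(parts)
  }
  out
}

#' Declared functional traits
#'
#' The four functional traits the pipeline recognises: larval host-plant
#' preference, larval specialism (single vs multiple host families),
#' overwintering stage, and wingspan.
#' @export
FUNCTIONAL_TRAITS <- c("host_plant", "larval_specialism",
                       "overwintering_stage", "wingspan")

#' Similarity matrix for one declared functional trait
#'
#' Dispatches to the categorical builder for `host_plant`,
#' `larval_specialism` and `overwintering_stage`, and to the continuous
#' builder for `wingspan` (ranges collapsed to midpoints first). One matrix
#' is built per trait; traits are never pooled into a combined matrix.
#'
#' @param traits data frame with column `species` and the trait columns
#'   named in [FUNCTIONAL_TRAITS].
#' @param trait_name one of [FUNCTIONAL_TRAITS].
#' @return An S x S similarity matrix over `traits$species`.
#' @export
trait_similarity <- function(traits, trait_name) {
  if (!is.character(trait_name) || length(trait_name) != 1L ||
      !trait_name %in% FUNCTIONAL_TRAITS)
    stop("unknown trait: ", paste(trait_name, collapse = ", "),
         " (expected one of ", paste(FUNCTIONAL_TRAITS, collapse = ", "), ")")
  if (!"species" %in% names(traits) || !trait_name %in% names(traits))
    stop("trait table must have columns 'species' and '", trait_name, "'")
  ids <- check_species_ids(traits$species)
  v <- traits[[trait_name]]
  if (trait_name == "wingspan")
    continuous_trait_similarity(wingspan_midpoint(v), ids)
  else
    categorical_trait_similarity(v, ids)
}

#' Build the full set of similarity matrices for an analysis
#'
#' @param traits trait table (see [trait_similarity()]).
#' @param taxonomy taxonomy table (see [taxonomic_similarity()]).
#' @param constraints character vector of constraint names among
#'   `"naive"`, `"taxonomic"` and [FUNCTIONAL_TRAITS].
#' @return Named list of similarity matrices, one per constraint.
#' @export
similarity_set <- function(traits, taxonomy,
                           constraints = c("naive", "taxonomic", FUNCTIONAL_TRAITS)) {
  ids <- check_species_ids(traits$species)
  out <- list()
  for (cn in constraints) {
    out[[cn]] <- switch(cn,
      naive = identity_similarity(ids),
      taxonomic = taxonomic_similarity(taxonomy),
      trait_similarity(traits, cn))
  }
  out
}

#' Write / read a similarity matrix as square CSV
#'
#' Species ids appear as the header row and the first column; values are
#' written at full precision.
#'
#' @param Z similarity matrix.
#' @param path file path.
#' @return `read_similarity` returns the validated matrix.
#' @export
write_similarity <- function(Z, path) {
  validate_similarity(Z)
  df <- data.frame(species = rownames(Z), Z, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  Z <- as.matrix(df[, -1, drop = FALSE])
  mode(Z) <- "numeric"
  rownames(Z) <- ids
  validate_similarity(Z)
  Z
}
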