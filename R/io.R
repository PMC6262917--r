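META_COLS <- c("site_id", "pair_id", "habitat", "year", "month")
HABITATS <- c("broadleaf", "plantation")

#' Validate an abundance table
#'
#' An abundance table is a data frame with the metadata columns `site_id`,
#' `pair_id`, `habitat`, `year`, `month` followed by one integer count column
#' per species (explicit zeros for absences, so the species set is shared
#' across sites). Habitat labels must be exactly `broadleaf` or
#' `plantation`.
#'
#' @param abundance data frame to validate.
#' @return the table, invisibly, if valid.
#' @export
validate_abundance <- function(abundance) {
  if (!is.data.frame(abundance)) stop("abundance table must be a data frame")
  missing_meta <- setdiff(META_COLS, names(abundance))
  if (length(missing_meta))
    stop("abundance table missing metadata column(s): ",
         paste(missing_meta, collapse = ", "))
  sp_cols <- setdiff(names(abundance), META_COLS)
  if (length(sp_cols) == 0L) stop("abundance table has no species columns")
  if (anyDuplicated(abundance$site_id)) stop("duplicate site_id")
  bad_hab <- setdiff(unique(as.character(abundance$habitat)), HABITATS)
  if (length(bad_hab))
    stop("unknown habitat label(s): ", paste(bad_hab, collapse = ", "),
         " (expected ", paste(HABITATS, collapse = "/"), ")")
  for (sc in sp_cols) {
    v <- abundance[[sc]]
    if (!is.numeric(v) || anyNA(v))
      stop("species column '", sc, "' must be numeric with no missing values")
    bad <- which(v < 0 | v != round(v))
    if (length(bad))
      stop("invalid count at site '", abundance$site_id[bad[1]],
           "', species '", sc, "': counts must be non-negative integers")
  }
  invisible(abundance)
}

#' @rdname validate_abundance
#' @param path CSV file path.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_abundance(ab)
  ab
}

#' @rdname validate_abundance
#' @param abundance abundance table.
#' @export
write_abundance <- function(abundance, path) {
  validate_abundance(abundance)
  utils::write.csv(abundance, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract the site x species count matrix / metadata from an abundance table
#'
#' @param abundance abundance table.
#' @return `abundance_matrix`: numeric matrix (sites x species, rownames =
#'   site ids); `abundance_meta`: data frame of the metadata columns.
#' @export
abundance_matrix <- function(abundance) {
  sp_cols <- setdiff(names(abundance), META_COLS)
  m <- as.matrix(abundance[, sp_cols, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(abundance$site_id)
  m
}

#' @rdname abundance_matrix
#' @export
abundance_meta <- function(abundance) {
  abundance[, META_COLS, drop = FALSE]
}

#' Read / validate a species trait table
#'
#' Columns: `species`, `host_plant`, `larval_specialism`,
#' `overwintering_stage` (categorical; empty fields = missing), `wingspan`
#' (mm, positive; a `"min-max"` range is accepted and collapsed to its
#' midpoint downstream).
#'
#' @param path CSV file path.
#' @return validated trait data frame.
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_traits(tr)
  tr
}

#' @rdname read_traits
#' @param traits trait data frame.
#' @export
validate_traits <- function(traits) {
  need <- c("species", FUNCTIONAL_TRAITS)
  missing_cols <- setdiff(need, names(traits))
  if (length(missing_cols))
    stop("trait table missing column(s): ", paste(missing_cols, collapse = ", "))
  check_species_ids(traits$species)
  ws <- wingspan_midpoint(traits$wingspan)
  if (any(!is.na(ws) & ws <= 0)) stop("wingspan must be positive when present")
  invisible(traits)
}

#' @rdname read_traits
#' @export
write_traits <- function(traits, path) {
  validate_traits(traits)
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / validate a taxonomy table
#'
#' Columns `species,genus,family`; complete lineages, and each genus must
#' belong to exactly one family.
#'
#' @param path CSV file path.
#' @return validated taxonomy data frame.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tx <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_taxonomy(tx)
  tx
}

#' @rdname read_taxonomy
#' @param taxonomy taxonomy data frame.
#' @export
validate_taxonomy <- function(taxonomy) {
  need <- c("species", "genus", "family")
  missing_cols <- setdiff(need, names(taxonomy))
  if (length(missing_cols))
    stop("taxonomy table missing column(s): ", paste(missing_cols, collapse = ", "))
  taxonomic_similarity(taxonomy)   # full structural check
  invisible(taxonomy)
}

#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.csv(taxonomy, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-habitat summary of a site-level quantity
#'
#' Mean and SD per habitat, plus the plantation-as-percent-of-broadleaf
#' ratio and the percent deficit `(broadleaf - plantation)/broadleaf * 100`.
#' SD is `NA` for a single-site habitat.
#'
#' @param values numeric site-level values.
#' @param habitat habitat label per value (`broadleaf`/`plantation`).
#' @return list with `summary` (data frame: habitat, n, mean, sd),
#'   `ratio_pct`, `deficit_pct`.
#' @export
summarize_habitats <- function(values, habitat) {
  habitat <- as.character(habitat)
  if (length(values) != length(habitat))
    stop("values and habitat must have equal length")
  bad <- setdiff(unique(habitat), HABITATS)
  if (length(bad)) stop("unknown habitat label(s): ", paste(bad, collapse = ", "))
  if (!all(HABITATS %in% habitat))
    stop("both habitats must be represented")
  s <- do.call(rbind, lapply(HABITATS, function(h) {
    v <- values[habitat == h]
    data.frame(habitat = h, n = length(v), mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }))
  mb <- s$mean[s$habitat == "broadleaf"]
  mp <- s$mean[s$habitat == "plantation"]
  list(summary = s,
       ratio_pct = 100 * mp / mb,
       deficit_pct = 100 * (mb - mp) / mb)
}
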