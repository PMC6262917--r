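# Shared fixture builders. Everything is generated in code; seeds are fixed
# per test site so runs are reproducible.

random_proportions <- function(S) {
  p <- rgamma(S, shape = 0.7)
  p <- p / sum(p)
  names(p) <- paste0("sp", seq_len(S))
  p
}

# a valid random similarity matrix: symmetric, [0,1], unit diagonal
random_similarity <- function(S) {
  Z <- matrix(runif(S * S), S, S)
  Z <- (Z + t(Z)) / 2
  diag(Z) <- 1
  dimnames(Z) <- list(paste0("sp", seq_len(S)), paste0("sp", seq_len(S)))
  Z
}

# block-structured similarity: species in the same block identical,
# different blocks completely distinct
block_similarity <- function(block_sizes) {
  S <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  Z <- outer(lab, lab, function(a, b) as.numeric(a == b))
  dimnames(Z) <- list(paste0("sp", seq_len(S)), paste0("sp", seq_len(S)))
  Z
}

random_lineage <- function(S, n_genera, n_families) {
  fam <- paste0("F", seq_len(n_families))
  gen <- paste0("G", seq_len(n_genera))
  gen_fam <- fam[c(seq_len(n_families),
                   sample.int(n_families, n_genera - n_families, replace = TRUE))]
  sp_gen <- gen[c(seq_len(n_genera),
                  sample.int(n_genera, S - n_genera, replace = TRUE))]
  data.frame(species = paste0("s", seq_len(S)), genus = sp_gen,
             family = gen_fam[match(sp_gen, gen)])
}

# small abundance table with paired metadata, built by hand
toy_abundance <- function(counts, habitats = NULL) {
  n <- nrow(counts)
  if (is.null(habitats)) habitats <- rep(c("broadleaf", "plantation"),
                                         length.out = n)
  df <- data.frame(site_id = paste0("site", seq_len(n)),
                   pair_id = paste0("pair", rep(seq_len(ceiling(n / 2)),
                                                each = 2)[seq_len(n)]),
                   habitat = habitats,
                   year = rep(c(2014L, 2015L), length.out = n),
                   month = rep(6:8, length.out = n))
  cbind(df, as.data.frame(counts))
}

small_config <- function(seed = 1, ...) {
  study_config(n_pairs = 4, pool_size = 50, mean_richness_broadleaf = 25,
               mean_richness_plantation = 12, n_families = 6, n_genera = 15,
               seed = seed, ...)
}
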