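test_that("a default study has 26 sites in 13 labelled pairs", {
  st <- generate_study(study_config(seed = 3))
  ab <- st$abundance
  expect_equal(nrow(ab), 26)
  expect_equal(length(unique(ab$pair_id)), 13)
  expect_true(all(table(ab$pair_id) == 2))
  # each pair holds one site of each habitat, sharing year and month
  for (pid in unique(ab$pair_id)) {
    sub <- ab[ab$pair_id == pid, ]
    expect_setequal(sub$habitat, c("broadleaf", "plantation"))
    expect_equal(length(unique(sub$year)), 1)
    expect_equal(length(unique(sub$month)), 1)
  }
  expect_gt(length(unique(ab$year)), 1)
  expect_gt(length(unique(ab$month)), 2)
  expect_silent(validate_abundance(ab))
  expect_silent(validate_traits(st$traits))
  expect_silent(validate_taxonomy(st$taxonomy))
})

test_that("generation is deterministic in the seed", {
  a <- generate_study(small_config(seed = 9))
  b <- generate_study(small_config(seed = 9))
  expect_identical(a, b)
  c2 <- generate_study(small_config(seed = 10))
  expect_false(identical(a$abundance, c2$abundance))
})

test_that("written study CSVs are byte-identical under the same seed", {
  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  write_study(generate_study(small_config(seed = 4)), d1)
  write_study(generate_study(small_config(seed = 4)), d2)
  for (f in c("abundance.csv", "traits.csv", "taxonomy.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  expect_true(file.exists(file.path(d1, "provenance.json")))
  # round-trip through the validators
  expect_silent(validate_abundance(read_abundance(file.path(d1, "abundance.csv"))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("pool hierarchy edge cases behave", {
  set.seed(51)
  pool <- generate_species_pool(12, n_families = 3, n_genera = 12)
  expect_equal(length(unique(pool$taxonomy$genus)), 12)  # one genus each
  expect_error(generate_species_pool(10, n_families = 5, n_genera = 3),
               "n_families <= n_genera")
  vocab1 <- list(host_plant = "herbs", larval_specialism = "single_family",
                 overwintering_stage = "egg")
  p1 <- generate_species_pool(8, 2, 4, trait_vocab = vocab1)
  Z <- trait_similarity(p1$traits, "host_plant")
  expect_true(all(Z == 1))  # degenerate vocabulary: all species identical
})

test_that("degenerate study sizes are handled", {
  cfg0 <- small_config(seed = 1)
  cfg0$n_pairs <- 0
  ab0 <- generate_paired_communities(cfg0, generate_species_pool(50, 6, 15,
                                                                 seed = 2))
  expect_equal(nrow(ab0), 0)
  expect_error(study_config(pool_size = 20, mean_richness_broadleaf = 63),
               "exceed pool size")
})

test_that("realized per-habitat richness tracks the configured means", {
  mb <- mp <- numeric(30)
  for (s in 1:30) {
    st <- generate_study(study_config(seed = 1000 + s))
    m <- abundance_matrix(st$abundance)
    rich <- rowSums(m > 0)
    hab <- abundance_meta(st$abundance)$habitat
    mb[s] <- mean(rich[hab == "broadleaf"])
    mp[s] <- mean(rich[hab == "plantation"])
  }
  expect_lt(abs(mean(mb) - 63), 3)
  expect_lt(abs(mean(mp) - 27), 3)
})

test_that("full trait sharing equalises host-plant constrained richness", {
  diffs <- numeric(25)
  for (s in 1:25) {
    st <- generate_study(study_config(seed = 2000 + s, trait_sharing = 1,
                                      habitat_effect_on_traits = 0))
    Z <- trait_similarity(st$traits, "host_plant")
    m <- abundance_matrix(st$abundance)
    hab <- abundance_meta(st$abundance)$habitat
    d0 <- apply(m, 1, function(x)
      similarity_diversity(relative_abundance(x), Z, 0))
    diffs[s] <- mean(d0[hab == "broadleaf"]) - mean(d0[hab == "plantation"])
  }
  mean_b <- 6  # six host-plant classes available
  expect_lt(abs(mean(diffs)), 0.05 * mean_b)
})

test_that("a strong trait filter produces a detectable filtering signal", {
  det <- logical(15)
  for (s in 1:15) {
    st <- generate_study(study_config(seed = 3000 + s, trait_sharing = 0,
                                      habitat_effect_on_traits = 1))
    Z <- trait_similarity(st$traits, "host_plant")
    nm <- null_model_test(st$abundance, Z, q = 1, n_perm = 199,
                          seed = 3000 + s)
    ht <- habitat_ses_test(nm$ses, nm$habitat)
    pl <- ht[ht$habitat == "plantation", ]
    det[s] <- !pl$degenerate && pl$mean_ses < 0 && pl$p_value < 0.05
  }
  expect_gte(mean(det), 0.8)
})
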