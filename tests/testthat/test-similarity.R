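test_that("identity similarity is the identity matrix with valid structure", {
  Z <- identity_similarity(c("a", "b", "c"))
  expect_equal(unname(Z), diag(3))
  expect_identical(rownames(Z), c("a", "b", "c"))
  expect_equal(unname(identity_similarity("solo")), matrix(1, 1, 1))
  expect_error(identity_similarity(character(0)), "non-empty")
  expect_error(identity_similarity(c("a", "a")), "unique")
})

test_that("categorical trait similarity is 0/1 mismatch and enumerates pairs", {
  Z2 <- categorical_trait_similarity(c("egg", "egg"))
  expect_equal(Z2[1, 2], 1)
  Z2b <- categorical_trait_similarity(c("egg", "pupa"))
  expect_equal(Z2b[1, 2], 0)
  Z3 <- categorical_trait_similarity(c("egg", "egg", "pupa"))
  expect_equal(unname(Z3),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_error(categorical_trait_similarity(c(NA, NA)), "missing")
})

test_that("categorical similarity is invariant under relabeling", {
  set.seed(11)
  for (rep in 1:5) {
    v <- sample(letters[1:4], 12, replace = TRUE)
    relab <- setNames(paste0("LEVEL_", 1:4), letters[1:4])
    Z1 <- categorical_trait_similarity(v)
    Z2 <- categorical_trait_similarity(unname(relab[v]))
    expect_equal(unname(Z1), unname(Z2))
  }
})

test_that("missing categorical values get the mean observed-pair similarity", {
  v <- c("egg", "egg", "pupa", NA)
  Z <- categorical_trait_similarity(v)
  # observed pairs: (1,2)=1, (1,3)=0, (2,3)=0 -> mean 1/3
  expect_equal(Z[4, 1], 1 / 3)
  expect_equal(Z[4, 2], 1 / 3)
  expect_equal(Z[4, 4], 1)
  expect_equal(attr(Z, "imputed"), 1L)
  expect_silent(validate_similarity(Z))
})

test_that("continuous trait similarity is range-normalised distance", {
  Z <- continuous_trait_similarity(c(20, 40))
  expect_equal(Z[1, 2], 0)
  Z3 <- continuous_trait_similarity(c(20, 30, 40))
  expect_equal(Z3[1, 2], 0.5)
  expect_equal(Z3[1, 3], 0)
  Zd <- continuous_trait_similarity(c(25, 25, 40))
  expect_equal(Zd[1, 2], 1)   # tied values are fully similar
  expect_error(continuous_trait_similarity(c(30, 30, 30)), "range")
})

test_that("continuous similarity is invariant under affine rescaling", {
  set.seed(12)
  for (rep in 1:5) {
    x <- runif(10, 10, 60)
    a <- runif(1, 0.5, 3)
    b <- runif(1, -5, 5)
    expect_equal(unname(continuous_trait_similarity(x)),
                 unname(continuous_trait_similarity(a * x + b)))
  }
})

test_that("taxonomic similarity uses equal rank steps on [0, 1]", {
  tx <- data.frame(species = c("s1", "s2", "s3", "s4"),
                   genus = c("G1", "G1", "G2", "G3"),
                   family = c("F1", "F1", "F1", "F2"))
  Z <- taxonomic_similarity(tx)
  expect_equal(diag(Z), setNames(rep(1, 4), tx$species))  # same species
  expect_equal(Z["s1", "s2"], 2 / 3)  # congeners
  expect_equal(Z["s1", "s3"], 1 / 3)  # same family, different genus
  expect_equal(Z["s1", "s4"], 0)      # different families
  expect_error(taxonomic_similarity(tx[, c("species", "genus")]), "columns")
  tx_bad <- tx; tx_bad$family[2] <- NA
  expect_error(taxonomic_similarity(tx_bad), "complete")
  tx_gf <- tx; tx_gf$family[2] <- "F2"  # genus G1 in two families
  expect_error(taxonomic_similarity(tx_gf), "more than one family")
})

test_that("taxonomic similarity matches a brute-force lowest-shared-rank oracle", {
  set.seed(13)
  for (rep in 1:5) {
    tx <- random_lineage(15, n_genera = 8, n_families = 4)
    Z <- taxonomic_similarity(tx)
    for (i in 1:15) for (j in 1:15) {
      shared <- if (i == j) 3 else if (tx$genus[i] == tx$genus[j]) 2 else
        if (tx$family[i] == tx$family[j]) 1 else 0
      expect_equal(Z[i, j], shared / 3)
    }
  }
})

test_that("taxonomic similarity agrees with vegan::taxa2dist", {
  set.seed(14)
  tx <- random_lineage(20, n_genera = 9, n_families = 4)
  ref <- as.matrix(vegan::taxa2dist(
    data.frame(genus = tx$genus, family = tx$family, row.names = tx$species),
    varstep = FALSE))
  Z <- taxonomic_similarity(tx)
  expect_equal(unname(Z), unname(1 - ref / 100), tolerance = 1e-12)
})

test_that("trait_similarity dispatches by trait type and rejects unknowns", {
  tr <- data.frame(species = paste0("s", 1:4),
                   host_plant = c("herbs", "trees", "herbs", "grasses"),
                   larval_specialism = c("single_family", "multi_family",
                                         "multi_family", "single_family"),
                   overwintering_stage = c("egg", "egg", "pupa/cocoon", "adult"),
                   wingspan = c("20-40", "30", "25-35", "18"))
  Zo <- trait_similarity(tr, "overwintering_stage")
  expect_equal(unname(Zo),
               unname(categorical_trait_similarity(tr$overwintering_stage)))
  Zw <- trait_similarity(tr, "wingspan")
  # midpoints 30, 30, 30, 18: range 12
  expect_equal(Zw[1, 2], 1)
  expect_equal(Zw[1, 4], 0)
  expect_error(trait_similarity(tr, "colour"), "unknown trait")
})

test_that("every builder returns a valid similarity matrix on random input", {
  set.seed(15)
  for (rep in 1:10) {
    S <- sample(3:20, 1)
    expect_silent(validate_similarity(
      categorical_trait_similarity(sample(letters[1:3], S, replace = TRUE))))
    expect_silent(validate_similarity(
      continuous_trait_similarity(runif(S, 1, 9))))
    expect_silent(validate_similarity(
      taxonomic_similarity(random_lineage(S, min(S, 4), min(S, 2)))))
  }
})

test_that("similarity matrices round-trip through square CSV", {
  set.seed(16)
  Z <- continuous_trait_similarity(runif(8, 10, 50))
  f <- tempfile(fileext = ".csv")
  write_similarity(Z, f)
  Z2 <- read_similarity(f)
  expect_equal(Z2, Z, ignore_attr = "imputed", tolerance = 1e-14)
  unlink(f)
})
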