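test_that("power mean handles its classical special cases", {
  expect_equal(power_mean(c(2, 4, 6), 1, rep(1 / 3, 3)), 4)
  expect_equal(power_mean(c(1, 4), 0, c(0.5, 0.5)), 2)       # geometric mean
  for (t in c(-Inf, -2, 0, 1, 3, Inf))
    expect_equal(power_mean(rep(5, 4), t, rep(0.25, 4)), 5)  # idempotence
  expect_equal(power_mean(c(1, 9), -Inf, c(0.5, 0.5)), 1)
  expect_equal(power_mean(c(1, 9), Inf, c(0.5, 0.5)), 9)
  # zero-weight values are excluded before positivity checks
  expect_equal(power_mean(c(3, -1), 2, c(1, 0)), 3)
  expect_error(power_mean(c(3, -1), 2, c(0.5, 0.5)), "positive")
  expect_error(power_mean(c(1, 2), 1, c(0.9, 0.9)), "sum to 1")
})

test_that("relative abundance drops zeros and normalises", {
  p <- relative_abundance(c(a = 10, b = 30, c = 0, d = 60))
  expect_equal(p, c(a = 0.1, b = 0.3, d = 0.6))
  expect_equal(unname(relative_abundance(5)), 1)
  expect_error(relative_abundance(c(0, 0)), "no individuals")
  expect_error(relative_abundance(c(-1, 2)), "non-negative")
})

test_that("naive diversity reproduces richness, Shannon and Simpson forms", {
  p <- c(0.5, 0.3, 0.2)
  expect_equal(naive_diversity(p, 0), 3)
  expect_equal(naive_diversity(p, 2), 1 / 0.38, tolerance = 1e-10)
  expect_equal(naive_diversity(p, 1), exp(-sum(p * log(p))))
  for (q in c(0, 0.5, 1, 2, 5))
    expect_equal(naive_diversity(rep(0.1, 10), q), 10)
  expect_error(naive_diversity(p, -1), "q must be")
})

test_that("similarity diversity reduces to naive with identity Z", {
  set.seed(21)
  for (rep in 1:50) {
    S <- sample(2:30, 1)
    p <- random_proportions(S)
    q <- sample(c(0, 0.5, 1, 1.7, 2, 4), 1)
    expect_equal(similarity_diversity(p, identity_similarity(names(p)), q),
                 naive_diversity(p, q), tolerance = 1e-10)
  }
})

test_that("similarity diversity has the correct closed-form special cases", {
  set.seed(22)
  # all-ones similarity: one effective species whatever the abundances
  for (rep in 1:10) {
    S <- sample(2:15, 1)
    ones <- matrix(1, S, S,
                   dimnames = list(paste0("sp", 1:S), paste0("sp", 1:S)))
    p <- random_proportions(S)
    expect_equal(similarity_diversity(p, ones, runif(1, 0, 3)), 1,
                 tolerance = 1e-12)
  }
  # two half-similar species: Zp is constant 0.75, diversity 4/3 at any q
  Z <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  for (q in c(0, 1, 2, 3.7))
    expect_equal(similarity_diversity(c(a = 0.5, b = 0.5), Z, q), 4 / 3,
                 tolerance = 1e-12)
  expect_error(similarity_diversity(c(x = 0.5, y = 0.5), Z, 1), "missing species")
})

test_that("diversity profiles are non-increasing in q and within [1, S]", {
  set.seed(23)
  qg <- c(0, 0.5, 1, 1.5, 2, 5)
  for (rep in 1:30) {
    S <- sample(2:25, 1)
    p <- random_proportions(S)
    Z <- random_similarity(S)
    prof <- diversity_profile(p, Z, qg)
    expect_true(all(diff(prof$effective_number) <= 1e-10))
    expect_true(all(prof$effective_number >= 1 - 1e-10))
    expect_true(all(prof$effective_number <= S + 1e-10))
    # constrained diversity never exceeds naive
    naive <- vapply(qg, function(q) naive_diversity(p, q), numeric(1))
    expect_true(all(prof$effective_number <= naive + 1e-10))
  }
})

test_that("profiles handle uniform, block and empty-grid cases", {
  p <- setNames(rep(0.1, 10), paste0("sp", 1:10))
  prof <- diversity_profile(p, q_grid = c(0, 1, 2))
  expect_equal(prof$effective_number, c(10, 10, 10))
  Zb <- block_similarity(c(5, 5))
  prof_b <- diversity_profile(p, Zb, c(0, 1, 2))
  expect_equal(prof_b$effective_number, rep(2, 3), tolerance = 1e-12)
  empty <- diversity_profile(p, q_grid = numeric(0))
  expect_equal(nrow(empty), 0)
})

test_that("diversity at q = 1 is continuous in q", {
  set.seed(24)
  for (rep in 1:20) {
    S <- sample(3:20, 1)
    p <- random_proportions(S)
    Z <- random_similarity(S)
    d1 <- similarity_diversity(p, Z, 1)
    expect_lt(abs(d1 - similarity_diversity(p, Z, 1 + 1e-6)), 1e-4)
    expect_lt(abs(d1 - similarity_diversity(p, Z, 1 - 1e-6)), 1e-4)
  }
})

test_that("diversity is invariant under species reordering", {
  set.seed(25)
  for (rep in 1:10) {
    S <- sample(3:15, 1)
    p <- random_proportions(S)
    Z <- random_similarity(S)
    perm <- sample(S)
    q <- runif(1, 0, 3)
    expect_equal(similarity_diversity(p[perm], Z[perm, perm], q),
                 similarity_diversity(p, Z, q), tolerance = 1e-12)
  }
})

test_that("redundancy is the naive / constrained richness ratio", {
  counts <- setNames(rep(3, 10), paste0("sp", 1:10))
  r_id <- redundancy(counts, identity_similarity(names(counts)))
  expect_equal(r_id$redundancy, 1)
  ones <- matrix(1, 10, 10, dimnames = list(names(counts), names(counts)))
  expect_equal(redundancy(counts, ones)$redundancy, 10, tolerance = 1e-12)
  # two blocks of five identical species: constrained richness 2
  rb <- redundancy(counts, block_similarity(c(5, 5)))
  expect_equal(rb$constrained_richness, 2, tolerance = 1e-12)
  expect_equal(rb$redundancy, 5, tolerance = 1e-12)
  # redundancy >= 1 for any similarity matrix
  set.seed(26)
  for (rep in 1:20) {
    S <- sample(2:20, 1)
    cts <- setNames(rpois(S, 5) + 1, paste0("sp", 1:S))
    expect_gte(redundancy(cts, random_similarity(S))$redundancy, 1 - 1e-10)
  }
})

test_that("site_diversity computes per-site subcommunity profiles", {
  counts <- rbind(c(10, 5, 0, 1), c(0, 0, 8, 8))
  colnames(counts) <- paste0("sp", 1:4)
  ab <- toy_abundance(counts)
  Zs <- list(naive = identity_similarity(colnames(counts)))
  div <- site_diversity(ab, Zs, q_grid = c(0, 2))
  expect_equal(nrow(div), 4)
  expect_equal(div$effective_number[div$site_id == "site1" & div$q == 0], 3)
  expect_equal(div$effective_number[div$site_id == "site2" & div$q == 0], 2)
  expect_equal(div$effective_number[div$site_id == "site2" & div$q == 2], 2)
})
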