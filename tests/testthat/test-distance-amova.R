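test_that("haplotype distances obey the two model definitions", {
  h <- .base_hap
  expect_identical(haplotype_distance(h, h, model = "identity"), 0)
  expect_identical(haplotype_distance(h, h, model = "stepwise"), 0)

  h2 <- h; h2["DYS391"] <- h["DYS391"] + 1
  expect_identical(haplotype_distance(h, h2, model = "identity"), 1)
  expect_identical(haplotype_distance(h, h2, model = "stepwise"), 1)

  # DYS385 (11,14) vs (12,14): enumerate both pairings, take the minimum
  g1 <- h; g1[c("DYS385a", "DYS385b")] <- c(11, 14)
  g2 <- h; g2[c("DYS385a", "DYS385b")] <- c(12, 14)
  pairings <- c(abs(11 - 12) + abs(14 - 14), abs(11 - 14) + abs(14 - 12))
  expect_identical(haplotype_distance(g1, g2, model = "stepwise"),
                   min(pairings))
  expect_identical(haplotype_distance(g1, g2, model = "identity"), 1)

  expect_error(haplotype_distance(h[-1], h), "complete")
})

test_that("distance matrices are symmetric with zero diagonal", {
  set.seed(31)
  ds <- random_small_ds(3)
  for (model in c("identity", "stepwise")) {
    D <- distance_matrix(ds, model)
    expect_equal(unname(diag(D)), rep(0, nrow(D)))
    expect_equal(max(abs(D - t(D))), 0)
    if (model == "identity") expect_true(all(D %in% c(0, 1)))
    # matrix agrees with the scalar definition entry by entry (spot check)
    cols <- panel_columns(ds$panel)
    for (pair in list(c(1, 2), c(2, 5), c(1, nrow(D)))) {
      d12 <- haplotype_distance(ds$data[pair[1], cols], ds$data[pair[2], cols],
                                ds$panel, model)
      expect_equal(D[pair[1], pair[2]], d12)
    }
  }
})

test_that("AMOVA endpoints: identical composition gives ~0, fixation gives 1", {
  same <- rbind(hap_row("a1", "P1"), hap_row("a2", "P1", DYS391 = 11),
                hap_row("b1", "P2"), hap_row("b2", "P2", DYS391 = 11))
  am0 <- amova_two_level(ystr_dataset(same))
  expect_lte(am0$phi, 0)

  fixed <- rbind(hap_row("a1", "P1"), hap_row("a2", "P1"),
                 hap_row("b1", "P2", DYS391 = 12),
                 hap_row("b2", "P2", DYS391 = 12))
  am1 <- amova_two_level(ystr_dataset(fixed))
  expect_equal(am1$phi, 1)

  flat <- amova_two_level(uniform_ds(list(P1 = 3, P2 = 3)))
  expect_true(flat$degenerate)
  expect_identical(flat$phi, 0)

  solo <- rbind(hap_row("a1", "P1"), hap_row("a2", "P1"), hap_row("b1", "P2"))
  expect_error(amova_two_level(ystr_dataset(solo)), "at least 2")
})

test_that("AMOVA matches the brute-force pairwise oracle on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    k <- sample(2:4, 1)
    ds <- random_small_ds(k)           # N <= 20, sizes 2-5 per population
    for (model in c("identity", "stepwise")) {
      am <- amova_two_level(ds, model)
      D2 <- distance_matrix(ds, model, squared = TRUE)
      oracle <- brute_amova(D2, attr(D2, "population"))
      expect_equal(am$ss_total, oracle$ss_total, tolerance = 1e-9)
      expect_equal(am$ss_within, oracle$ss_within, tolerance = 1e-9)
      expect_equal(am$ss_among, oracle$ss_among, tolerance = 1e-9)
      expect_equal(am$sigma2_a, oracle$sigma2_a, tolerance = 1e-9)
      expect_equal(am$sigma2_w, oracle$sigma2_w, tolerance = 1e-9)
      expect_equal(am$phi, oracle$phi, tolerance = 1e-9)
      expect_equal(am$ss_total, am$ss_among + am$ss_within, tolerance = 1e-9)
    }
  }
})

test_that("identity-model AMOVA matches the centroid-deviation route", {
  # independent derivation: haplotypes as indicator vectors, sums of squares
  # from deviations around group and grand centroids
  set.seed(101)
  for (rep in 1:10) {
    ds <- random_small_ds(3)
    am <- amova_two_level(ds, "identity")
    keys <- haplotype_keys(ds)
    ss <- indicator_amova_ss(keys, ds$data$population)
    expect_equal(am$ss_total, ss$ss_total, tolerance = 1e-9)
    expect_equal(am$ss_within, ss$ss_within, tolerance = 1e-9)
    expect_equal(am$ss_among, ss$ss_among, tolerance = 1e-9)
  }
})

test_that("FST is invariant to population renaming and row order", {
  set.seed(55)
  ds <- random_small_ds(3)
  am <- amova_two_level(ds)
  perm <- sample(n_donors(ds))
  shuffled <- ystr_dataset(ds$data[perm, ], ds$panel)
  expect_equal(amova_two_level(shuffled)$phi, am$phi, tolerance = 1e-12)
  renamed_df <- ds$data
  renamed_df$population <- paste0("ZZ_", renamed_df$population)
  expect_equal(amova_two_level(ystr_dataset(renamed_df))$phi, am$phi,
               tolerance = 1e-12)
})

test_that("pairwise FST matrices carry calibrated permutation p-values", {
  # one population duplicated under two labels: Phi ~ 0, p large
  df <- rbind(hap_row("a1", "P1"), hap_row("a2", "P1", DYS391 = 11),
              hap_row("a3", "P1", DYS448 = 20),
              hap_row("b1", "P2"), hap_row("b2", "P2", DYS391 = 11),
              hap_row("b3", "P2", DYS448 = 20))
  fst <- pairwise_fst_matrix(ystr_dataset(df), B = 199, seed = 3)
  expect_lte(fst$values["P1", "P2"], 0)
  expect_gte(fst$pvalues["P1", "P2"], 0.5)

  # complete fixation with 8 donors per group: Phi = 1, and no random
  # relabelling recreates the split (2/choose(16,8) per draw), so p sits
  # at its floor 1/(B+1)
  fixed <- do.call(rbind, c(
    lapply(1:8, function(i) hap_row(sprintf("a%d", i), "P1")),
    lapply(1:8, function(i) hap_row(sprintf("b%d", i), "P2", DYS391 = 12))))
  B <- 199
  f2 <- pairwise_fst_matrix(ystr_dataset(fixed), B = B, seed = 4)
  expect_equal(f2$values["P1", "P2"], 1)
  expect_equal(f2$pvalues["P1", "P2"], 1 / (B + 1))

  # structural contracts
  ds <- cached_fixture("tiny")
  f3 <- pairwise_fst_matrix(ds, B = 99, seed = 10)
  expect_equal(f3$values, t(f3$values))
  expect_equal(unname(diag(f3$values)), rep(0, 3))
  off <- f3$pvalues[upper.tri(f3$pvalues)]
  expect_true(all(off >= 1 / 100 & off <= 1))
  # reproducibility from the seed
  f4 <- pairwise_fst_matrix(ds, B = 99, seed = 10)
  expect_identical(f4$values, f3$values)
  expect_identical(f4$pvalues, f3$pvalues)

  expect_error(pairwise_fst_matrix(ds, B = 0, seed = 1),
               class = "ystr_config_error")
  expect_error(pairwise_fst_matrix(ds, B = 10),
               class = "ystr_config_error")
})
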