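test_that("stepwise mutation honours rate, bounds and microvariants", {
  h <- .base_hap
  set.seed(1)
  expect_identical(mutate_haplotype(h, mu = 0), h)

  # mu = 1 at the lower bound: reflection forces +1 with certainty
  panel <- yfiler_panel()
  info <- ystrpop:::.panel_column_info(panel)
  at_min <- stats::setNames(info$allele_min, info$column)
  for (i in 1:10) {
    m <- mutate_haplotype(at_min, panel, mu = 1)
    expect_identical(unname(m), unname(at_min + 1))
  }
  at_max <- stats::setNames(info$allele_max, info$column)
  m <- mutate_haplotype(at_max, panel, mu = 1)
  expect_identical(unname(m), unname(at_max - 1))

  # microvariant fractional part survives mutation
  mv <- h; mv["DYS458"] <- 17.2
  set.seed(3)
  hit <- replicate(200, mutate_haplotype(mv, mu = 1)["DYS458"])
  expect_true(all(abs(hit %% 1 - 0.2) < 1e-9))
  expect_true(all(abs(hit - 16.2) < 1e-9 | abs(hit - 18.2) < 1e-9))
})

test_that("realised mutation fraction matches the binomial expectation", {
  # ~1.02e5 allele copies at mu = 0.002; every mutation changes the value,
  # so the changed fraction is Binomial(n, mu)/n, checked at the 99% CI
  panel <- yfiler_panel()
  info <- ystrpop:::.panel_column_info(panel)
  n_rows <- 6000L
  mat <- matrix(rep(stats::setNames(round((info$allele_min + info$allele_max) / 2),
                                    info$column), each = n_rows),
                n_rows, nrow(info))
  set.seed(8)
  mut <- ystrpop:::.mutate_matrix(mat, rep(0.002, ncol(mat)),
                                  info$allele_min, info$allele_max)
  n <- length(mat)
  frac <- mean(mut != mat)
  ci <- 0.002 + c(-1, 1) * stats::qnorm(0.995) * sqrt(0.002 * 0.998 / n)
  expect_gt(frac, ci[1])
  expect_lt(frac, ci[2])
})

test_that("simulations are bit-reproducible from the seed", {
  cfg <- sim_config(k = 2, n_sample = 8, Ne = 20, generations = 15,
                    migration_rate = 0.1, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$dataset$data, s2$dataset$data)
  expect_identical(s1$truth$allele_freqs, s2$truth$allele_freqs)
  expect_identical(s1$truth$lineage_counts, s2$truth$lineage_counts)
  # a different seed moves the result
  cfg2 <- sim_config(k = 2, n_sample = 8, Ne = 20, generations = 15,
                     migration_rate = 0.1, seed = 124)
  expect_false(identical(simulate_dataset(cfg2)$dataset$data,
                         s1$dataset$data))
})

test_that("truth log conserves patrilines and sampling bookkeeping", {
  cfg <- sim_config(k = 3, n_sample = c(5, 7, 9), Ne = 25, generations = 10,
                    migration_rate = 0.05, seed = 42)
  sim <- simulate_dataset(cfg)
  expect_equal(unname(pop_sizes(sim$dataset)), c(5L, 7L, 9L))
  expect_true(all(sim$truth$lineage_counts >= 1 &
                    sim$truth$lineage_counts <= 25))
  freqs <- sim$truth$allele_freqs
  expect_equal(length(freqs), 3L)
  for (p in freqs) for (col in p) expect_equal(sum(col), 1, tolerance = 1e-12)
})

test_that("a mutation-free single founder yields a monomorphic sample", {
  cfg <- sim_config(k = 1, n_sample = 12, Ne = 30, generations = 20, mu = 0,
                    seed = 5)
  ds <- simulate_dataset(cfg)$dataset
  expect_equal(length(unique(haplotype_keys(ds))), 1L)
  expect_identical(haplotype_diversity(ds), 0)
  expect_equal(discrimination_capacity(ds), 1 / 12)
})

test_that("isolated populations drift to fixation and FST -> 1", {
  info <- ystrpop:::.panel_column_info(yfiler_panel())
  freqs <- stats::setNames(lapply(seq_len(nrow(info)), function(j)
    ystrpop:::.geom_founder_freqs(info$allele_min[j], info$allele_max[j], 0.6)),
    info$column)
  cfg <- sim_config(k = 2, n_sample = 10, Ne = 20, generations = 400,
                    migration_rate = 0, mu = 0, founder_freqs = freqs,
                    seed = 17)
  ds <- simulate_dataset(cfg)$dataset
  keys <- split(haplotype_keys(ds), ds$data$population)
  expect_true(all(lengths(lapply(keys, unique)) == 1L))  # lineage sorting
  expect_false(identical(unique(keys[[1]]), unique(keys[[2]])))
  expect_equal(amova_two_level(ds)$phi, 1)
})

test_that("gene diversity decays under drift when mutation is off", {
  info <- ystrpop:::.panel_column_info(yfiler_panel())
  freqs <- stats::setNames(lapply(seq_len(nrow(info)), function(j)
    ystrpop:::.geom_founder_freqs(info$allele_min[j], info$allele_max[j], 0.6)),
    info$column)
  # E[H_t] = H_0 (1 - 1/Ne)^t; at Ne = 40, t = 40 the factor is ~0.36
  gd_at <- function(gen, seed) {
    cfg <- sim_config(k = 1, n_sample = 40, Ne = 40, generations = gen,
                      mu = 0, founder_freqs = freqs, seed = seed)
    mean(gd_matrix(simulate_dataset(cfg)$dataset,
                   combine_dys385 = TRUE)$pooled)
  }
  set.seed(2)
  early <- vapply(1:8, function(i) gd_at(0, 1000 + i), numeric(1))
  late <- vapply(1:8, function(i) gd_at(40, 2000 + i), numeric(1))
  expect_lt(mean(late), mean(early))
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(k = 1, n_sample = 5, Ne = 10, generations = 5,
                          migration_rate = 0.1, seed = 1),
               class = "ystr_config_error")
  expect_error(sim_config(k = 2, n_sample = 20, Ne = 10, generations = 5,
                          seed = 1), class = "ystr_config_error")
  expect_error(sim_config(k = 2, n_sample = 5, Ne = 10, generations = 5,
                          migration_rate = 1.5, seed = 1),
               class = "ystr_config_error")
  expect_error(sim_config(k = 2, n_sample = 5, Ne = 10, generations = 5),
               class = "ystr_config_error")  # seed mandatory
  expect_error(make_fixture("nope"), "arg")
})

test_that("the tiny fixture has the documented shape", {
  ds <- cached_fixture("tiny")
  expect_equal(unname(pop_sizes(ds)), rep(10L, 3))
  expect_equal(n_donors(ds), 30L)
  expect_true(all(complete_haplotypes(ds)))
  # deterministic given the default seed
  expect_identical(make_fixture("tiny")$data, ds$data)
})

test_that("the iran-like fixture reproduces the emulated study structure", {
  ds <- cached_fixture("iran-like")
  sizes <- pop_sizes(ds)
  expect_equal(length(sizes), 16L)
  expect_equal(sum(sizes), 1353L)
  expect_equal(unname(sizes[c("Tehran", "SouthKhorasan")]), c(236L, 27L))
  expect_gte(haplotype_diversity(ds), 0.99)
  g <- gd_matrix(ds)
  expect_true(all(g$pooled >= 0.3 & g$pooled <= 0.9))
  truth <- attr(ds, "truth")
  expect_s3_class(truth$config, "sim_config")
})
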