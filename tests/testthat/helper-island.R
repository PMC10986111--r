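# Island-model FST recovery experiment: two demes of size Ne exchanging
# migrants at rate m per offspring per generation reach a migration-drift
# balance whose fixation index, in the weak-migration weak-mutation limit,
# is F = 1 / (1 + 4*Ne*m). The exact two-deme equilibrium carries a factor
# (1-m)/(1-2m)^2 on 4Nm, so the classic formula requires m << 1: Ne is
# scaled per case to cap m at 0.005 (2.5e-3 for the strongest-drift case),
# and generations cover several relaxation times 1/(4m + 1/Ne) of the
# fixation index. The aggregate estimate over replicates is the ratio of
# summed variance components (multilocus convention), with a delete-one
# jackknife standard error over replicates. Per-locus mutation is tied to
# migration (mu = m/500) so its extra homogenising term stays below ~2%
# of the migration term.
island_fst_experiment <- function(four_nem, reps, n_sample = 50L,
                                  seed = 1L) {
  Ne <- as.integer(max(100, 50 * four_nem))   # caps m at 0.005
  generations <- if (Ne == 100L) 600L else 400L
  m <- four_nem / (4 * Ne)
  mu <- m / 500
  comp <- vapply(seq_len(reps), function(r) {
    cfg <- sim_config(k = 2, n_sample = n_sample, Ne = Ne,
                      generations = generations, migration_rate = m,
                      mu = mu, seed = seed * 100000L + r)
    ds <- simulate_dataset(cfg)$dataset
    am <- amova_two_level(ds, "identity")
    c(a = am$sigma2_a, w = am$sigma2_w)
  }, c(a = 0, w = 0))
  a <- comp["a", ]; w <- comp["w", ]
  est <- sum(a) / sum(a + w)
  # delete-one jackknife over replicates
  loo <- vapply(seq_len(reps), function(r)
    sum(a[-r]) / sum(a[-r] + w[-r]), numeric(1))
  se <- sqrt((reps - 1) / reps * sum((loo - mean(loo))^2))
  list(estimate = est, se = se, expected = 1 / (1 + four_nem),
       reps = reps)
}

# null permutation calibration: repeated 30/30 splits of donors drawn from
# one panmictic simulated population; returns the permutation p-values
null_pvalues <- function(n_pops = 10L, draws_per_pop = 20L, B = 999L,
                         seed = 1L) {
  pvals <- numeric(0)
  for (i in seq_len(n_pops)) {
    cfg <- sim_config(k = 1, n_sample = 200, Ne = 200, generations = 400,
                      mu = 1e-3, seed = seed * 1000L + i)
    ds <- simulate_dataset(cfg)$dataset
    set.seed(seed * 2000L + i)
    for (d in seq_len(draws_per_pop)) {
      rows <- sample(n_donors(ds), 60)
      sub <- ds$data[rows, ]
      sub$population <- rep(c("A", "B"), each = 30)
      sub$sample_id <- sprintf("x%03d", seq_len(60))
      split_ds <- ystr_dataset(sub, ds$panel)
      fst <- pairwise_fst_matrix(split_ds, model = "stepwise", B = B,
                                 seed = seed * 4000L + i * 100L + d)
      pvals <- c(pvals, fst$pvalues["A", "B"])
    }
  }
  pvals
}
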