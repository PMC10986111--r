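# Shared builders and independent oracles for the test suite.

.base_hap <- c(DYS456 = 15, DYS389I = 13, DYS390 = 24, DYS389II = 29,
               DYS458 = 17, DYS19 = 14, DYS385a = 11, DYS385b = 14,
               DYS393 = 12, DYS391 = 10, DYS439 = 11, DYS635 = 23,
               DYS392 = 13, YGATAH4 = 12, DYS437 = 15, DYS438 = 10,
               DYS448 = 19)

# one haplotype row with overrides, e.g. hap_row("s1", "P1", DYS391 = 11)
hap_row <- function(sample_id, population, ...) {
  h <- .base_hap
  over <- list(...)
  h[names(over)] <- unlist(over)
  cbind(data.frame(sample_id = sample_id, population = population,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(h), check.names = FALSE))
}

# dataset from a list of (population, overrides) specs; ids auto-numbered
hap_ds <- function(specs) {
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    do.call(hap_row, c(list(sample_id = sprintf("s%03d", i),
                            population = sp$population),
                       sp$alleles))
  })
  ystr_dataset(do.call(rbind, rows))
}

# n donors per population, all sharing the base haplotype
uniform_ds <- function(sizes) {
  sizes <- unlist(sizes)
  n <- sum(sizes)
  df <- cbind(data.frame(sample_id = sprintf("s%04d", seq_len(n)),
                         population = rep(names(sizes), sizes),
                         stringsAsFactors = FALSE),
              as.data.frame(lapply(.base_hap, rep, n), check.names = FALSE))
  ystr_dataset(df)
}

# session-cached fixtures (the iran-like profile takes ~15 s to simulate)
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(profile) {
  if (is.null(.fixture_cache[[profile]]))
    .fixture_cache[[profile]] <- make_fixture(profile)
  .fixture_cache[[profile]]
}

# --- independent AMOVA oracles -------------------------------------------

# brute force: explicit double loops over all N(N-1)/2 pairs of squared
# distances, then the two-level variance decomposition
brute_amova <- function(D2, group) {
  N <- length(group)
  pops <- unique(group)
  k <- length(pops)
  ss_total <- 0
  for (i in seq_len(N - 1)) for (j in seq(i + 1, N))
    ss_total <- ss_total + D2[i, j]
  ss_total <- ss_total / N
  ss_within <- 0
  for (p in pops) {
    idx <- which(group == p)
    acc <- 0
    if (length(idx) > 1)
      for (a in seq_len(length(idx) - 1)) for (b in seq(a + 1, length(idx)))
        acc <- acc + D2[idx[a], idx[b]]
    ss_within <- ss_within + acc / length(idx)
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1; df_within <- N - k
  sigma2_w <- ss_within / df_within
  sizes <- as.numeric(table(group)[pops])
  n_bar <- (N - sum(sizes^2) / N) / df_among
  sigma2_a <- (ss_among / df_among - sigma2_w) / n_bar
  phi <- if (sigma2_a + sigma2_w <= 0) 0 else sigma2_a / (sigma2_a + sigma2_w)
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w, phi = phi)
}

# identity-model route via haplotype indicator vectors: squared Euclidean
# deviations from group/grand centroids (sums of squares computed from
# centroids, not from pairwise distances; d2_identity = ||x_i - x_j||^2 / 2)
indicator_amova_ss <- function(keys, group) {
  lev <- unique(keys)
  X <- outer(keys, lev, "==") * 1
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2) / 2
  ss_within <- 0
  for (p in unique(group)) {
    idx <- which(group == p)
    cen <- colMeans(X[idx, , drop = FALSE])
    ss_within <- ss_within + sum(sweep(X[idx, , drop = FALSE], 2, cen)^2) / 2
  }
  list(ss_total = ss_total, ss_within = ss_within,
       ss_among = ss_total - ss_within)
}

# random small dataset for oracle property tests: haplotypes drawn from a
# small allele pool so sharing is common; 2-5 donors per population
random_small_ds <- function(k) {
  sizes <- sample(2:5, k, replace = TRUE)
  group <- rep(sprintf("P%d", seq_len(k)), sizes)
  rows <- lapply(seq_along(group), function(i)
    hap_row(sprintf("r%03d", i), group[i],
            DYS391 = sample(9:11, 1), DYS448 = sample(19:20, 1),
            DYS385a = sample(11:12, 1), DYS385b = sample(13:14, 1)))
  ystr_dataset(do.call(rbind, rows))
}
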