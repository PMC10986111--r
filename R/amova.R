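# Two-level AMOVA on haplotype distances and pairwise FST with permutation
# significance (Excoffier variance-component decomposition).

# Variance decomposition given a squared-distance matrix and group labels.
# SS_total = sum_{i<j} d2_ij / N ; SS_within = sum_g sum_{i<j in g} d2 / n_g ;
# sigma2_w = SS_w / (N - k) ; sigma2_a = (SS_a/(k-1) - sigma2_w) / n_bar with
# n_bar = (N - sum n_g^2 / N) / (k - 1), the unequal-size coefficient.
.amova_d2 <- function(D2, group) {
  group <- as.character(group)
  N <- length(group)
  sizes <- table(group)
  k <- length(sizes)
  if (k < 2)
    .ystr_stop("AMOVA needs at least 2 populations")
  if (any(sizes < 2))
    .ystr_stop("every population needs at least 2 complete haplotypes")
  ss_total <- sum(D2) / (2 * N)
  ss_within <- 0
  for (g in names(sizes)) {
    idx <- which(group == g)
    ss_within <- ss_within + sum(D2[idx, idx]) / (2 * length(idx))
  }
  ss_among <- ss_total - ss_within
  df_among <- k - 1L
  df_within <- N - k
  sigma2_w <- ss_within / df_within
  n_bar <- (N - sum(sizes^2) / N) / df_among
  sigma2_a <- (ss_among / df_among - sigma2_w) / n_bar
  degenerate <- ss_total <= .Machine$double.eps * N
  denom <- sigma2_a + sigma2_w
  phi <- if (degenerate || denom <= 0) 0 else sigma2_a / denom
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       df_among = df_among, df_within = df_within,
       sigma2_a = sigma2_a, sigma2_w = sigma2_w, n_bar = n_bar,
       phi = phi, degenerate = degenerate, N = N, k = k)
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions squared inter-haplotype distances into among- and
#' within-population sums of squares, derives the variance components
#' (with the standard unequal-sample-size coefficient n_bar) and the
#' fixation index Phi = sigma2_among / (sigma2_among + sigma2_within).
#' With identity distances Phi is a haplotype-frequency FST; with stepwise
#' distances it is an RST-like statistic on repeat counts.
#'
#' A negative among-population component can arise by sampling noise and is
#' reported as computed (Phi may be slightly negative). If the haplotypes
#' carry no variation at all, Phi is defined as 0 with `degenerate = TRUE`.
#'
#' @param ds a [ystr_dataset]; only complete haplotypes enter.
#' @param model distance model, see [haplotype_distance()].
#' @param populations optional character vector restricting (and ordering)
#'   the populations analysed.
#' @return Object of class `ystr_amova`: list with `ss_total`, `ss_among`,
#'   `ss_within`, `df_among`, `df_within`, `sigma2_a`, `sigma2_w`, `n_bar`,
#'   `phi`, `degenerate`, `N`, `k`, `model`.
#' @export
amova_two_level <- function(ds, model = c("identity", "stepwise"),
                            populations = NULL) {
  model <- match.arg(model)
  if (!is.null(populations)) {
    keep <- ds$data$population %in% populations
    if (!any(keep)) .ystr_stop("no donors in the requested populations")
    ds <- .ds_subset(ds, which(keep))
  }
  D2 <- distance_matrix(ds, model, squared = TRUE)
  res <- .amova_d2(D2, attr(D2, "population"))
  res$model <- model
  class(res) <- "ystr_amova"
  res
}

#' @export
print.ystr_amova <- function(x, ...) {
  cat(sprintf("Two-level AMOVA (%s distances): %d haplotypes, %d populations\n",
              x$model, x$N, x$k))
  tab <- data.frame(source = c("among populations", "within populations", "total"),
                    df = c(x$df_among, x$df_within, x$df_among + x$df_within),
                    SS = c(x$ss_among, x$ss_within, x$ss_total),
                    sigma2 = c(x$sigma2_a, x$sigma2_w, NA))
  print(tab, row.names = FALSE, digits = 6)
  cat(sprintf("Phi_ST = %.6f%s\n", x$phi,
              if (x$degenerate) " (degenerate: no variation)" else ""))
  invisible(x)
}

# Phi for a 2-group split of a fixed squared-distance matrix; constants
# precomputed so the permutation loop stays cheap.
.phi_pair <- function(D2, idx1, idx2, ss_total, df_within, n_bar) {
  n1 <- length(idx1); n2 <- length(idx2)
  ss_within <- sum(D2[idx1, idx1]) / (2 * n1) + sum(D2[idx2, idx2]) / (2 * n2)
  sigma2_w <- ss_within / df_within
  sigma2_a <- ((ss_total - ss_within) - sigma2_w) / n_bar  # df_among = 1
  denom <- sigma2_a + sigma2_w
  if (denom <= 0) 0 else sigma2_a / denom
}

#' Pairwise FST matrix with permutation p-values
#'
#' For every pair of populations, computes the two-level AMOVA Phi (see
#' [amova_two_level()]) and a one-sided permutation p-value obtained by
#' randomly reassigning the pair's individuals to the two labels, holding
#' the sample sizes fixed. The p-value carries the +1 correction,
#' p = (1 + #\{Phi_perm >= Phi_obs\}) / (B + 1), so it is bounded below by
#' 1/(B+1) and never exactly zero. No multiple-testing correction is
#' applied to the matrix; a Bonferroni-adjusted copy is emitted alongside
#' by [run_report()].
#'
#' @param ds a [ystr_dataset] with at least two populations, each holding
#'   at least 2 complete haplotypes.
#' @param model distance model, see [haplotype_distance()].
#' @param B number of permutations (default 10000).
#' @param seed integer seed; mandatory, so every p-value is reproducible.
#' @return Object of class `ystr_fst`: list with `population_ids`, `values`
#'   (symmetric k x k Phi matrix, zero diagonal, negatives kept as
#'   computed), `pvalues` (NA diagonal), `B`, `seed`, `model`.
#' @export
pairwise_fst_matrix <- function(ds, model = c("identity", "stepwise"),
                                B = 10000L, seed = NULL) {
  model <- match.arg(model)
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    .ystr_stop("a seed is required for permutation p-values",
               "ystr_config_error")
  B <- as.integer(B)
  if (is.na(B) || B < 1L)
    .ystr_stop("B must be a positive integer", "ystr_config_error")
  pops <- unique(ds$data$population)
  k <- length(pops)
  if (k < 2) .ystr_stop("need at least 2 populations")

  D2 <- distance_matrix(ds, model, squared = TRUE)
  labels <- attr(D2, "population")
  idx_by_pop <- split(seq_along(labels), labels)[pops]
  small <- names(which(vapply(idx_by_pop, length, 0L) < 2))
  if (length(small) > 0)
    .ystr_stop(sprintf("population(s) with <2 complete haplotypes: %s",
                       paste(small, collapse = ", ")))

  values <- matrix(0, k, k, dimnames = list(pops, pops))
  pvalues <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  set.seed(as.integer(seed))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    idx <- c(idx_by_pop[[i]], idx_by_pop[[j]])
    n1 <- length(idx_by_pop[[i]]); n <- length(idx)
    D2p <- D2[idx, idx]
    N <- n; sizes <- c(n1, n - n1)
    ss_total <- sum(D2p) / (2 * N)
    df_within <- N - 2L
    n_bar <- N - sum(sizes^2) / N  # df_among = 1
    obs <- .phi_pair(D2p, seq_len(n1), seq(n1 + 1, n),
                     ss_total, df_within, n_bar)
    hits <- 0L
    for (b in seq_len(B)) {
      g1 <- sample.int(n, n1)
      phi_b <- .phi_pair(D2p, g1, setdiff(seq_len(n), g1),
                         ss_total, df_within, n_bar)
      if (phi_b >= obs - 1e-12) hits <- hits + 1L
    }
    values[i, j] <- values[j, i] <- obs
    pvalues[i, j] <- pvalues[j, i] <- (1 + hits) / (B + 1)
  }
  structure(list(population_ids = pops, values = values, pvalues = pvalues,
                 B = B, seed = as.integer(seed), model = model),
            class = "ystr_fst")
}

#' @export
print.ystr_fst <- function(x, ...) {
  cat(sprintf("Pairwise FST (%s distances), %d populations, B = %d permutations, seed = %d\n",
              x$model, length(x$population_ids), x$B, x$seed))
  print(round(x$values, 4))
  cat("permutation p-values:\n")
  print(round(x$pvalues, 4))
  invisible(x)
}
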