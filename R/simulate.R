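# Forward-time patrilineal Wright-Fisher simulator with stepwise-mutating
# Y-STR haplotypes. Generates synthetic multi-population tables with the
# statistical structure the analysis assumes, plus a truth log.

#' Simulation configuration
#'
#' Describes a forward Wright-Fisher simulation of `k` patrilineal
#' populations of constant effective size `Ne` (haploid males), evolving
#' for `generations` generations under the island model: each offspring
#' draws its father from its own deme with probability `1 - migration_rate`
#' and from a uniformly chosen *other* deme otherwise. Each allele copy
#' mutates independently per generation with probability `mu` under the
#' stepwise mutation model (+/-1 repeat with equal probability, reflecting
#' at the panel bounds; microvariant fractional parts are preserved).
#'
#' The founding state is either a single founder haplotype (`founder`,
#' default panel midpoints: classic mutation--drift build-up) or, via
#' `founder_freqs`, per-column allele distributions from which the initial
#' alleles are drawn i.i.d. The latter seeds standing variation so that
#' realistic diversity levels are reached in tens rather than thousands of
#' generations, which is what the packaged fixtures use.
#'
#' @param k number of populations.
#' @param n_sample donors sampled per population at the end (scalar or
#'   length-k vector); must not exceed `Ne`.
#' @param Ne patrilineal effective size per population.
#' @param generations number of non-overlapping generations to evolve.
#' @param migration_rate island-model migration probability per offspring
#'   per generation, in \[0, 1\].
#' @param mu per-locus mutation rate per generation: scalar or one value
#'   per reported column (default 2e-3, a typical Y-STR locus rate).
#' @param panel a [ystr_panel].
#' @param founder named allele vector over the reported columns (default:
#'   rounded panel midpoints).
#' @param founder_freqs optional named list (per reported column) of named
#'   probability vectors over allele values; overrides `founder`.
#' @param pop_names optional population labels (default "P01", "P02", ...).
#' @param seed integer seed; mandatory, the simulation is fully
#'   reproducible from it.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(k, n_sample, Ne, generations, migration_rate = 0,
                       mu = 2e-3, panel = yfiler_panel(), founder = NULL,
                       founder_freqs = NULL, pop_names = NULL, seed = NULL) {
  if (is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    .ystr_stop("sim_config requires an integer seed", "ystr_config_error")
  k <- as.integer(k); Ne <- as.integer(Ne)
  generations <- as.integer(generations)
  if (k < 1L || Ne < 2L || generations < 0L)
    .ystr_stop("need k >= 1, Ne >= 2, generations >= 0", "ystr_config_error")
  if (migration_rate < 0 || migration_rate > 1)
    .ystr_stop("migration_rate must lie in [0, 1]", "ystr_config_error")
  if (k == 1L && migration_rate > 0)
    .ystr_stop("migration needs at least 2 populations", "ystr_config_error")
  n_sample <- as.integer(rep_len(n_sample, k))
  if (any(n_sample < 1L) || any(n_sample > Ne))
    .ystr_stop("n_sample must lie in [1, Ne] for every population",
               "ystr_config_error")
  cols <- panel_columns(panel)
  mu <- rep_len(as.numeric(mu), length(cols))
  if (any(mu < 0) || any(mu > 1))
    .ystr_stop("mu must lie in [0, 1]", "ystr_config_error")
  names(mu) <- cols
  info <- .panel_column_info(panel)
  if (is.null(founder)) {
    founder <- stats::setNames(round((info$allele_min + info$allele_max) / 2),
                               cols)
  } else {
    founder <- unlist(founder)[cols]
    if (anyNA(founder))
      .ystr_stop("founder must cover every reported column",
                 "ystr_config_error")
  }
  if (!is.null(founder_freqs)) {
    if (!all(cols %in% names(founder_freqs)))
      .ystr_stop("founder_freqs must cover every reported column",
                 "ystr_config_error")
    founder_freqs <- founder_freqs[cols]
    for (cc in cols) {
      f <- founder_freqs[[cc]]
      if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-8)
        .ystr_stop(sprintf("founder_freqs[[%s]] must be a named probability vector", cc),
                   "ystr_config_error")
    }
  }
  if (is.null(pop_names)) pop_names <- sprintf("P%02d", seq_len(k))
  if (length(pop_names) != k || anyDuplicated(pop_names))
    .ystr_stop("pop_names must be k unique labels", "ystr_config_error")
  structure(list(k = k, n_sample = n_sample, Ne = Ne,
                 generations = generations,
                 migration_rate = migration_rate, mu = mu, panel = panel,
                 founder = founder, founder_freqs = founder_freqs,
                 pop_names = pop_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Apply one round of stepwise mutation to a haplotype
#'
#' Each allele copy mutates independently with probability `mu`; a mutation
#' moves the allele by one full repeat unit up or down with equal
#' probability, reflecting at the panel bounds (an allele at the minimum
#' that mutates must step up), so microvariant fractional parts survive.
#' Draws come from R's global RNG; call `set.seed()` for reproducibility.
#'
#' @param h named numeric allele vector over the panel's reported columns.
#' @param panel a [ystr_panel].
#' @param mu mutation probability per allele copy (scalar or per column).
#' @return The mutated allele vector.
#' @export
mutate_haplotype <- function(h, panel = yfiler_panel(), mu = 2e-3) {
  cols <- panel_columns(panel)
  h <- unlist(h)[cols]
  if (anyNA(h)) .ystr_stop("haplotype must be complete")
  mu <- rep_len(as.numeric(mu), length(cols))
  info <- .panel_column_info(panel)
  m <- .mutate_matrix(matrix(h, nrow = 1), mu, info$allele_min, info$allele_max)
  stats::setNames(drop(m), cols)
}

# SMM step on an Ne x C allele matrix; lo/hi per column. Each copy mutates
# independently with its column's mu, so the per-column mutant count is
# Binomial(n, mu) with uniform positions — drawn directly, which keeps the
# cost proportional to the number of mutations rather than to n*C.
.mutate_matrix <- function(mat, mu_col, lo, hi) {
  n <- nrow(mat)
  counts <- stats::rbinom(length(mu_col), n, mu_col)
  for (j in which(counts > 0L)) {
    rows <- if (counts[j] == n) seq_len(n) else sample.int(n, counts[j])
    step <- ifelse(stats::runif(counts[j]) < 0.5, -1, 1)
    old <- mat[rows, j]
    val <- old + step
    low <- val < lo[j]; high <- val > hi[j]
    val[low] <- old[low] + 1
    val[high] <- old[high] - 1
    mat[rows, j] <- val
  }
  mat
}

#' Simulate a multi-population Y-STR dataset
#'
#' Runs the forward Wright-Fisher process described by a [sim_config()]:
#' every generation each deme draws `Ne` fathers multinomially (island-model
#' migration included), then every allele copy undergoes stepwise mutation.
#' Patriline (founder-lineage) identities are tracked throughout. At the
#' end, `n_sample` donors are drawn without replacement per deme.
#'
#' @param cfg a [sim_config()].
#' @return List with elements
#'   \describe{
#'     \item{dataset}{a [ystr_dataset] (two-copy pairs sorted on output).}
#'     \item{truth}{the generator's truth log: `config`, `allele_freqs`
#'       (per population, per column, full-deme frequencies at the final
#'       generation), `lineage_counts` (surviving founder patrilines per
#'       deme), `sampled_rows` (deme row indices sampled).}
#'   }
#'   The run is bit-reproducible from `cfg$seed` (RNG state is saved and
#'   restored around the call).
#' @export
simulate_dataset <- function(cfg) {
  if (!inherits(cfg, "sim_config"))
    .ystr_stop("cfg must be a sim_config", "ystr_config_error")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  cols <- panel_columns(cfg$panel)
  C <- length(cols)
  info <- .panel_column_info(cfg$panel)
  lo <- info$allele_min; hi <- info$allele_max
  k <- cfg$k; Ne <- cfg$Ne; m <- cfg$migration_rate

  init_deme <- function() {
    if (is.null(cfg$founder_freqs)) {
      matrix(rep(cfg$founder, each = Ne), Ne, C)
    } else {
      mat <- matrix(0, Ne, C)
      for (j in seq_len(C)) {
        f <- cfg$founder_freqs[[cols[j]]]
        mat[, j] <- as.numeric(sample(names(f), Ne, replace = TRUE, prob = f))
      }
      mat
    }
  }
  demes <- lapply(seq_len(k), function(i) init_deme())
  lineages <- lapply(seq_len(k), function(i) (i - 1L) * Ne + seq_len(Ne))

  for (g in seq_len(cfg$generations)) {
    new_demes <- demes; new_lineages <- lineages
    for (i in seq_len(k)) {
      src <- rep.int(i, Ne)
      if (m > 0 && k > 1L) {
        mig <- which(stats::runif(Ne) < m)
        if (length(mig) > 0L) {
          others <- seq_len(k)[-i]
          src[mig] <- others[sample.int(k - 1L, length(mig), replace = TRUE)]
        }
      }
      parent <- sample.int(Ne, Ne, replace = TRUE)
      mat <- matrix(0, Ne, C); lin <- integer(Ne)
      for (d in unique(src)) {
        sel <- src == d
        mat[sel, ] <- demes[[d]][parent[sel], , drop = FALSE]
        lin[sel] <- lineages[[d]][parent[sel]]
      }
      new_demes[[i]] <- .mutate_matrix(mat, cfg$mu, lo, hi)
      new_lineages[[i]] <- lin
    }
    demes <- new_demes; lineages <- new_lineages
  }

  rows <- vector("list", k)
  sampled_rows <- vector("list", k)
  for (i in seq_len(k)) {
    take <- sample.int(Ne, cfg$n_sample[i])
    sampled_rows[[i]] <- take
    d <- as.data.frame(demes[[i]][take, , drop = FALSE])
    names(d) <- cols
    d <- cbind(sample_id = sprintf("%s_%04d", cfg$pop_names[i],
                                   seq_len(cfg$n_sample[i])),
               population = cfg$pop_names[i], d,
               stringsAsFactors = FALSE)
    rows[[i]] <- d
  }
  ds <- ystr_dataset(do.call(rbind, rows), cfg$panel)

  truth <- list(
    config = cfg,
    allele_freqs = stats::setNames(lapply(seq_len(k), function(i) {
      stats::setNames(lapply(seq_len(C), function(j) {
        tab <- table(demes[[i]][, j])
        stats::setNames(as.numeric(tab) / Ne, names(tab))
      }), cols)
    }), cfg$pop_names),
    lineage_counts = stats::setNames(
      vapply(lineages, function(l) length(unique(l)), 0L), cfg$pop_names),
    sampled_rows = stats::setNames(sampled_rows, cfg$pop_names)
  )
  list(dataset = ds, truth = truth)
}

# discretised double-geometric allele distribution over [lo, hi] centred at
# mid, with decay rho solved so that 1 - sum(p^2) == target_gd
.geom_founder_freqs <- function(lo, hi, target_gd) {
  vals <- seq(floor(lo), ceiling(hi))
  mid <- vals[ceiling(length(vals) / 2)]
  gd_of <- function(rho) {
    w <- rho^abs(vals - mid)
    p <- w / sum(w)
    1 - sum(p^2)
  }
  max_gd <- gd_of(1)
  if (target_gd >= max_gd)
    .ystr_stop(sprintf("target GD %.3f unreachable on %d alleles", target_gd,
                       length(vals)), "ystr_config_error")
  rho <- stats::uniroot(function(r) gd_of(r) - target_gd,
                        c(1e-9, 1), tol = 1e-12)$root
  w <- rho^abs(vals - mid)
  stats::setNames(w / sum(w), as.character(vals))
}

# per-province donor counts of the emulated 16-population study design
.iran_sizes <- function() {
  c(Tehran = 236L, Isfahan = 153L, Golestan = 82L, Mazandaran = 102L,
    Gilan = 77L, Tabriz = 41L, Urmia = 53L, Kermanshah = 75L,
    Kurdistan = 50L, Ilam = 55L, Hamedan = 34L, Fars = 105L,
    Khuzestan = 34L, KhorasanRazavi = 127L, SouthKhorasan = 27L,
    SistanBaluchestan = 102L)
}

# per-column initial GD targets for the iran-like fixture: DYS391 least
# polymorphic, DYS385 most, the rest spread over the mid band
.iran_gd_targets <- function() {
  c(DYS456 = 0.62, DYS389I = 0.55, DYS390 = 0.70, DYS389II = 0.66,
    DYS458 = 0.72, DYS19 = 0.58, DYS385a = 0.87, DYS385b = 0.87,
    DYS393 = 0.48, DYS391 = 0.34, DYS439 = 0.60, DYS635 = 0.56,
    YGATAH4 = 0.50, DYS392 = 0.52, DYS437 = 0.45, DYS438 = 0.55,
    DYS448 = 0.65)
}

#' Packaged synthetic fixtures
#'
#' Deterministic synthetic datasets used throughout the tests and examples.
#' \describe{
#'   \item{`"iran-like"`}{16 populations named after provinces with the
#'     emulated study's sample sizes (27--236 donors, N = 1353 in total),
#'     simulated with standing founder variation shaped so per-column gene
#'     diversity falls in roughly \[0.3, 0.9\] (DYS391 least, DYS385a/b most
#'     polymorphic), moderate inter-province gene flow, and essentially all
#'     haplotypes unique (HD > 0.99). The truth log travels in
#'     `attr(ds, "truth")`.}
#'   \item{`"tiny"`}{3 populations x 10 donors, for quick oracle tests.}
#' }
#'
#' @param profile `"iran-like"` or `"tiny"`.
#' @param seed integer seed; the defaults make each fixture a fixed object.
#' @return A [ystr_dataset] with the simulation truth log attached as
#'   attribute `truth`.
#' @export
make_fixture <- function(profile = c("iran-like", "tiny"), seed = NULL) {
  profile <- match.arg(profile)
  panel <- yfiler_panel()
  info <- .panel_column_info(panel)
  if (profile == "iran-like") {
    if (is.null(seed)) seed <- 1353L
    targets <- .iran_gd_targets()[info$column]
    freqs <- stats::setNames(lapply(seq_len(nrow(info)), function(j)
      .geom_founder_freqs(info$allele_min[j], info$allele_max[j], targets[j])),
      info$column)
    sizes <- .iran_sizes()
    # large demes + short drift: with ~80k within-province donor pairs, the
    # expected number of shared patrilines is ~ pairs * generations / Ne, so
    # Ne >> n_sample and few generations keep >=99% of haplotypes unique
    # (real patrilineal populations are effectively huge on this timescale)
    cfg <- sim_config(k = 16L, n_sample = unname(sizes), Ne = 50000L,
                      generations = 3L, migration_rate = 0.05, mu = 4e-3,
                      panel = panel, founder_freqs = freqs,
                      pop_names = names(sizes), seed = seed)
  } else {
    if (is.null(seed)) seed <- 7L
    freqs <- stats::setNames(lapply(seq_len(nrow(info)), function(j)
      .geom_founder_freqs(info$allele_min[j], info$allele_max[j], 0.6)),
      info$column)
    cfg <- sim_config(k = 3L, n_sample = 10L, Ne = 30L, generations = 40L,
                      migration_rate = 0.05, mu = 2e-3, panel = panel,
                      founder_freqs = freqs, seed = seed)
  }
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  attr(ds, "truth") <- sim$truth
  ds
}

#' Deterministic all-distinct haplotype dataset
#'
#' Builds n haplotypes guaranteed pairwise distinct by stepping the first
#' few columns through their integer allele ranges as a mixed-radix
#' counter (all values in-range; no randomness). Useful for closed-form
#' checks: with every haplotype unique, Nei haplotype diversity is exactly
#' 1 for any n and discrimination capacity is exactly 1.
#'
#' @param sizes named integer vector of donors per population (names become
#'   population labels), or a single total n.
#' @param panel a [ystr_panel].
#' @return A [ystr_dataset] with `sum(sizes)` pairwise-distinct haplotypes.
#' @export
make_unique_haplotypes <- function(sizes, panel = yfiler_panel()) {
  if (is.null(names(sizes)) && length(sizes) == 1L)
    sizes <- c(POP = as.integer(sizes))
  sizes <- stats::setNames(as.integer(sizes), names(sizes))
  n <- sum(sizes)
  if (n < 1L) .ystr_stop("need at least one donor", "ystr_config_error")
  info <- .panel_column_info(panel)
  vals <- lapply(seq_len(nrow(info)), function(j)
    seq(ceiling(info$allele_min[j]), floor(info$allele_max[j])))
  base <- vapply(vals, function(v) v[1L], numeric(1))
  radix <- vapply(vals, length, integer(1))
  use <- which(cumprod(radix) < n)
  use <- seq_len(min(length(use) + 1L, length(radix)))
  if (prod(radix[use]) < n)
    .ystr_stop("panel allele space too small for n distinct haplotypes",
               "ystr_config_error")
  mat <- matrix(rep(base, each = n), n, length(base))
  idx <- seq_len(n) - 1L
  for (j in use) {
    mat[, j] <- vals[[j]][(idx %% radix[j]) + 1L]
    idx <- idx %/% radix[j]
  }
  colnames(mat) <- info$column
  df <- data.frame(sample_id = sprintf("U%05d", seq_len(n)),
                   population = rep(names(sizes), sizes),
                   mat, check.names = FALSE, stringsAsFactors = FALSE)
  ystr_dataset(df, panel)
}
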