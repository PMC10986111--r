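# Nei diversity statistics: per-locus gene diversity, haplotype diversity,
# discrimination capacity, haplotype match probability.

#' Nei's unbiased gene diversity
#'
#' Computes GD = (n/(n-1)) * (1 - sum(p_i^2)) from allele counts, where
#' n is the number of gene copies and p_i the relative allele frequencies.
#' This is the unbiased heterozygosity estimator standard in Y-STR reports;
#' applied to whole-haplotype counts it gives haplotype diversity.
#'
#' @param counts numeric vector of non-negative allele (or haplotype)
#'   counts; zero entries are ignored.
#' @return GD in \[0, 1\]; exactly 0 iff monomorphic.
#' @examples
#' gene_diversity(c(5, 3, 2))  # (10/9)*(1 - .25 - .09 - .04) = 0.68889
#' @export
gene_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    .ystr_stop("counts must be non-negative and non-missing",
               "ystr_domain_error")
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2)
    .ystr_stop("gene diversity is undefined for fewer than 2 gene copies",
               "ystr_domain_error")
  p <- counts / n
  gd <- n / (n - 1) * (1 - sum(p^2))
  min(max(gd, 0), 1)
}

# complete-row subset for a scope ("ALL" or one population id)
.scope_rows <- function(ds, population) {
  keep <- complete_haplotypes(ds)
  if (!is.null(population) && !identical(population, "ALL")) {
    if (!population %in% ds$data$population)
      .ystr_stop(sprintf("unknown population: %s", population))
    keep <- keep & ds$data$population == population
  }
  which(keep)
}

#' Haplotype diversity
#'
#' Nei's unbiased estimator applied to whole-haplotype frequencies (keys
#' from [haplotype_keys()]). Equals 1 to machine precision whenever all
#' haplotypes are distinct, for any n, since
#' (n/(n-1)) * (1 - n * (1/n)^2) = 1.
#'
#' @param ds a [ystr_dataset].
#' @param population restrict to one population id; `NULL` (or `"ALL"`)
#'   pools the whole dataset. Only complete haplotypes are used.
#' @return HD in \[0, 1\].
#' @export
haplotype_diversity <- function(ds, population = NULL) {
  rows <- .scope_rows(ds, population)
  if (length(rows) < 2)
    .ystr_stop("haplotype diversity needs at least 2 complete haplotypes",
               "ystr_domain_error")
  gene_diversity(table(haplotype_keys(ds, rows)))
}

#' Discrimination capacity
#'
#' The number of distinct haplotypes divided by the number of (complete)
#' haplotypes sampled: the fraction of donors a haplotype lookup can tell
#' apart. DC = 1 when all haplotypes are unique.
#'
#' @inheritParams haplotype_diversity
#' @return DC in (0, 1\].
#' @export
discrimination_capacity <- function(ds, population = NULL) {
  rows <- .scope_rows(ds, population)
  if (length(rows) < 1)
    .ystr_stop("discrimination capacity needs at least 1 complete haplotype",
               "ystr_domain_error")
  keys <- haplotype_keys(ds, rows)
  length(unique(keys)) / length(keys)
}

#' Haplotype match probability
#'
#' The chance that two randomly drawn males share a haplotype:
#' HMP = 1 - HD, the exact complement of haplotype diversity.
#'
#' @param hd haplotype diversity value in \[0, 1\].
#' @return HMP = 1 - hd.
#' @export
match_probability <- function(hd) {
  if (!is.numeric(hd) || length(hd) != 1L || is.na(hd) || hd < 0 || hd > 1)
    .ystr_stop("hd must be a single value in [0, 1]", "ystr_domain_error")
  1 - hd
}

# allele counts for one reported column over given rows (non-missing calls)
.column_counts <- function(ds, column, rows = seq_len(nrow(ds$data))) {
  v <- ds$data[[column]][rows]
  table(v[!is.na(v)])
}

#' Per-column allele frequencies
#'
#' Relative allele frequencies per reported column, from all non-missing
#' calls in the scope (incomplete haplotypes contribute their clean loci).
#' With `combine_dys385 = TRUE` the two calls of any two-copy locus are
#' pooled into a single 2n-gene-copy frequency table under the locus name.
#'
#' @inheritParams haplotype_diversity
#' @param combine_dys385 pool two-copy loci into one column.
#' @return Named list: per column, a named numeric vector of frequencies
#'   summing to 1.
#' @export
allele_frequencies <- function(ds, population = NULL, combine_dys385 = FALSE) {
  d <- ds$data
  rows <- seq_len(nrow(d))
  if (!is.null(population) && !identical(population, "ALL")) {
    if (!population %in% d$population)
      .ystr_stop(sprintf("unknown population: %s", population))
    rows <- which(d$population == population)
  }
  cols <- .gd_columns(ds$panel, combine_dys385)
  out <- lapply(cols$members, function(mem) {
    v <- unlist(d[rows, mem, drop = FALSE], use.names = FALSE)
    cnt <- table(v[!is.na(v)])
    if (sum(cnt) == 0) return(stats::setNames(numeric(0), character(0)))
    freq <- as.numeric(cnt) / sum(cnt)
    stats::setNames(freq, names(cnt))
  })
  stats::setNames(out, cols$name)
}

# GD column layout: split (17 columns) or combined two-copy loci
.gd_columns <- function(panel, combine = FALSE) {
  if (!combine) {
    cols <- panel_columns(panel)
    list(name = cols, members = as.list(cols))
  } else {
    list(name = panel$locus,
         members = lapply(seq_len(nrow(panel)), function(i)
           if (panel$copies[i] == 2L) paste0(panel$locus[i], c("a", "b"))
           else panel$locus[i]))
  }
}

#' Gene-diversity matrix across populations and loci
#'
#' Computes Nei GD for every reported column within every population and in
#' the pooled sample, and reports the extreme cells and the pooled mean
#' across columns. By default DYS385a (smaller allele of the sorted pair)
#' and DYS385b are two separate columns, matching how duplicated loci are
#' reported in forensic summaries; `combine_dys385 = TRUE` instead pools
#' the pair into 2n gene copies.
#'
#' Populations with fewer than 2 non-missing calls at any column cannot
#' support the unbiased estimator there and are excluded with a warning.
#'
#' @inheritParams allele_frequencies
#' @return An object of class `ystr_gd_matrix`: list with `gd` (populations
#'   x columns matrix), `pooled` (per-column GD of the pooled sample),
#'   `pooled_mean` (mean of `pooled` across columns), and `min`/`max`
#'   (lists `column`, `population`, `value` over the per-population cells).
#' @export
gd_matrix <- function(ds, combine_dys385 = FALSE) {
  cols <- .gd_columns(ds$panel, combine_dys385)
  pops <- unique(ds$data$population)
  d <- ds$data

  col_gd <- function(rows) vapply(cols$members, function(mem) {
    v <- unlist(d[rows, mem, drop = FALSE], use.names = FALSE)
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    gene_diversity(table(v))
  }, numeric(1))

  rows_by_pop <- split(seq_len(nrow(d)), d$population)[pops]
  gd_rows <- lapply(rows_by_pop, col_gd)
  usable <- !vapply(gd_rows, anyNA, logical(1))
  if (any(!usable))
    warning(sprintf("excluded population(s) with <2 calls at some column: %s",
                    paste(pops[!usable], collapse = ", ")), call. = FALSE)
  if (!any(usable))
    .ystr_stop("no population supports per-locus gene diversity")
  gd <- do.call(rbind, gd_rows[usable])
  dimnames(gd) <- list(pops[usable], cols$name)

  pooled <- col_gd(seq_len(nrow(d)))
  names(pooled) <- cols$name
  which_cell <- function(f) {
    idx <- which(gd == f(gd), arr.ind = TRUE)[1, ]
    list(column = colnames(gd)[idx[2]], population = rownames(gd)[idx[1]],
         value = gd[idx[1], idx[2]])
  }
  structure(list(gd = gd, pooled = pooled,
                 pooled_mean = mean(pooled, na.rm = TRUE),
                 min = which_cell(min), max = which_cell(max)),
            class = "ystr_gd_matrix")
}

#' @export
print.ystr_gd_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Gene diversity: %d populations x %d columns\n",
              nrow(x$gd), ncol(x$gd)))
  cat(sprintf("  range %.3f (%s in %s) to %.3f (%s in %s); pooled mean %.3f\n",
              x$min$value, x$min$column, x$min$population,
              x$max$value, x$max$column, x$max$population, x$pooled_mean))
  print(round(x$gd, digits))
  invisible(x)
}

#' Per-population diversity summary
#'
#' One row per population plus a pooled `ALL` row, with the sample size,
#' number of complete haplotypes, number of distinct haplotypes h, Nei
#' haplotype diversity HD, discrimination capacity DC = h / n_complete, and
#' haplotype match probability HMP = 1 - HD. Populations with fewer than 2
#' complete haplotypes get `NA` for HD/HMP (DC needs only 1).
#'
#' @param ds a [ystr_dataset].
#' @return data.frame of class `ystr_diversity_summary` with columns
#'   `scope`, `n`, `n_complete`, `h`, `HD`, `DC`, `HMP` (full precision;
#'   rounding profiles are applied only when reports are written).
#' @export
diversity_summary <- function(ds) {
  scopes <- c(unique(ds$data$population), "ALL")
  complete <- complete_haplotypes(ds)
  rows <- lapply(scopes, function(s) {
    in_scope <- if (s == "ALL") rep(TRUE, nrow(ds$data))
                else ds$data$population == s
    idx <- which(in_scope & complete)
    h <- if (length(idx) >= 1) length(unique(haplotype_keys(ds, idx))) else NA_integer_
    hd <- if (length(idx) >= 2) haplotype_diversity(ds, if (s == "ALL") NULL else s)
          else NA_real_
    data.frame(scope = s, n = sum(in_scope), n_complete = length(idx),
               h = h,
               HD = hd,
               DC = if (length(idx) >= 1) h / length(idx) else NA_real_,
               HMP = if (is.na(hd)) NA_real_ else match_probability(hd),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ystr_diversity_summary", "data.frame")
  out
}
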