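# The haplotype dataset container: one row per male donor, one numeric
# column per reported panel column, plus sample and population identifiers.

#' Construct a validated Y-STR haplotype dataset
#'
#' The central container of the package. `data` holds one row per donor with
#' a `sample_id`, a `population` label and one numeric allele column (repeat
#' units; microvariants keep their exact decimal part) per reported panel
#' column. Construction enforces the data model:
#' \itemize{
#'   \item sample identifiers are unique;
#'   \item the DYS385 (or any two-copy locus) pair is stored sorted
#'     ascending, whatever order it arrived in;
#'   \item alleles outside the panel bounds are not rejected but recorded in
#'     the `flags` attribute (`attr(ds, "flags")`), one row per offending
#'     call, so validity bookkeeping is never silent;
#'   \item a `complete` indicator marks rows with no missing allele —
#'     haplotype-level statistics use complete rows only, while per-locus
#'     statistics use every non-missing call.
#' }
#'
#' @param data data.frame with columns `sample_id`, `population`, then the
#'   allele columns named as in [panel_columns()].
#' @param panel a [ystr_panel]; defaults to [yfiler_panel()].
#' @return An object of class `ystr_dataset`: a list with elements `panel`
#'   and `data` (allele columns numeric, multicopy pairs sorted), carrying a
#'   `flags` attribute with out-of-range calls.
#' @examples
#' df <- data.frame(sample_id = c("s1", "s2"), population = "P1",
#'                  DYS456 = c(15, 16), DYS389I = 13, DYS390 = 24,
#'                  DYS389II = 29, DYS458 = 17, DYS19 = 14, DYS385a = 14,
#'                  DYS385b = 11, DYS393 = 12, DYS391 = 10, DYS439 = 11,
#'                  DYS635 = 23, DYS392 = 13, YGATAH4 = 12, DYS437 = 15,
#'                  DYS438 = 10, DYS448 = 19)
#' ds <- ystr_dataset(df)
#' ds$data$DYS385a  # pair re-sorted ascending: 11 11
#' @export
ystr_dataset <- function(data, panel = yfiler_panel()) {
  data <- as.data.frame(data)
  for (col in c("sample_id", "population")) {
    if (!col %in% names(data))
      .ystr_stop(sprintf("missing required column: %s", col),
                 "ystr_format_error")
    data[[col]] <- as.character(data[[col]])
  }
  cols <- panel_columns(panel)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L)
    .ystr_stop(sprintf("missing allele column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "ystr_format_error")
  if (nrow(data) == 0L)
    .ystr_stop("dataset has no rows", "ystr_validation_error")
  dup <- data$sample_id[duplicated(data$sample_id)]
  if (length(dup) > 0L)
    .ystr_stop(sprintf("duplicate sample_id: %s",
                       paste(unique(dup), collapse = ", ")))
  if (anyNA(data$population) || any(data$population == ""))
    .ystr_stop("every row needs a non-empty population label")
  data <- data[c("sample_id", "population", cols)]
  for (col in cols) data[[col]] <- as.numeric(data[[col]])

  # sort each two-copy pair ascending; a half-missing pair is left as given
  for (i in which(panel$copies == 2L)) {
    ca <- paste0(panel$locus[i], "a"); cb <- paste0(panel$locus[i], "b")
    swap <- !is.na(data[[ca]]) & !is.na(data[[cb]]) & data[[ca]] > data[[cb]]
    if (any(swap)) {
      tmp <- data[[ca]][swap]
      data[[ca]][swap] <- data[[cb]][swap]
      data[[cb]][swap] <- tmp
    }
  }

  info <- .panel_column_info(panel)
  flags <- do.call(rbind, lapply(seq_len(nrow(info)), function(j) {
    v <- data[[info$column[j]]]
    bad <- which(!is.na(v) & (v < info$allele_min[j] | v > info$allele_max[j]))
    if (length(bad) == 0L) return(NULL)
    data.frame(sample_id = data$sample_id[bad], column = info$column[j],
               value = v[bad], stringsAsFactors = FALSE)
  }))
  if (is.null(flags))
    flags <- data.frame(sample_id = character(), column = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  rownames(data) <- NULL
  ds <- structure(list(panel = panel, data = data),
                  class = "ystr_dataset", flags = flags)
  ds
}

#' Dataset bookkeeping helpers
#'
#' `pop_sizes()` returns the number of donors per population (in order of
#' first appearance), `n_donors()` the total N, and `complete_haplotypes()`
#' the logical indicator of rows with no missing allele call.
#'
#' @param ds a [ystr_dataset].
#' @return Named integer vector, integer, and logical vector respectively.
#' @export
pop_sizes <- function(ds) {
  pops <- unique(ds$data$population)
  stats::setNames(as.integer(table(ds$data$population)[pops]), pops)
}

#' @rdname pop_sizes
#' @export
n_donors <- function(ds) nrow(ds$data)

#' @rdname pop_sizes
#' @export
complete_haplotypes <- function(ds) {
  cols <- panel_columns(ds$panel)
  stats::complete.cases(ds$data[cols])
}

# subset a dataset to given row indices (keeps class/panel; flags dropped)
.ds_subset <- function(ds, idx) {
  structure(list(panel = ds$panel, data = ds$data[idx, , drop = FALSE]),
            class = "ystr_dataset",
            flags = attr(ds, "flags"))
}

#' Canonical haplotype keys
#'
#' Serialises each complete haplotype to a deterministic string over the
#' panel's reported column order (two-copy pairs already stored ascending),
#' so two donors match if and only if all 17 allele values match. The key is
#' the unit for counting distinct haplotypes.
#'
#' @param ds a [ystr_dataset].
#' @param rows optional integer/logical row selector; every selected row
#'   must be complete.
#' @return Character vector of keys, one per selected row.
#' @export
haplotype_keys <- function(ds, rows = NULL) {
  cols <- panel_columns(ds$panel)
  d <- ds$data
  if (!is.null(rows)) d <- d[rows, , drop = FALSE]
  if (anyNA(d[cols]))
    .ystr_stop("haplotype keys require complete haplotypes (no missing alleles)")
  do.call(paste, c(lapply(d[cols], as.character), sep = "|"))
}

#' @export
print.ystr_dataset <- function(x, ...) {
  sizes <- pop_sizes(x)
  cat(sprintf("Y-STR haplotype dataset: %d donors, %d populations, %d reported columns\n",
              n_donors(x), length(sizes), length(panel_columns(x$panel))))
  cat(sprintf("  complete haplotypes: %d; out-of-range calls flagged: %d\n",
              sum(complete_haplotypes(x)), nrow(attr(x, "flags"))))
  cat("  populations: ",
      paste(sprintf("%s (%d)", names(sizes), sizes), collapse = ", "), "\n")
  invisible(x)
}
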