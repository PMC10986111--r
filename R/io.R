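# Delimited-text input/output for haplotype tables.

.table_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.norm_colname <- function(x) toupper(gsub("[ _.-]", "", x))

#' Read a Y-STR haplotype table
#'
#' Reads a delimited text file (TSV or CSV, auto-detected by extension;
#' UTF-8; header required) with columns `SampleID`, `Population` and the
#' panel's allele columns. Column matching is case- and separator-
#' insensitive (`DYS389 I` == `dys389i`). DYS385 may arrive either as the
#' split pair `DYS385a`/`DYS385b` or as one combined `DYS385` column holding
#' a comma- or slash-separated pair (`"14,11"`); pairs are stored sorted
#' ascending either way. Microvariant alleles (`13.2`) are parsed exactly.
#'
#' Rows with unparseable allele entries are never silently accepted:
#' with `on_invalid = "skip"` (default) they are dropped and recorded in the
#' `skipped` attribute; with `"keep"` they are retained with `NA` at the bad
#' cells (and so excluded from haplotype-level statistics, while their clean
#' loci still feed per-locus statistics).
#'
#' @param path input file path.
#' @param panel a [ystr_panel]; defaults to [yfiler_panel()].
#' @param on_invalid `"skip"` or `"keep"` for rows with unparseable alleles.
#' @return A [ystr_dataset]; attributes `flags` (out-of-range calls) and
#'   `skipped` (dropped/incomplete parse records) carry the validation log.
#' @seealso [write_haplotype_table()]
#' @export
read_haplotype_table <- function(path, panel = yfiler_panel(),
                                 on_invalid = c("skip", "keep")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path))
    .ystr_stop(sprintf("file not found: %s", path), "ystr_io_error")
  if (file.size(path) == 0L)
    .ystr_stop(sprintf("empty file: %s", path), "ystr_format_error")
  raw <- utils::read.table(path, header = TRUE, sep = .table_sep(path),
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           fileEncoding = "UTF-8",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L)
    .ystr_stop(sprintf("no data rows in file: %s", path), "ystr_format_error")
  norm <- .norm_colname(names(raw))

  pick <- function(name) {
    hit <- which(norm == .norm_colname(name))
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }
  id_col <- pick("SampleID")
  pop_col <- pick("Population")
  if (is.na(id_col))
    .ystr_stop("missing required column: SampleID", "ystr_format_error")
  if (is.na(pop_col))
    .ystr_stop("missing required column: Population", "ystr_format_error")

  n <- nrow(raw)
  out <- data.frame(sample_id = trimws(raw[[id_col]]),
                    population = trimws(raw[[pop_col]]),
                    stringsAsFactors = FALSE)
  bad <- data.frame(sample_id = character(), column = character(),
                    value = character(), stringsAsFactors = FALSE)
  parse_num <- function(txt, column) {
    txt <- trimws(txt)
    v <- suppressWarnings(as.numeric(txt))
    unparsed <- which(!is.na(txt) & txt != "" & is.na(v))
    if (length(unparsed) > 0L)
      bad <<- rbind(bad, data.frame(sample_id = out$sample_id[unparsed],
                                    column = column,
                                    value = txt[unparsed],
                                    stringsAsFactors = FALSE))
    v
  }

  for (i in seq_len(nrow(panel))) {
    locus <- panel$locus[i]
    if (panel$copies[i] == 2L) {
      ca <- paste0(locus, "a"); cb <- paste0(locus, "b")
      ja <- pick(ca); jb <- pick(cb); jc <- pick(locus)
      if (!is.na(ja) && !is.na(jb)) {
        out[[ca]] <- parse_num(raw[[ja]], ca)
        out[[cb]] <- parse_num(raw[[jb]], cb)
      } else if (!is.na(jc)) {
        parts <- strsplit(trimws(raw[[jc]]), "[,/;]")
        a <- vapply(parts, function(p) if (length(p) >= 1L) trimws(p[1L]) else NA_character_, "")
        b <- vapply(parts, function(p) if (length(p) >= 2L) trimws(p[2L]) else NA_character_, "")
        out[[ca]] <- parse_num(a, ca)
        out[[cb]] <- parse_num(b, cb)
      } else {
        .ystr_stop(sprintf("missing required column: %s/%s (or combined %s)",
                           ca, cb, locus), "ystr_format_error")
      }
    } else {
      j <- pick(locus)
      if (is.na(j))
        .ystr_stop(sprintf("missing required column: %s", locus),
                   "ystr_format_error")
      out[[locus]] <- parse_num(raw[[j]], locus)
    }
  }

  skipped <- bad
  if (on_invalid == "skip" && nrow(bad) > 0L) {
    drop <- out$sample_id %in% unique(bad$sample_id)
    out <- out[!drop, , drop = FALSE]
    if (nrow(out) == 0L)
      .ystr_stop("all rows failed allele parsing", "ystr_format_error")
  }
  ds <- ystr_dataset(out, panel)
  attr(ds, "skipped") <- skipped
  ds
}

#' Write a Y-STR haplotype table
#'
#' Emits the dataset as TSV or CSV (by extension) with columns `SampleID`,
#' `Population`, then the split reported allele columns (DYS385a/DYS385b,
#' ascending). Allele values round-trip exactly: `read(write(ds))`
#' reproduces every allele (including microvariant decimals) bit-for-bit.
#'
#' @param ds a [ystr_dataset] with at least one row.
#' @param path output path; directory must exist.
#' @return Invisibly, `path`.
#' @export
write_haplotype_table <- function(ds, path) {
  if (!inherits(ds, "ystr_dataset"))
    .ystr_stop("ds must be a ystr_dataset")
  if (nrow(ds$data) == 0L)
    .ystr_stop("refusing to write a dataset with no donors")
  if (!dir.exists(dirname(path)))
    .ystr_stop(sprintf("output directory does not exist: %s", dirname(path)),
               "ystr_io_error")
  cols <- panel_columns(ds$panel)
  out <- ds$data[c("sample_id", "population", cols)]
  names(out)[1:2] <- c("SampleID", "Population")
  for (col in cols) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", as.character(v))
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = .table_sep(path), quote = FALSE,
                       row.names = FALSE, col.names = TRUE,
                       fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    .ystr_stop(sprintf("could not write %s: %s", path,
                       conditionMessage(ok)), "ystr_io_error")
  invisible(path)
}
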