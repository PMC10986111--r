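# Locus panel definitions for Y-STR haplotyping.

.ystr_stop <- function(msg, subclass = "ystr_validation_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(subclass, "ystr_error", "error", "condition")))
}

#' Construct a Y-STR locus panel
#'
#' A panel is the ordered list of loci a haplotype table reports, with the
#' allele bounds (in repeat units, decimal-valued so microvariants such as
#' 13.2 are admissible) and the number of allele calls per donor at each
#' locus (2 for the duplicated locus DYS385, otherwise 1).
#'
#' @param loci data.frame with columns `locus` (character), `allele_min`,
#'   `allele_max` (numeric repeat-count bounds) and `copies` (integer 1 or 2).
#' @return An object of class `ystr_panel`: the validated data.frame.
#' @seealso [yfiler_panel()] for the built-in default panel,
#'   [panel_columns()] for the reported column names.
#' @export
ystr_panel <- function(loci) {
  required <- c("locus", "allele_min", "allele_max", "copies")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols) > 0L)
    .ystr_stop(sprintf("panel definition lacks column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "ystr_format_error")
  loci <- as.data.frame(loci)[required]
  loci$locus <- as.character(loci$locus)
  loci$allele_min <- as.numeric(loci$allele_min)
  loci$allele_max <- as.numeric(loci$allele_max)
  loci$copies <- as.integer(loci$copies)
  if (anyDuplicated(loci$locus))
    .ystr_stop("locus names must be unique within a panel")
  if (any(!loci$copies %in% c(1L, 2L)))
    .ystr_stop("locus copies must be 1 or 2")
  if (any(loci$allele_min >= loci$allele_max))
    .ystr_stop("allele_min must be strictly below allele_max for every locus")
  rownames(loci) <- NULL
  class(loci) <- c("ystr_panel", "data.frame")
  loci
}

#' The default Yfiler 17-column Y-STR panel
#'
#' The AmpFlSTR Yfiler multiplex genotypes 16 Y-STR loci; the duplicated
#' locus DYS385 yields two unordered allele calls (reported as DYS385a/b,
#' a = smaller), so each donor carries 17 reported allele columns. Published
#' kit tables commonly list DYS456 twice when enumerating 17 rows; the panel
#' here keeps the 16 distinct loci and lets DYS385 supply the 17th column.
#' Allele bounds are the kit's observed repeat-count ranges.
#'
#' @return A [ystr_panel] with 16 loci / 17 reported columns.
#' @examples
#' p <- yfiler_panel()
#' panel_columns(p)
#' @export
yfiler_panel <- function() {
  ystr_panel(data.frame(
    locus = c("DYS456", "DYS389I", "DYS390", "DYS389II", "DYS458", "DYS19",
              "DYS385", "DYS393", "DYS391", "DYS439", "DYS635", "DYS392",
              "YGATAH4", "DYS437", "DYS438", "DYS448"),
    allele_min = c(13, 9, 17, 23, 14, 10, 7, 8, 6, 8, 20, 7, 8, 13, 8, 17),
    allele_max = c(18, 17, 28, 34, 20, 19, 25, 16, 14, 15, 26, 18, 13, 17, 13, 27),
    copies = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L)
  ))
}

#' Reported column names of a panel
#'
#' Expands two-copy loci into their `a`/`b` columns, in panel row order
#' (e.g. DYS385 becomes DYS385a, DYS385b). These are the allele column
#' names used by haplotype tables, keys, and all per-locus statistics.
#'
#' @param panel a [ystr_panel].
#' @return Character vector of reported column names.
#' @export
panel_columns <- function(panel) {
  unlist(lapply(seq_len(nrow(panel)), function(i) {
    if (panel$copies[i] == 2L) paste0(panel$locus[i], c("a", "b"))
    else panel$locus[i]
  }), use.names = FALSE)
}

# Per reported column: locus name, bounds, and multicopy pairing.
.panel_column_info <- function(panel) {
  cols <- panel_columns(panel)
  idx <- rep(seq_len(nrow(panel)), panel$copies)
  data.frame(column = cols,
             locus = panel$locus[idx],
             allele_min = panel$allele_min[idx],
             allele_max = panel$allele_max[idx],
             stringsAsFactors = FALSE)
}

#' Read or write a panel definition file
#'
#' Panels are stored as a small YAML file with one `loci` list whose entries
#' carry `locus`, `allele_min`, `allele_max` and `copies`. A copy of the
#' default panel ships with the package
#' (`system.file("extdata", "yfiler_panel.yaml", package = "ystrpop")`).
#'
#' @param path file path of the YAML panel definition.
#' @return `read_panel()` returns a [ystr_panel]; `write_panel()` invisibly
#'   returns `path`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path))
    .ystr_stop(sprintf("panel file not found: %s", path), "ystr_io_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$loci))
    .ystr_stop("panel file must contain a top-level 'loci' list",
               "ystr_format_error")
  ystr_panel(do.call(rbind, lapply(y$loci, function(l)
    data.frame(locus = l$locus, allele_min = l$allele_min,
               allele_max = l$allele_max,
               copies = if (is.null(l$copies)) 1L else l$copies))))
}

#' @rdname read_panel
#' @param panel a [ystr_panel] to serialise.
#' @export
write_panel <- function(panel, path) {
  loci <- lapply(seq_len(nrow(panel)), function(i)
    list(locus = panel$locus[i], allele_min = panel$allele_min[i],
         allele_max = panel$allele_max[i], copies = panel$copies[i]))
  yaml::write_yaml(list(loci = loci), path)
  invisible(path)
}

#' @export
print.ystr_panel <- function(x, ...) {
  cat(sprintf("Y-STR panel: %d loci, %d reported columns\n",
              nrow(x), length(panel_columns(x))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
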