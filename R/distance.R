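# Inter-haplotype distances: identity (0/1) and stepwise (repeat-count).

#' Distance between two haplotypes
#'
#' Two distance models are supported. `identity` scores 0 when all reported
#' alleles match and 1 otherwise — the haplotype-frequency convention that
#' makes AMOVA's Phi a haplotype FST. `stepwise` sums absolute repeat-count
#' differences over single-copy columns and, for each unordered two-copy
#' locus (DYS385), takes the minimum total difference over the two possible
#' pairings of the pairs — the conservative choice for an unordered locus.
#'
#' @param h1,h2 named numeric allele vectors over the panel's reported
#'   columns (as one row of `ds$data`), complete.
#' @param panel the shared [ystr_panel].
#' @param model `"identity"` or `"stepwise"`.
#' @return Non-negative scalar; 0 iff the haplotypes are identical
#'   (identity model: only values 0 and 1).
#' @export
haplotype_distance <- function(h1, h2, panel = yfiler_panel(),
                               model = c("identity", "stepwise")) {
  model <- match.arg(model)
  cols <- panel_columns(panel)
  h1 <- unlist(h1)[cols]; h2 <- unlist(h2)[cols]
  if (anyNA(h1) || anyNA(h2))
    .ystr_stop("haplotype distance requires complete haplotypes over the panel")
  h1 <- as.numeric(unlist(h1)[cols]); h2 <- as.numeric(unlist(h2)[cols])
  names(h1) <- names(h2) <- cols
  if (model == "identity") return(as.numeric(any(h1 != h2)))
  d <- 0
  for (i in seq_len(nrow(panel))) {
    locus <- panel$locus[i]
    if (panel$copies[i] == 2L) {
      a1 <- h1[paste0(locus, "a")]; b1 <- h1[paste0(locus, "b")]
      a2 <- h2[paste0(locus, "a")]; b2 <- h2[paste0(locus, "b")]
      d <- d + min(abs(a1 - a2) + abs(b1 - b2),
                   abs(a1 - b2) + abs(b1 - a2))
    } else {
      d <- d + abs(h1[locus] - h2[locus])
    }
  }
  unname(d)
}

#' Pairwise distance matrix of a dataset
#'
#' Vectorised all-against-all distances over the complete haplotypes of a
#' dataset, under either distance model (see [haplotype_distance()]).
#'
#' @param ds a [ystr_dataset]; only complete haplotypes enter.
#' @param model `"identity"` or `"stepwise"`.
#' @param squared return squared distances (the AMOVA convention; identity
#'   distances are unchanged by squaring).
#' @return Symmetric N x N matrix with zero diagonal, N = number of
#'   complete haplotypes, rows in dataset order. Attribute `rows` holds the
#'   original row indices, `population` the matching labels.
#' @export
distance_matrix <- function(ds, model = c("identity", "stepwise"),
                            squared = FALSE) {
  model <- match.arg(model)
  rows <- which(complete_haplotypes(ds))
  d <- ds$data[rows, , drop = FALSE]
  n <- nrow(d)
  if (model == "identity") {
    keys <- haplotype_keys(ds, rows)
    D <- matrix(1, n, n)
    D[outer(keys, keys, "==")] <- 0
  } else {
    D <- matrix(0, n, n)
    panel <- ds$panel
    for (i in seq_len(nrow(panel))) {
      locus <- panel$locus[i]
      if (panel$copies[i] == 2L) {
        a <- d[[paste0(locus, "a")]]; b <- d[[paste0(locus, "b")]]
        same <- abs(outer(a, a, "-")) + abs(outer(b, b, "-"))
        cross <- abs(outer(a, b, "-")) + abs(outer(b, a, "-"))
        D <- D + pmin(same, cross)
      } else {
        D <- D + abs(outer(d[[locus]], d[[locus]], "-"))
      }
    }
    if (squared) D <- D^2
  }
  structure(D, rows = rows, population = d$population)
}
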