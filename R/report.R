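# End-to-end report bundle: diversity summary, GD matrix, pairwise FST with
# permutation p-values, overall AMOVA, MDS coordinates, run manifest.

# rounding profile applied to written tables (full precision kept in R)
.round_profile <- list(HD = 5L, DC = 3L, GD = 3L, HMP = 4L, FST = 4L,
                       P = 4L, MDS = 6L)

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  path
}

.matrix_tsv <- function(m, path, digits) {
  df <- data.frame(Population = rownames(m), round(m, digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Ties the stages together the way a forensic population study reports
#' them: a per-population diversity summary (n, h, HD, DC, HMP), the gene
#' diversity matrix across populations and loci, the pairwise FST matrix
#' with permutation p-values (raw and Bonferroni-adjusted), the overall
#' two-level AMOVA table, and MDS coordinates of the (negatives-clamped)
#' FST matrix. All tables are TSV with fixed column names; a JSON manifest
#' records every parameter, the seed and the package version, so a rerun
#' with the same inputs and seed reproduces the bundle byte for byte.
#'
#' Written values are rounded per the reporting profile (HD 5 d.p., DC and
#' GD 3 d.p., HMP 4 d.p., FST and p-values 4 d.p.); the returned objects
#' keep full precision.
#'
#' @param input a [ystr_dataset] or a haplotype table path for
#'   [read_haplotype_table()].
#' @param output_dir directory for the bundle (created if missing).
#' @param model distance model for AMOVA/FST.
#' @param B permutation count for FST p-values.
#' @param seed integer seed (mandatory: permutations depend on it).
#' @param mds_dim requested MDS dimensions (trimmed to k - 1).
#' @param panel panel used when `input` is a path.
#' @return Invisibly, a list with `summary`, `gd`, `fst`, `amova`, `mds`,
#'   `files`.
#' @export
run_report <- function(input, output_dir, model = c("identity", "stepwise"),
                       B = 1000L, seed = NULL, mds_dim = 2L,
                       panel = yfiler_panel()) {
  model <- match.arg(model)
  ds <- if (inherits(input, "ystr_dataset")) input
        else read_haplotype_table(input, panel)
  if (!dir.exists(output_dir) && !dir.create(output_dir, recursive = TRUE))
    .ystr_stop(sprintf("cannot create output directory: %s", output_dir),
               "ystr_io_error")
  message(sprintf("ystrpop report: %d donors, %d populations, model=%s, B=%d, seed=%s",
                  n_donors(ds), length(pop_sizes(ds)), model, B,
                  as.character(seed)))

  prof <- .round_profile
  files <- character(0)

  summ <- diversity_summary(ds)
  summ_out <- summ
  summ_out$HD <- round(summ_out$HD, prof$HD)
  summ_out$DC <- round(summ_out$DC, prof$DC)
  summ_out$HMP <- round(summ_out$HMP, prof$HMP)
  names(summ_out) <- c("Scope", "N", "NComplete", "Haplotypes", "HD", "DC", "HMP")
  files["summary"] <- .write_tsv(summ_out, file.path(output_dir, "summary.tsv"))

  gd <- gd_matrix(ds)
  gd_out <- rbind(gd$gd, ALL = gd$pooled)
  files["gd_matrix"] <- .matrix_tsv(gd_out, file.path(output_dir, "gd_matrix.tsv"),
                                    prof$GD)

  fst <- pairwise_fst_matrix(ds, model = model, B = B, seed = seed)
  files["fst_matrix"] <- .matrix_tsv(fst$values,
                                     file.path(output_dir, "fst_matrix.tsv"),
                                     prof$FST)
  files["fst_pvalues"] <- .matrix_tsv(fst$pvalues,
                                      file.path(output_dir, "fst_pvalues.tsv"),
                                      prof$P)
  padj <- fst$pvalues
  off <- upper.tri(padj)
  adj <- stats::p.adjust(padj[off], method = "bonferroni")
  padj[off] <- adj
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  files["fst_pvalues_bonferroni"] <-
    .matrix_tsv(padj, file.path(output_dir, "fst_pvalues_bonferroni.tsv"), prof$P)

  am <- amova_two_level(ds, model = model)
  am_df <- data.frame(
    Source = c("AmongPopulations", "WithinPopulations", "Total"),
    df = c(am$df_among, am$df_within, am$df_among + am$df_within),
    SS = round(c(am$ss_among, am$ss_within, am$ss_total), 6),
    VarianceComponent = round(c(am$sigma2_a, am$sigma2_w, NA), 6),
    PhiST = c(round(am$phi, 6), NA, NA))
  files["amova"] <- .write_tsv(am_df, file.path(output_dir, "amova.tsv"))

  k <- length(fst$population_ids)
  mds <- classical_mds(fst, m = min(as.integer(mds_dim), k - 1L))
  mds_df <- data.frame(Population = rownames(mds$coordinates),
                       round(mds$coordinates, prof$MDS),
                       check.names = FALSE)
  files["mds"] <- .write_tsv(mds_df, file.path(output_dir, "mds_coordinates.tsv"))

  manifest <- list(
    package = "ystrpop",
    version = as.character(utils::packageVersion("ystrpop")),
    parameters = list(model = model, B = B, seed = seed,
                      mds_dim = ncol(mds$coordinates),
                      rounding = prof),
    input = list(n_donors = n_donors(ds),
                 populations = as.list(pop_sizes(ds)),
                 n_complete = sum(complete_haplotypes(ds)),
                 flagged_out_of_range = nrow(attr(ds, "flags"))),
    files = as.list(basename(files)))
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files["manifest"] <- manifest_path

  invisible(list(summary = summ, gd = gd, fst = fst, amova = am, mds = mds,
                 files = files))
}
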