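#' Pair GRC genes with their A-chromosome paralogs by gene symbol
#'
#' Gene models in the two compartments sharing a gene symbol are treated
#' as paralogs. The gene-level "copy number" of a symbol is the number of
#' distinct gene models carrying it in a compartment (a concept distinct
#' from the coverage-based window copy number of
#' [estimate_copy_number()]).
#'
#' @param models gene-model table (see [read_models_bed12()]): one row per
#'   isoform with gene_id, gene_symbol, compartment.
#' @return list: `pairs` (per shared symbol: grc_copies, achr_copies,
#'   grc_isoforms, achr_isoforms), `grc_only` and `achr_only` symbol
#'   vectors.
#' @export
pair_paralogs <- function(models) {
  m <- models[!is.na(gene_symbol) & gene_symbol != ""]
  per <- m[, .(copies = uniqueN(gene_id), isoforms = .N),
           by = .(gene_symbol, compartment)]
  wide <- dcast(per, gene_symbol ~ compartment,
                value.var = c("copies", "isoforms"))
  for (col in setdiff(names(wide), "gene_symbol"))
    set(wide, which(is.na(wide[[col]])), col, 0L)
  need <- c("copies_GRC", "copies_A-chr", "isoforms_GRC", "isoforms_A-chr")
  for (col in setdiff(need, names(wide))) wide[, (col) := 0L]
  pairs <- wide[`copies_GRC` > 0L & `copies_A-chr` > 0L,
                .(gene_symbol, grc_copies = `copies_GRC`,
                  achr_copies = `copies_A-chr`,
                  grc_isoforms = `isoforms_GRC`,
                  achr_isoforms = `isoforms_A-chr`)]
  setkey(pairs, gene_symbol)
  list(pairs = pairs[],
       grc_only = sort(wide[`copies_GRC` > 0L & `copies_A-chr` == 0L,
                            gene_symbol]),
       achr_only = sort(wide[`copies_GRC` == 0L & `copies_A-chr` > 0L,
                             gene_symbol]))
}

#' Compare gene architecture between GRC and A-chromosome paralogs
#'
#' For each shared symbol and compartment, computes the median isoform
#' count per gene copy, the median spliced isoform length (sum of exon
#' block sizes, not genomic span) and the median coding fraction, then the
#' per-symbol GRC minus A-chromosome deltas. Across symbols, a paired
#' two-sided Wilcoxon signed-rank test is run per metric on the per-symbol
#' medians (exact null distribution for 25 or fewer non-zero differences
#' and no ties, normal approximation otherwise; zero differences are
#' dropped, the convention of the exact test).
#'
#' @param pairs `pairs` table from [pair_paralogs()].
#' @param models gene-model table with `spliced_length` and
#'   `coding_fraction` columns.
#' @return list: `per_symbol` (medians and deltas) and `tests`
#'   (metric, n non-zero pairs, statistic V, p_value).
#' @export
compare_architecture <- function(pairs, models) {
  stopifnot(nrow(pairs) >= 1L)
  m <- models[gene_symbol %in% pairs$gene_symbol]
  per_gene <- m[, .(n_iso = .N), by = .(gene_symbol, compartment, gene_id)]
  med_iso <- per_gene[, .(median_isoforms = as.numeric(median(n_iso))),
                      by = .(gene_symbol, compartment)]
  med_len <- m[, .(median_length = as.numeric(median(spliced_length)),
                   median_coding = as.numeric(median(coding_fraction))),
               by = .(gene_symbol, compartment)]
  med <- merge(med_iso, med_len, by = c("gene_symbol", "compartment"))
  wide <- dcast(med, gene_symbol ~ compartment,
                value.var = c("median_isoforms", "median_length",
                              "median_coding"))
  per_symbol <- wide[, .(
    gene_symbol,
    grc_median_isoforms = `median_isoforms_GRC`,
    achr_median_isoforms = `median_isoforms_A-chr`,
    grc_median_length = `median_length_GRC`,
    achr_median_length = `median_length_A-chr`,
    grc_median_coding = `median_coding_GRC`,
    achr_median_coding = `median_coding_A-chr`)]
  per_symbol[, `:=`(
    delta_isoforms = grc_median_isoforms - achr_median_isoforms,
    delta_length = grc_median_length - achr_median_length,
    delta_coding = grc_median_coding - achr_median_coding)]

  run_test <- function(grc, achr, metric) {
    d <- grc - achr
    n_nonzero <- sum(d != 0, na.rm = TRUE)
    if (nrow(per_symbol) < 2L || n_nonzero < 1L) {
      warning("compare_architecture: too few informative pairs for the ",
              metric, " signed-rank test; test skipped")
      return(data.table(metric = metric, n = n_nonzero,
                        statistic = NA_real_, p_value = NA_real_))
    }
    wt <- suppressWarnings(wilcox.test(grc, achr, paired = TRUE,
                                       exact = n_nonzero <= 25L,
                                       correct = TRUE))
    data.table(metric = metric, n = n_nonzero,
               statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  tests <- rbind(
    run_test(per_symbol$grc_median_isoforms,
             per_symbol$achr_median_isoforms, "isoform_count"),
    run_test(per_symbol$grc_median_length,
             per_symbol$achr_median_length, "isoform_length"),
    run_test(per_symbol$grc_median_coding,
             per_symbol$achr_median_coding, "coding_fraction"))
  list(per_symbol = per_symbol[], tests = tests)
}

#' Correlation of per-symbol gene copy numbers between compartments
#'
#' Pearson correlation (two-sided) of the numbers of GRC and
#' A-chromosome gene models per shared symbol.
#'
#' @param pairs `pairs` table from [pair_paralogs()].
#' @return list: r, n, p_value.
#' @export
copy_number_correlation <- function(pairs) {
  stopifnot(nrow(pairs) >= 3L)
  if (stats::sd(pairs$grc_copies) == 0 || stats::sd(pairs$achr_copies) == 0)
    grcscan_error("grcscan_zero_variance",
                  paste0("copy_number_correlation: copy numbers constant ",
                         "in one compartment; correlation undefined"))
  ct <- cor.test(pairs$grc_copies, pairs$achr_copies, method = "pearson")
  list(r = unname(ct$estimate), n = nrow(pairs), p_value = ct$p.value)
}

#' Per-symbol expression summary and fold-change flags
#'
#' TPM values are summed over all isoforms per symbol, compartment and
#' sex; sums are floored at `tpm_floor` before fold-changes (the
#' pseudo-count convention that keeps ratios of unexpressed genes at 1).
#' A symbol is flagged when its GRC/A-chromosome TPM ratio reaches
#' `fold_threshold` in at least one sex. `female_bias_*` is the
#' female/male ratio of the floored sums within a compartment.
#'
#' @param pairs `pairs` table from [pair_paralogs()].
#' @param models gene-model table (isoform_id, gene_symbol, compartment).
#' @param expression expression table (isoform_id, tpm_female, tpm_male);
#'   model isoforms missing from it get TPM 0 with a warning.
#' @param tpm_floor pseudo-count floor (default 0.1).
#' @param fold_threshold flagging threshold (default 10).
#' @return data.table per shared symbol: TPM sums by compartment and sex,
#'   fold_female, fold_male, flagged, female_bias_grc, female_bias_achr.
#' @export
expression_summary <- function(pairs, models, expression, tpm_floor = 0.1,
                               fold_threshold = 10) {
  stopifnot(tpm_floor > 0, fold_threshold > 1)
  iso <- models[gene_symbol %in% pairs$gene_symbol,
                .(isoform_id, gene_symbol, compartment)]
  ex <- merge(iso, expression[, .(isoform_id, tpm_female, tpm_male)],
              by = "isoform_id", all.x = TRUE)
  n_missing <- sum(is.na(ex$tpm_female) | is.na(ex$tpm_male))
  if (n_missing > 0L) {
    warning("expression_summary: ", n_missing,
            " model isoform(s) missing from the expression table; TPM 0")
    for (col in c("tpm_female", "tpm_male"))
      set(ex, which(is.na(ex[[col]])), col, 0)
  }
  sums <- ex[, .(tpm_female = sum(tpm_female), tpm_male = sum(tpm_male)),
             by = .(gene_symbol, compartment)]
  wide <- dcast(sums, gene_symbol ~ compartment,
                value.var = c("tpm_female", "tpm_male"), fill = 0)
  fl <- function(x) pmax(x, tpm_floor)
  out <- wide[, .(
    gene_symbol,
    grc_tpm_female = `tpm_female_GRC`, grc_tpm_male = `tpm_male_GRC`,
    achr_tpm_female = `tpm_female_A-chr`, achr_tpm_male = `tpm_male_A-chr`)]
  out[, `:=`(
    fold_female = fl(grc_tpm_female) / fl(achr_tpm_female),
    fold_male = fl(grc_tpm_male) / fl(achr_tpm_male),
    female_bias_grc = fl(grc_tpm_female) / fl(grc_tpm_male),
    female_bias_achr = fl(achr_tpm_female) / fl(achr_tpm_male))]
  out[, flagged := fold_female >= fold_threshold |
        fold_male >= fold_threshold]
  setkey(out, gene_symbol)
  out[]
}
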