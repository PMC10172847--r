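## File-format plumbing. Intervals are 0-based half-open in memory and in
## BED-style output; site tables are written 1-based (VCF convention).

#' Write reads to FASTA
#' @param reads data.table with `read_id` and `seq`.
#' @param path output FASTA path.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(stats::setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write / read the SNV site table
#'
#' Tab-separated with header; positions are written 1-based
#' (`pos_1based`) and converted back to 0-based on read.
#'
#' @param sites site table from [call_snv_sites()].
#' @param path file path.
#' @export
write_sites <- function(sites, path) {
  out <- copy(sites)
  out[, pos_1based := pos + 1L]
  setcolorder(out, c("contig", "pos_1based"))
  out[, pos := NULL]
  fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  dt <- fread(path, sep = "\t",
              colClasses = list(character = c("soma_alleles",
                                              "germline_alleles",
                                              "germline_specific",
                                              "soma_specific")))
  dt[, pos := pos_1based - 1L]
  dt[, pos_1based := NULL]
  setcolorder(dt, c("contig", "pos"))
  dt[]
}

#' Write window statistics as BED6+
#'
#' Headerless BED-style TSV: contig, start, end, relspec, n_snvs,
#' sum_germline_specific, sum_soma_specific (0-based half-open).
#'
#' @param stats window table from [window_relspec()] or
#'   [select_top_windows()].
#' @param path file path.
#' @export
write_windows_bed <- function(stats, path) {
  fwrite(stats[, .(contig, start, end,
                   relspec = fifelse(is.na(relspec), ".",
                                     format(relspec, digits = 10)),
                   n_snvs, sum_germline_specific, sum_soma_specific)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_bed
#' @export
read_windows_bed <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE,
              col.names = c("contig", "start", "end", "relspec", "n_snvs",
                            "sum_germline_specific", "sum_soma_specific"))
  dt[, relspec := suppressWarnings(as.numeric(relspec))]
  dt[]
}

#' Write / read gene models as BED12 plus documented extension columns
#'
#' Standard BED12 columns 1-12, then four extension columns: `gene_id`,
#' `gene_symbol`, `compartment` (GRC or A-chr) and `coding_fraction`
#' (percent of the reference protein aligned). Headerless,
#' 0-based half-open.
#'
#' @param models model table (see [simulate_annotation()]).
#' @param path file path.
#' @export
write_models_bed12 <- function(models, path) {
  fwrite(models[, .(contig, start, end, isoform_id, 0L, strand,
                    start, end, "0,0,0", n_blocks, block_sizes,
                    block_starts, gene_id, gene_symbol, compartment,
                    coding_fraction)],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_models_bed12
#' @export
read_models_bed12 <- function(path) {
  dt <- fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) != 16L)
    stop("read_models_bed12: expected BED12 + 4 extension columns, got ",
         ncol(dt))
  setnames(dt, c("contig", "start", "end", "isoform_id", "score", "strand",
                 "thick_start", "thick_end", "rgb", "n_blocks",
                 "block_sizes", "block_starts", "gene_id", "gene_symbol",
                 "compartment", "coding_fraction"))
  dt[, spliced_length := vapply(strsplit(block_sizes, ","),
                                function(x) sum(as.integer(x)), numeric(1))]
  dt[, c("score", "thick_start", "thick_end", "rgb") := NULL]
  dt[]
}

#' Write / read the isoform expression table
#'
#' TSV with header: isoform_id, gene_symbol, compartment, tpm_female,
#' tpm_male.
#'
#' @param expression expression table.
#' @param path file path.
#' @export
write_expression_tsv <- function(expression, path) {
  fwrite(expression[, .(isoform_id, gene_symbol, compartment, tpm_female,
                        tpm_male)], path, sep = "\t")
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  fread(path, sep = "\t")
}

#' Convert a SAM file to a coordinate-sorted, indexed BAM
#' @param sam_path path to a SAM file.
#' @return path to the BAM file.
#' @export
sam_to_bam <- function(sam_path) {
  Rsamtools::asBam(sam_path, sub("\\.sam$", "", sam_path),
                   overwrite = TRUE, indexDestination = TRUE)
}
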