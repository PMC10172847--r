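#' Generate a complete ground-truthed synthetic dataset on disk
#'
#' Runs [simulate_reference()], [simulate_reads()],
#' [simulate_alignments()] and [simulate_annotation()] and writes:
#' reference FASTA (+ .fai), soma and germline SAM/BAM (+ .bai), germline
#' reads FASTA, gene models (BED12 + extension columns), expression TSV,
#' and headered truth TSVs (read origins, donor segments, diverged sites,
#' heterozygous sites, per-window true copy number). Regenerating with the
#' same configuration reproduces byte-identical files.
#'
#' @param config a [sim_config()] object.
#' @param outdir output directory (created if needed).
#' @param window_size window size used for the truth window labels (bp).
#' @param bam also convert SAM to sorted+indexed BAM (default TRUE).
#' @param annotation also simulate gene models and expression
#'   (default TRUE).
#' @return (invisibly) a list with the file `paths`, the truth tables, and
#'   the in-memory `reference`.
#' @export
simulate_dataset <- function(config, outdir, window_size = 25000L,
                             bam = TRUE, annotation = TRUE) {
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, paste0(...))

  ref <- simulate_reference(config)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref$contigs),
                              p("ref.fa"))
  Rsamtools::indexFa(p("ref.fa"))

  reads <- simulate_reads(config, ref)
  soma_aln <- simulate_alignments(reads$soma, ref, p("soma.sam"), bam = bam)
  germ_aln <- simulate_alignments(reads$germline, ref, p("germline.sam"),
                                  bam = bam)
  write_reads_fasta(reads$germline, p("germline_reads.fasta"))

  fwrite(reads$truth_reads, p("truth_reads.tsv"), sep = "\t")
  fwrite(ref$truth$segments, p("truth_segments.tsv"), sep = "\t")
  fwrite(ref$truth$diverged_sites, p("truth_diverged_sites.tsv"),
         sep = "\t")
  fwrite(ref$truth$het_sites, p("truth_het_sites.tsv"), sep = "\t")

  tw <- truth_windows(ref, window_size)
  fwrite(tw, p("truth_windows.tsv"), sep = "\t")

  paths <- list(reference = p("ref.fa"), soma = soma_aln,
                germline = germ_aln,
                germline_reads = p("germline_reads.fasta"),
                truth_reads = p("truth_reads.tsv"),
                truth_segments = p("truth_segments.tsv"),
                truth_diverged_sites = p("truth_diverged_sites.tsv"),
                truth_het_sites = p("truth_het_sites.tsv"),
                truth_windows = p("truth_windows.tsv"))

  ann <- NULL
  if (annotation) {
    ann <- simulate_annotation(seed = config$seed,
                               contig_names = names(ref$contigs))
    write_models_bed12(ann$models, p("models.bed"))
    write_expression_tsv(ann$expression, p("expression.tsv"))
    fwrite(ann$truth, p("truth_annotation.tsv"), sep = "\t")
    paths$models <- p("models.bed")
    paths$expression <- p("expression.tsv")
    paths$truth_annotation <- p("truth_annotation.tsv")
  }

  invisible(list(paths = paths, reference = ref,
                 truth_reads = reads$truth_reads,
                 truth_windows = tw, annotation = ann, config = config))
}

#' Per-window true copy number from the simulation truth
#'
#' Windows tiled at `window_size` over the A-chromosome contigs; a window
#' overlapping a GRC donor segment carries that segment's copy count
#' (maximum if several), all other windows 0.
#'
#' @param ref a [simulate_reference()] result.
#' @param window_size window size (bp).
#' @return data.table contig, start, end, true_copy_number.
#' @export
truth_windows <- function(ref, window_size = 25000L) {
  win <- make_windows(nchar(ref$contigs), window_size)
  seg <- ref$truth$segments
  win[, true_copy_number := 0L]
  for (i in seq_len(nrow(seg))) {
    win[contig == seg$donor_contig[i] & start < seg$donor_end[i] &
          end > seg$donor_start[i],
        true_copy_number := pmax(true_copy_number, seg$copies[i])]
  }
  win[]
}
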