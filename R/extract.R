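#' Extract germline reads carrying germline-specific variants
#'
#' A germline read is selected iff its primary alignment overlaps at least
#' one selected window AND its aligned base equals a germline-specific
#' allele at `min_specific` or more SNV sites. Each read is counted once
#' (secondary/supplementary alignments are ignored). The selected reads
#' are the input for an external assembler; the study design assembles
#' them with `hifiasm grc_reads.fasta` (not invoked here).
#'
#' @param germline_bam coordinate-sorted, indexed germline BAM (SAM
#'   converted on the fly).
#' @param selected_windows window table (contig/start/end), e.g. from
#'   [select_top_windows()].
#' @param sites site table from [call_snv_sites()].
#' @param min_specific minimum germline-specific alleles carried
#'   (default 1). With error-bearing reads, 2 suppresses singleton false
#'   carriers from sequencing error.
#' @param reads_fasta optional FASTA with the germline read sequences; if
#'   given together with `out_fasta`, selected reads are written out.
#'   Reads present in the BAM but absent from the FASTA are an error
#'   (ids listed).
#' @param out_fasta optional output FASTA path for the selected reads.
#' @return list: `manifest` (data.table read_id, contig, align_start,
#'   align_end, n_specific), `summary` (n_reads, n_windows,
#'   per_window read counts), and `fasta` (path or NULL).
#' @export
extract_reads <- function(germline_bam, selected_windows, sites,
                          min_specific = 1L, reads_fasta = NULL,
                          out_fasta = NULL) {
  stopifnot(min_specific >= 1L)
  empty <- data.table(read_id = character(), contig = character(),
                      align_start = integer(), align_end = integer(),
                      n_specific = integer())
  if (nrow(selected_windows) == 0L)
    return(list(manifest = empty,
                summary = list(n_reads = 0L, n_windows = 0L,
                               per_window = data.table()),
                fasta = NULL))

  if (grepl("\\.sam$", germline_bam)) germline_bam <- sam_to_bam(germline_bam)
  fl <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                               isSecondaryAlignment = FALSE,
                               isSupplementaryAlignment = FALSE)
  bam <- Rsamtools::scanBam(germline_bam, param = Rsamtools::ScanBamParam(
    flag = fl, what = c("qname", "rname", "pos", "cigar", "seq")))[[1L]]
  n_reads_bam <- length(bam$qname)
  reads <- data.table(
    read_id = bam$qname,
    contig = as.character(bam$rname),
    align_start = bam$pos - 1L, # 0-based
    ref_width = GenomicAlignments::cigarWidthAlongReferenceSpace(bam$cigar))
  reads[, align_end := align_start + ref_width]
  seq_chr <- as.character(bam$seq)

  ## reads overlapping >= 1 selected window
  rgr <- GenomicRanges::GRanges(reads$contig,
                                IRanges::IRanges(reads$align_start + 1L,
                                                 reads$align_end))
  wgr <- GenomicRanges::GRanges(selected_windows$contig,
                                IRanges::IRanges(selected_windows$start + 1L,
                                                 selected_windows$end))
  cand <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(rgr, wgr)))
  if (length(cand) == 0L)
    return(list(manifest = empty,
                summary = list(n_reads = 0L,
                               n_windows = nrow(selected_windows),
                               per_window = data.table()),
                fasta = NULL))

  ## germline-specific alleles, one row per (site, allele)
  spec <- sites[n_germline_specific > 0L,
                .(contig, pos, germline_specific)]
  spec <- spec[, .(allele = unlist(strsplit(germline_specific, ","))),
               by = .(contig, pos)]

  cand_dt <- reads[cand]
  cand_dt[, rid := .I]
  carried <- integer(nrow(cand_dt))
  if (nrow(spec)) {
    setkey(cand_dt, contig, align_start, align_end)
    spec[, `:=`(s = pos, e = pos + 1L)]
    ov <- foverlaps(spec, cand_dt,
                    by.x = c("contig", "s", "e"),
                    by.y = c("contig", "align_start", "align_end"),
                    type = "within", nomatch = NULL)
    if (nrow(ov)) {
      off <- ov$pos - ov$align_start + 1L
      base <- substring(seq_chr[cand][ov$rid], off, off)
      hits <- ov[base == allele, .N, by = rid]
      carried[hits$rid] <- hits$N
    }
  }
  cand_dt[, n_specific := carried[rid]] # rid indexes the pre-sort order
  sel <- cand_dt[n_specific >= min_specific,
                 .(read_id, contig, align_start, align_end, n_specific)]
  sel <- sel[order(contig, align_start)]

  ## per-window counts of selected reads
  per_window <- copy(selected_windows[, .(contig, start, end)])
  if (nrow(sel)) {
    sgr <- GenomicRanges::GRanges(sel$contig,
                                  IRanges::IRanges(sel$align_start + 1L,
                                                   sel$align_end))
    per_window[, n_reads := GenomicRanges::countOverlaps(wgr, sgr)]
  } else per_window[, n_reads := 0L]

  fasta_out <- NULL
  if (!is.null(reads_fasta) && !is.null(out_fasta) && nrow(sel)) {
    fa <- Biostrings::readDNAStringSet(reads_fasta)
    names(fa) <- sub("\\s.*$", "", names(fa))
    missing <- setdiff(sel$read_id, names(fa))
    if (length(missing))
      stop("extract_reads: reads absent from FASTA source: ",
           paste(head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) sprintf(" (and %d more)",
                                              length(missing) - 10L))
    Biostrings::writeXStringSet(fa[sel$read_id], out_fasta)
    fasta_out <- out_fasta
  }

  message(sprintf(
    "extract_reads: %d of %d primary germline reads selected (%d windows)",
    nrow(sel), n_reads_bam, nrow(selected_windows)))
  list(manifest = sel,
       summary = list(n_reads = nrow(sel),
                      n_windows = nrow(selected_windows),
                      per_window = per_window),
       fasta = fasta_out)
}
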