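#' Simulate a combined-assembly dataset for coverage validation
#'
#' The copy-number stage of the study design does not run on the
#' permissive A-chromosome mapping but on a stringent re-mapping of both
#' read sets against the combined assembly (A-chromosome contigs plus the
#' assembled GRC contigs): there, GRC windows carry only GRC-derived
#' germline reads plus a small cross-mapping component, and a collapsed
#' multicopy region shows up as a local coverage pile-up. This generator
#' emulates exactly that coverage structure:
#'
#' * A-chromosome contigs receive soma reads at `soma_depth` and germline
#'   reads at `germline_achr_depth`;
#' * a GRC assembly contig of `grc_total_bp` receives germline reads at
#'   `grc_cell_fraction_depth`; regions named in `multicopy_region`
#'   receive the additional `(copies - 1)` copies' worth of reads, drawn
#'   with overhang across the region boundaries the way reads from a
#'   collapsed tandem array pile onto its single assembled copy (so the
#'   in-region depth is exactly `copies x grc_cell_fraction_depth`, with
#'   transition shoulders outside);
#' * cross-mapping onto the GRC assembly: soma at `cross_map_depth`,
#'   germline at `cross_map_depth * germline_achr_depth / soma_depth`
#'   (cross-mapping scales with sequencing effort — the assumption under
#'   which the corrected-coverage subtraction removes it exactly).
#'
#' Read counts are calibrated so that the coverage plateau away from
#' contig ends equals the configured depth (the quantity the depth
#' medians report). The GRC assembly sequence itself is synthetic
#' (uniform random): the coverage arithmetic validated here is
#' independent of sequence homology, which matters only in the detection
#' stage ([simulate_dataset()]).
#'
#' @param config a [sim_config()] object (fields `divergence`, `het_rate`
#'   and `segment_align` are not used by this generator).
#' @param outdir output directory.
#' @param window_size window size for the truth labels (bp).
#' @return (invisibly) list with `paths` (combined reference FASTA, soma
#'   and germline BAMs, truth TSV), `windows` (labelled window table:
#'   contig, start, end, label A-chr|GRC, true_copy_number), and `config`.
#' @export
simulate_validation_dataset <- function(config, outdir,
                                        window_size = 25000L) {
  validate_sim_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  set.seed(config$seed + 3L)

  achr_names <- sprintf("achr%02d", seq_len(config$n_contigs))
  contigs <- stats::setNames(vapply(seq_len(config$n_contigs), function(i)
    paste(sample(DNA_BASES, config$contig_length_bp, replace = TRUE),
          collapse = ""), character(1L)), achr_names)
  grc_seq <- paste(sample(DNA_BASES, config$grc_total_bp, replace = TRUE),
                   collapse = "")
  combined <- c(contigs, grc_asm01 = grc_seq)
  ref <- structure(list(contigs = combined), class = "grc_sim_reference")

  ## region layout on the assembled GRC contig
  n <- config$n_grc_segments
  seg_len <- rep(config$grc_total_bp %/% n, n)
  seg_len[n] <- seg_len[n] + config$grc_total_bp - sum(seg_len)
  seg_start <- cumsum(c(0L, head(seg_len, -1L)))
  copies <- rep(1L, n)
  mc <- config$multicopy_region
  if (!is.null(mc)) copies[mc$segment] <- as.integer(mc$copies)

  germ_ratio <- config$germline_achr_depth / config$soma_depth

  soma <- rbind(
    rbindlist(lapply(achr_names, function(cn)
      draw_reads_plateau(config, contigs[[cn]], cn, config$soma_depth,
                         "A-chr"))),
    draw_reads_plateau(config, grc_seq, "grc_asm01",
                       config$cross_map_depth, "cross"))
  germline <- rbind(
    rbindlist(lapply(achr_names, function(cn)
      draw_reads_plateau(config, contigs[[cn]], cn,
                         config$germline_achr_depth, "A-chr"))),
    draw_reads_plateau(config, grc_seq, "grc_asm01",
                       config$grc_cell_fraction_depth, "GRC"),
    rbindlist(lapply(which(copies > 1L), function(i)
      draw_reads_plateau(config, grc_seq, "grc_asm01",
                         (copies[i] - 1L) * config$grc_cell_fraction_depth,
                         "GRC", segment_id = sprintf("grc_seg%02d", i),
                         region = c(seg_start[i],
                                    seg_start[i] + seg_len[i])))))

  finish <- function(dt, tag) {
    if (nrow(dt) == 0L) {
      dt[, read_id := character(0)]
      return(dt)
    }
    dt <- dt[sample.int(nrow(dt))]
    dt[, read_id := sprintf("%s_%07d", tag, .I)]
    dt
  }
  soma <- finish(soma, "soma")
  germline <- finish(germline, "germline")

  Biostrings::writeXStringSet(Biostrings::DNAStringSet(combined),
                              p("combined_ref.fa"))
  Rsamtools::indexFa(p("combined_ref.fa"))
  soma_bam <- simulate_alignments(
    soma[, .(read_id, contig, start, length, seq)], ref, p("soma.sam"))
  germ_bam <- simulate_alignments(
    germline[, .(read_id, contig, start, length, seq)], ref,
    p("germline.sam"))

  win <- make_windows(nchar(combined), window_size)
  win[, label := fifelse(contig == "grc_asm01", "GRC", "A-chr")]
  win[, true_copy_number := 0L]
  win[label == "GRC", true_copy_number := 1L]
  for (i in which(copies > 1L))
    win[contig == "grc_asm01" & start >= seg_start[i] &
          end <= seg_start[i] + seg_len[i], true_copy_number := copies[i]]
  fwrite(win, p("truth_validation_windows.tsv"), sep = "\t")

  invisible(list(
    paths = list(reference = p("combined_ref.fa"), soma = soma_bam,
                 germline = germ_bam,
                 truth_windows = p("truth_validation_windows.tsv")),
    windows = win, config = config))
}

## Plateau-calibrated read draw: the number of reads is chosen so that the
## coverage plateau (away from edges) equals `depth`. With `region`
## (0-based half-open), read starts range over [region_start - rl,
## region_end) so that every in-region position sees the full plateau and
## the ramps fall outside the region.
#' @keywords internal
draw_reads_plateau <- function(config, seq_string, target_contig, depth,
                               origin, segment_id = NA_character_,
                               region = NULL) {
  if (depth <= 0) return(empty_read_block())
  L <- nchar(seq_string)
  mrl <- config$read_length_mean
  if (is.null(region)) {
    a <- 0
    b <- max(L - mrl, 1)
  } else {
    a <- max(0, region[1L] - mrl + 1)
    b <- min(max(L - mrl, 1), region[2L] - 1)
  }
  W <- b - a + 1
  n <- rpois(1L, W * depth / mrl)
  if (n == 0L) return(empty_read_block())
  rl <- pmin(pmax(as.integer(round(rnorm(n, mrl, config$read_length_sd))),
                  200L), L)
  start <- as.integer(floor(runif(n, a, b + 1)))
  start <- pmin(start, L - rl) # keep within the contig for long draws
  seqs <- substring(seq_string, start + 1L, start + rl)
  n_err <- rbinom(n, rl, config$error_rate)
  for (i in which(n_err > 0L)) {
    pp <- sample.int(rl[i], n_err[i])
    seqs[i] <- splice_substitutions(seqs[i], pp,
                                    mutate_bases(substring(seqs[i], pp, pp)))
  }
  data.table(contig = target_contig, start = start, length = rl,
             seq = seqs, origin = origin, segment_id = segment_id,
             n_errors = n_err)
}

#' Default configuration of the coverage-validation dataset
#'
#' Two 500-kb A-chromosome contigs (for the depth medians and the
#' germline:soma factor) and a 4-Mb GRC assembly — 160 windows of 25 kb,
#' of which one interior 1-Mb region (40 windows) is planted at 5 genomic
#' copies — at the study depths 30x/88x/24x with 0.4x soma cross-mapping.
#' The region is large enough that the median copy number over its
#' windows estimates the planted value with a standard error well below
#' the half-copy scale (25-kb window means of 18-kb reads are individually
#' noisy).
#'
#' @param seed integer seed.
#' @param copies planted copy number of the multicopy region (default 5).
#' @return a [sim_config()] object.
#' @export
validation_config <- function(seed = 1L, copies = 5L) {
  sim_config(seed = seed, n_contigs = 2L, contig_length_bp = 500000L,
             grc_total_bp = 4000000L, n_grc_segments = 4L,
             multicopy_region = list(segment = 2L, copies = copies))
}
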