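#' Mean per-base read depth over windows
#'
#' Depth is computed from primary alignments only, using the reference
#' span of each alignment's CIGAR.
#'
#' @param bam coordinate-sorted, indexed BAM (SAM converted on the fly).
#' @param windows window table (contig, start, end; 0-based half-open).
#' @param min_mapq mapping-quality floor.
#' @return the window table with a `mean_depth` column.
#' @export
window_coverage <- function(bam, windows, min_mapq = 0L) {
  if (grepl("\\.sam$", bam)) bam <- sam_to_bam(bam)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  fl <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                               isSecondaryAlignment = FALSE,
                               isSupplementaryAlignment = FALSE)
  b <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    flag = fl, mapqFilter = as.integer(min_mapq),
    what = c("rname", "pos", "cigar")))[[1L]]
  out <- copy(windows)
  if (length(b$pos) == 0L) {
    out[, mean_depth := 0]
    return(out[])
  }
  gr <- GenomicRanges::GRanges(
    as.character(b$rname),
    IRanges::IRanges(b$pos,
                     width = GenomicAlignments::cigarWidthAlongReferenceSpace(
                       b$cigar)),
    seqlengths = hdr)
  cov <- GenomicRanges::coverage(gr)
  out[, mean_depth := {
    rl <- cov[[contig[1L]]]
    as.numeric(IRanges::viewMeans(IRanges::Views(rl, start + 1L, end)))
  }, by = contig]
  out[]
}

#' Coverage summary over labelled windows
#'
#' Medians of soma and germline depth over A-chromosome and GRC windows,
#' the germline:soma normalization factor, and the GRC:A-chromosome
#' germline coverage ratio.
#'
#' `ratio_factor` is the median over A-chromosome windows of the
#' per-window germline/soma depth ratio (windows with zero soma depth are
#' excluded and reported via a message); this per-window-median definition
#' can differ slightly from the ratio of the two medians.
#' `grc_achr_ratio` is the median germline depth over GRC windows divided
#' by the median germline depth over A-chromosome windows.
#'
#' @param cov data.table with columns `soma_cov`, `germline_cov`, and
#'   `label` ("A-chr" or "GRC") — one row per window.
#' @return a list of class `grc_coverage_summary`: soma_achr_median,
#'   soma_grc_median, germline_achr_median, germline_grc_median,
#'   ratio_factor, grc_achr_ratio, n_achr, n_grc, n_excluded_zero_soma.
#' @export
coverage_summary <- function(cov) {
  stopifnot(all(c("soma_cov", "germline_cov", "label") %in% names(cov)),
            all(cov$label %in% c("A-chr", "GRC")))
  a <- cov[label == "A-chr"]
  g <- cov[label == "GRC"]
  if (nrow(g) == 0L)
    grcscan_error("grcscan_no_grc_windows",
                  "coverage_summary: no GRC-labelled windows")
  a_ok <- a[soma_cov > 0]
  n_excl <- nrow(a) - nrow(a_ok)
  if (n_excl > 0L)
    message("coverage_summary: excluded ", n_excl,
            " zero-soma-depth window(s) from ratio_factor")
  if (nrow(a_ok) == 0L)
    grcscan_error("grcscan_degenerate_ratio",
                  "coverage_summary: no A-chr window with soma depth > 0")
  out <- list(
    soma_achr_median = median(a$soma_cov),
    soma_grc_median = median(g$soma_cov),
    germline_achr_median = median(a$germline_cov),
    germline_grc_median = median(g$germline_cov),
    ratio_factor = median(a_ok$germline_cov / a_ok$soma_cov),
    grc_achr_ratio = median(g$germline_cov) / median(a$germline_cov),
    n_achr = nrow(a), n_grc = nrow(g),
    n_excluded_zero_soma = n_excl)
  stopifnot(out$ratio_factor > 0)
  structure(out, class = "grc_coverage_summary")
}

#' Corrected-coverage copy-number estimation over candidate GRC windows
#'
#' For each window,
#' `corrected = germline_cov_raw - soma_cov * ratio_factor` (floored at 0
#' and flagged when clamped): subtracting the scaled soma depth removes
#' the A-chromosome cross-mapping component of the germline coverage.
#' The copy number is the corrected coverage divided by the median
#' corrected coverage across all candidate windows, and
#' `copy_number_int` truncates it to an integer (floor). Windows with
#' copy number above 1 indicate multicopy regions collapsed in assembly.
#'
#' @param cov data.table with columns contig, start, end, `soma_cov`,
#'   `germline_cov_raw` — one row per candidate GRC window.
#' @param ratio_factor germline:soma A-chromosome coverage factor (see
#'   [coverage_summary()]).
#' @return data.table with germline_cov_corrected, clamped, copy_number,
#'   copy_number_int; attribute `median_corrected`.
#' @export
estimate_copy_number <- function(cov, ratio_factor) {
  stopifnot(nrow(cov) >= 1L, ratio_factor > 0,
            all(c("soma_cov", "germline_cov_raw") %in% names(cov)))
  out <- copy(cov)
  raw_corr <- out$germline_cov_raw - out$soma_cov * ratio_factor
  out[, clamped := raw_corr < 0]
  out[, germline_cov_corrected := pmax(0, raw_corr)]
  med <- median(out$germline_cov_corrected)
  if (med == 0)
    grcscan_error("grcscan_degenerate_normalization",
                  paste0("estimate_copy_number: median corrected germline ",
                         "coverage is 0; copy numbers undefined"))
  out[, copy_number := germline_cov_corrected / med]
  out[, copy_number_int := as.integer(floor(copy_number))]
  setattr(out, "median_corrected", med)
  out[]
}

#' Assembly size estimates: raw length, copy-aware length, N50
#'
#' `raw_length` is the summed contig length and `n_contigs_over_minlen`
#' counts contigs above `min_length`. When a copy-number table is given,
#' `copy_aware_length` sums window length x integer copy number over its
#' windows, so collapsed multicopy regions contribute once per estimated
#' copy. Policy for sub-single-copy windows (the truncation rule is
#' silent on them): a window whose copy number rounds to 1 (>= 0.5)
#' counts once; windows with zero corrected coverage contribute nothing.
#' Set `round_half_up_single = FALSE` to use the bare floor instead.
#'
#' @param contig_lengths numeric vector of contig lengths.
#' @param cn_table optional [estimate_copy_number()] output.
#' @param min_length contig length cutoff for the count (default 50000).
#' @param round_half_up_single see above (default TRUE).
#' @return list: raw_length, n_contigs, n_contigs_over_minlen, n50, and
#'   (with `cn_table`) copy_aware_length.
#' @export
size_estimates <- function(contig_lengths, cn_table = NULL,
                           min_length = 50000, round_half_up_single = TRUE) {
  stopifnot(all(contig_lengths > 0))
  out <- list(raw_length = sum(as.numeric(contig_lengths)),
              n_contigs = length(contig_lengths),
              n_contigs_over_minlen = sum(contig_lengths > min_length),
              n50 = n50(contig_lengths))
  if (!is.null(cn_table)) {
    eff <- cn_table$copy_number_int
    if (round_half_up_single)
      eff <- ifelse(cn_table$copy_number_int == 0L &
                      cn_table$copy_number >= 0.5, 1L, eff)
    out$copy_aware_length <-
      sum(as.numeric(cn_table$end - cn_table$start) * eff)
  }
  out
}
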