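#' Run the detection pipeline on a synthetic dataset and score it
#' against the ground truth
#'
#' Executes pileup, SNV calling, window relspec, top-window selection and
#' germline-read extraction on a [simulate_dataset()] output, then
#' compares the selected windows with the true GRC donor windows and the
#' extracted reads with the true GRC-origin reads overlapping them.
#'
#' By default the selection fraction is matched to the known GRC share of
#' eligible windows (`(n_true + 0.5) / n_eligible`; the half window
#' guards the floor against floating-point noise). The scaled-down
#' synthetic genome devotes a far larger fraction of its windows to GRC
#' homology than a real genome, where the study constant of 1 percent
#' applies; the ranking itself is unchanged.
#'
#' `min_specific` defaults to 3 for this evaluation: with error-bearing
#' reads, pairs of reads sharing a sequencing error create sporadic
#' depth-2 germline-specific sites, and a carried-allele threshold above
#' 2 suppresses those false carriers (see the methods vignette).
#'
#' @param dataset a [simulate_dataset()] result.
#' @param window_size,min_snvs,soma_min_depth,germline_min_depth,min_specific
#'   stage parameters (study defaults).
#' @param top_fraction selection fraction; `NULL` (default) matches the
#'   truth fraction as above.
#' @return list of metrics (n_snvs, n_windows_eligible, n_true_windows,
#'   n_selected, window_recall, window_precision, relspec_separation,
#'   n_true_reads, n_reads_extracted, read_recall, read_precision) plus
#'   the stage tables (sites, windows, selected, read_manifest).
#' @export
evaluate_detection <- function(dataset, window_size = 25000L,
                               min_snvs = 20L, soma_min_depth = 15L,
                               germline_min_depth = 45L,
                               min_specific = 3L, top_fraction = NULL) {
  paths <- dataset$paths
  counts <- count_alleles(paths$soma, paths$germline)
  sites <- call_snv_sites(counts, soma_min_depth, germline_min_depth)
  win <- make_windows(reference_lengths(paths$reference), window_size)
  st <- window_relspec(sites, win, min_snvs)

  truth_win <- dataset$truth_windows
  true_win <- truth_win[true_copy_number > 0L]
  n_eligible <- sum(st$eligible)
  if (is.null(top_fraction))
    top_fraction <- (nrow(true_win) + 0.5) / n_eligible
  sel <- select_top_windows(st, top_fraction)

  hit <- merge(sel[, .(contig, start, end)],
               true_win[, .(contig, start, end)],
               by = c("contig", "start", "end"))
  stm <- merge(st, truth_win, by = c("contig", "start", "end"))
  separation <- min(stm[true_copy_number > 0L & eligible, relspec]) -
    max(stm[true_copy_number == 0L & eligible, relspec])

  ext <- extract_reads(paths$germline, sel, sites,
                       min_specific = min_specific)
  tr <- dataset$truth_reads
  grc_reads <- tr[sample == "germline" & origin == "GRC",
                  .(read_id, contig, s = start, e = start + length)]
  selk <- copy(sel[, .(contig, start, end)])
  setkey(selk, contig, start, end)
  ov <- foverlaps(grc_reads, selk, by.x = c("contig", "s", "e"),
                  nomatch = NULL)
  true_ids <- unique(ov$read_id)
  got <- ext$manifest$read_id

  list(
    n_snvs = nrow(sites),
    n_windows_eligible = n_eligible,
    n_true_windows = nrow(true_win),
    n_selected = nrow(sel),
    window_recall = nrow(hit) / nrow(true_win),
    window_precision = nrow(hit) / nrow(sel),
    relspec_separation = separation,
    n_true_reads = length(true_ids),
    n_reads_extracted = length(got),
    read_recall = length(intersect(got, true_ids)) / length(true_ids),
    read_precision = mean(got %in%
                            tr[origin == "GRC", read_id]),
    sites = sites, windows = st, selected = sel,
    read_manifest = ext$manifest)
}

#' Coverage validation and copy-number recovery on a combined-assembly
#' dataset
#'
#' Computes per-window soma and germline coverage on a
#' [simulate_validation_dataset()] output, the coverage summary (depth
#' medians, germline:soma factor, GRC:A-chr ratio), the
#' corrected-coverage copy-number table over GRC windows, and the median
#' copy number recovered over the planted multicopy region.
#'
#' @param dataset a [simulate_validation_dataset()] result.
#' @param min_mapq mapping-quality floor for coverage.
#' @return list: `coverage_summary`, `copy_number` table,
#'   `median_corrected`, `planted_copies` (truth), `region_copy_number`
#'   (median over the planted region's windows),
#'   `corrected_achr_ratio` (median corrected GRC coverage over the
#'   median germline A-chr coverage — the GRC:A-chr coverage ratio net of
#'   cross-mapping), and `size` ([size_estimates()] of the GRC windows).
#' @export
evaluate_validation <- function(dataset, min_mapq = 0L) {
  win <- dataset$windows
  sc <- window_coverage(dataset$paths$soma, win[, .(contig, start, end)],
                        min_mapq)
  gc <- window_coverage(dataset$paths$germline,
                        win[, .(contig, start, end)], min_mapq)
  cov <- copy(win)[, `:=`(soma_cov = sc$mean_depth,
                          germline_cov = gc$mean_depth)]
  cs <- coverage_summary(cov)
  cn <- estimate_copy_number(
    cov[label == "GRC", .(contig, start, end, soma_cov,
                          germline_cov_raw = germline_cov)],
    cs$ratio_factor)
  cnt <- merge(cn, win, by = c("contig", "start", "end"))
  planted <- max(win$true_copy_number)
  region <- cnt[true_copy_number == planted]
  grc_len <- win[label == "GRC", sum(end - start)]
  list(
    coverage_summary = cs,
    copy_number = cn,
    median_corrected = attr(cn, "median_corrected"),
    planted_copies = planted,
    n_region_windows = nrow(region),
    region_copy_number = median(region$copy_number),
    corrected_achr_ratio = attr(cn, "median_corrected") /
      cs$germline_achr_median,
    size = size_estimates(grc_len, cn_table = cn, min_length = 0))
}
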