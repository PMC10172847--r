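#' Tile a reference into fixed-size windows
#'
#' Non-overlapping tiling per contig, 0-based half-open. A final partial
#' window is retained and flagged.
#'
#' @param ref_lengths named vector of contig lengths (see
#'   [reference_lengths()]).
#' @param window_size window size in bp (default 25000).
#' @return data.table: contig, start, end, partial.
#' @export
make_windows <- function(ref_lengths, window_size = 25000L) {
  stopifnot(window_size > 0)
  if (length(ref_lengths) == 0L)
    return(data.table(contig = character(), start = integer(),
                      end = integer(), partial = logical()))
  stopifnot(!is.null(names(ref_lengths)))
  win <- rbindlist(lapply(names(ref_lengths), function(cn) {
    len <- as.integer(ref_lengths[[cn]])
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.table(contig = cn, start = starts,
               end = pmin(starts + as.integer(window_size), len))
  }))
  win[, partial := (end - start) < window_size]
  win[]
}

#' Window-level allele specificity (relspec)
#'
#' Aggregates SNV sites into the given windows and computes, per window,
#' the number of SNVs, the summed counts of germline- and soma-specific
#' alleles (each specific allele contributes 1 per site, regardless of its
#' depth), and
#' \deqn{relspec = (\sum germline\text{-}specific - \sum soma\text{-}specific) / n_{SNVs}.}
#' Windows with fewer than `min_snvs` SNVs are emitted with `relspec = NA`
#' and are excluded from ranking (`eligible = FALSE`). With at most one
#' specific allele per site and class, relspec lies in [-1, 1].
#'
#' @param sites site table from [call_snv_sites()].
#' @param windows window table from [make_windows()] (regular tiling).
#' @param min_snvs minimum SNVs for a window to be eligible (default 20).
#' @return the window table with n_snvs, sum_germline_specific,
#'   sum_soma_specific, relspec, eligible.
#' @export
window_relspec <- function(sites, windows, min_snvs = 20L) {
  stopifnot(min_snvs >= 1L)
  win <- copy(windows)
  if (nrow(win) == 0L) {
    win[, `:=`(n_snvs = integer(), sum_germline_specific = integer(),
               sum_soma_specific = integer(), relspec = numeric(),
               eligible = logical())]
    return(win)
  }
  ws <- max(win$end - win$start)
  if (nrow(sites)) {
    agg <- sites[, .(n_snvs = .N,
                     sum_germline_specific = sum(n_germline_specific),
                     sum_soma_specific = sum(n_soma_specific)),
                 by = .(contig, start = (pos %/% ws) * ws)]
    win <- merge(win, agg, by = c("contig", "start"), all.x = TRUE)
  } else {
    win[, `:=`(n_snvs = NA_integer_, sum_germline_specific = NA_integer_,
               sum_soma_specific = NA_integer_)]
  }
  for (col in c("n_snvs", "sum_germline_specific", "sum_soma_specific"))
    set(win, which(is.na(win[[col]])), col, 0L)
  win[, eligible := n_snvs >= min_snvs]
  win[, relspec := fifelse(eligible,
                           (sum_germline_specific - sum_soma_specific) /
                             n_snvs, NA_real_)]
  setkey(win, contig, start)
  win[]
}

#' Select the top fraction of windows by relspec
#'
#' Eligible windows (those meeting the SNV minimum) are ranked by relspec
#' descending; `k = max(1, floor(top_fraction * n_eligible))` windows are
#' taken. Ties at the cut are broken deterministically by higher
#' `sum_germline_specific`, then genomic order, so the result does not
#' depend on input row order. Windows without a positive germline-specific
#' excess (relspec <= 0) are never selected; if no window has
#' relspec > 0 a typed error (`grcscan_no_selection`) is raised — the
#' explicit no-selection outcome for data without a GRC signal.
#'
#' @param stats window table from [window_relspec()].
#' @param top_fraction fraction of eligible windows to select
#'   (default 0.01).
#' @return the selected windows, genomic order, with attributes
#'   `n_eligible` and `k`.
#' @export
select_top_windows <- function(stats, top_fraction = 0.01) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  elig <- stats[eligible == TRUE & !is.na(relspec)]
  n_eligible <- nrow(elig)
  if (n_eligible == 0L)
    grcscan_error("grcscan_no_eligible_windows",
                  "select_top_windows: no window meets the SNV minimum")
  k <- max(1L, as.integer(floor(top_fraction * n_eligible)))
  ord <- elig[order(-relspec, -sum_germline_specific, contig, start)]
  sel <- ord[seq_len(k)][relspec > 0]
  if (nrow(sel) == 0L)
    grcscan_error("grcscan_no_selection",
                  paste0("select_top_windows: no window shows a positive ",
                         "germline-specific excess; nothing to select ",
                         "(is a GRC present?)"))
  sel <- sel[order(contig, start)]
  setattr(sel, "n_eligible", n_eligible)
  setattr(sel, "k", k)
  sel[]
}
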