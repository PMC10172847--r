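#' Simulate a somatic reference and a diverged GRC
#'
#' Draws `n_contigs` uniform-random A-chromosome contigs, places
#' `n_grc_segments` non-overlapping donor intervals across at least two
#' distinct contigs, and derives the GRC from the donor sequence by point
#' substitutions at a `divergence` fraction of positions (never back to the
#' reference base). Heterozygous sites at `het_rate` define a second
#' A-chromosome haplotype shared by soma and germline. If
#' `multicopy_region` is set, that segment is present in multiple tandem
#' copies in the GRC truth.
#'
#' The number of diverged positions per segment is exactly
#' `round(divergence * segment_length)` (sampled without replacement), so
#' planted-site counts are deterministic given the configuration.
#'
#' @param config a [sim_config()] object.
#' @return a `grc_sim_reference` list with elements `contigs` (named
#'   character vector, haplotype 1 = the reference FASTA), `hap2` (second
#'   A-chromosome haplotype), `grc_segments` (diverged donor sequences, one
#'   per segment), and `truth` (`segments`, `diverged_sites`, `het_sites`
#'   data.tables; all coordinates 0-based).
#' @export
simulate_reference <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  contig_names <- sprintf("achr%02d", seq_len(config$n_contigs))
  contigs <- stats::setNames(vapply(seq_len(config$n_contigs), function(i) {
    paste(sample(DNA_BASES, config$contig_length_bp, replace = TRUE),
          collapse = "")
  }, character(1L)), contig_names)

  ## heterozygous A-chr sites -> haplotype 2
  het_list <- lapply(contig_names, function(cn) {
    n_het <- rbinom(1L, config$contig_length_bp, config$het_rate)
    if (n_het == 0L)
      return(data.table(contig = character(), pos = integer(),
                        ref_base = character(), alt_base = character()))
    p1 <- sort(sample.int(config$contig_length_bp, n_het)) # 1-based
    refb <- substring(contigs[[cn]], p1, p1)
    data.table(contig = cn, pos = p1 - 1L, ref_base = refb,
               alt_base = mutate_bases(refb))
  })
  het_sites <- rbindlist(het_list)
  hap2 <- contigs
  for (cn in contig_names) {
    h <- het_sites[contig == cn]
    if (nrow(h)) hap2[[cn]] <- splice_substitutions(contigs[[cn]],
                                                    h$pos + 1L, h$alt_base)
  }

  ## donor segment placement (aligned grid, non-overlapping, >= 2 contigs)
  seg <- place_segments(config)

  ## divergence: exact count per segment, positions unique within segment
  div_list <- vector("list", nrow(seg))
  grc_segments <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    L <- seg$length[i]
    donor <- substring(contigs[[seg$donor_contig[i]]],
                       seg$donor_start[i] + 1L, seg$donor_start[i] + L)
    n_div <- round(config$divergence * L)
    if (n_div > 0L) {
      loc <- sort(sample.int(L, n_div)) # 1-based within segment
      refb <- substring(donor, loc, loc)
      grcb <- mutate_bases(refb)
      grc_segments[i] <- splice_substitutions(donor, loc, grcb)
      div_list[[i]] <- data.table(
        segment_id = seg$segment_id[i], contig = seg$donor_contig[i],
        pos = seg$donor_start[i] + loc - 1L, ref_base = refb,
        grc_base = grcb)
    } else {
      grc_segments[i] <- donor
      div_list[[i]] <- data.table(segment_id = character(),
                                  contig = character(), pos = integer(),
                                  ref_base = character(),
                                  grc_base = character())
    }
  }
  names(grc_segments) <- seg$segment_id
  diverged_sites <- rbindlist(div_list)

  structure(list(
    contigs = contigs,
    hap2 = hap2,
    grc_segments = grc_segments,
    truth = list(segments = seg, diverged_sites = diverged_sites,
                 het_sites = het_sites),
    config = config
  ), class = "grc_sim_reference")
}

## Place n_grc_segments donor intervals on an alignment grid without
## overlap, spanning >= 2 distinct contigs (when more than one exists).
## Bounded retries, then an explicit error -- never a silent overlap.
#' @keywords internal
place_segments <- function(config, max_tries = 200L) {
  n <- config$n_grc_segments
  base_len <- config$grc_total_bp %/% n
  seg_len <- rep(base_len, n)
  seg_len[n] <- seg_len[n] + config$grc_total_bp - sum(seg_len)
  if (any(seg_len < 1L))
    stop("simulate_reference: grc_total_bp too small for n_grc_segments")
  if (max(seg_len) > config$contig_length_bp)
    stop("simulate_reference: segment length exceeds contig length")
  contig_names <- sprintf("achr%02d", seq_len(config$n_contigs))
  align <- config$segment_align

  for (try in seq_len(max_tries)) {
    placed_contig <- character(n)
    placed_start <- integer(n)
    occupied <- lapply(contig_names, function(x) integer(0)) # occupied grid cells
    names(occupied) <- contig_names
    ok <- TRUE
    for (i in seq_len(n)) {
      L <- seg_len[i]
      max_start <- config$contig_length_bp - L
      slots <- seq(0L, (max_start %/% align) * align, by = align)
      ## a candidate occupies grid cells [start, start+L); sample among
      ## the free slots of all contigs jointly
      cells <- function(s) seq(s %/% align, (s + L - 1L) %/% align)
      free <- rbindlist(lapply(contig_names, function(cn) {
        f <- slots[vapply(slots, function(s)
          !any(cells(s) %in% occupied[[cn]]), logical(1L))]
        if (length(f)) data.table(contig = cn, slot = f) else NULL
      }))
      if (is.null(free) || nrow(free) == 0L) { ok <- FALSE; break }
      pick <- free[sample.int(nrow(free), 1L)]
      placed_contig[i] <- pick$contig
      placed_start[i] <- pick$slot
      occupied[[pick$contig]] <- c(occupied[[pick$contig]],
                                   cells(pick$slot))
    }
    if (!ok) next
    if (config$n_contigs > 1L && length(unique(placed_contig)) < 2L) next
    mc <- config$multicopy_region
    copies <- rep(1L, n)
    if (!is.null(mc)) copies[mc$segment] <- as.integer(mc$copies)
    return(data.table(
      segment_id = sprintf("grc_seg%02d", seq_len(n)),
      donor_contig = placed_contig,
      donor_start = placed_start,
      donor_end = placed_start + seg_len,
      length = seg_len,
      copies = copies))
  }
  stop("simulate_reference: could not place ", n, " non-overlapping donor ",
       "segments across >= 2 contigs after ", max_tries, " attempts; ",
       "reduce grc_total_bp or n_grc_segments, or enlarge the reference")
}
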