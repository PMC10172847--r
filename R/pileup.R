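#' Count alleles per reference position in soma and germline samples
#'
#' Joint per-position nucleotide counts over the two alignment sets,
#' computed from primary alignments only (secondary, supplementary and
#' unmapped records are excluded; reads below `min_mapq` are skipped).
#' One row per position covered in either sample. Positions are 0-based
#' internally; [write_sites()] emits 1-based coordinates.
#'
#' @param soma,germline paths to coordinate-sorted, indexed BAM files
#'   (SAM paths are converted on the fly).
#' @param min_mapq mapping-quality floor (default 0: a permissive mapping
#'   run already reflects the intended cross-mapping behaviour).
#' @param max_depth per-position depth cap in the pileup engine.
#' @return data.table: contig, pos (0-based), soma_A/C/G/T,
#'   germline_A/C/G/T.
#' @export
count_alleles <- function(soma, germline, min_mapq = 0L,
                          max_depth = 100000L) {
  s <- pileup_base_counts(soma, "soma", min_mapq, max_depth)
  g <- pileup_base_counts(germline, "germline", min_mapq, max_depth)
  counts <- merge(s, g, by = c("contig", "pos"), all = TRUE)
  for (col in setdiff(names(counts), c("contig", "pos")))
    set(counts, which(is.na(counts[[col]])), col, 0L)
  setkey(counts, contig, pos)
  counts[]
}

#' @keywords internal
pileup_base_counts <- function(path, prefix, min_mapq, max_depth) {
  if (grepl("\\.sam$", path)) path <- sam_to_bam(path)
  if (!file.exists(paste0(path, ".bai")))
    Rsamtools::indexBam(path) # fails loudly on unsorted input
  fl <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                               isSecondaryAlignment = FALSE,
                               isSupplementaryAlignment = FALSE)
  pp <- Rsamtools::PileupParam(max_depth = as.integer(max_depth),
                               min_base_quality = 0L,
                               min_mapq = as.integer(min_mapq),
                               min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(path,
                         scanBamParam = Rsamtools::ScanBamParam(flag = fl),
                         pileupParam = pp)
  dt <- as.data.table(p)
  dt <- dt[nucleotide %in% DNA_BASES]
  if (nrow(dt) == 0L) {
    out <- data.table(contig = character(), pos = integer())
    for (b in DNA_BASES) out[, paste0(prefix, "_", b) := integer()]
    return(out)
  }
  dt[, nucleotide := factor(as.character(nucleotide), levels = DNA_BASES)]
  wide <- dcast(dt, seqnames + pos ~ nucleotide, value.var = "count",
                fill = 0L, drop = c(TRUE, FALSE))
  setnames(wide, c("contig", "pos", paste0(prefix, "_", DNA_BASES)))
  wide[, contig := as.character(contig)]
  wide[, pos := pos - 1L] # 0-based internally
  wide
}

#' Call candidate SNV sites with depth filters and allele specificity
#'
#' A site is emitted when (i) total soma depth meets `soma_min_depth`,
#' (ii) total germline depth meets `germline_min_depth`, and (iii) after
#' pruning low-depth alleles the union of alleles across both samples has
#' at least two members (reference-agnostic polymorphism). "Depth" is the
#' total read count at the site in that sample (pruned alleles still count
#' toward depth). With `ignore_singletons` (the default), alleles seen
#' only once in a sample are pruned from that sample's allele set before
#' any set operation — symmetrically in both samples. Germline-specific
#' alleles are those in the germline set but not the soma set;
#' soma-specific is the converse.
#'
#' Thresholds may be given as `"auto"`, which sets each to half the
#' median depth of the corresponding sample over covered positions.
#'
#' @param counts output of [count_alleles()].
#' @param soma_min_depth minimum soma depth (default 15) or `"auto"`.
#' @param germline_min_depth minimum germline depth (default 45) or
#'   `"auto"`.
#' @param ignore_singletons prune alleles of depth <= 1 (default TRUE).
#' @return data.table: contig, pos (0-based), soma_depth, germline_depth,
#'   allele sets as comma-separated strings (soma_alleles,
#'   germline_alleles, germline_specific, soma_specific), counts
#'   n_germline_specific / n_soma_specific, and a `multiallelic` flag
#'   (more than two alleles in the pruned union).
#' @export
call_snv_sites <- function(counts, soma_min_depth = 15L,
                           germline_min_depth = 45L,
                           ignore_singletons = TRUE) {
  sm <- as.matrix(counts[, paste0("soma_", DNA_BASES), with = FALSE])
  gm <- as.matrix(counts[, paste0("germline_", DNA_BASES), with = FALSE])
  soma_depth_v <- as.integer(rowSums(sm))
  germ_depth_v <- as.integer(rowSums(gm))

  if (identical(soma_min_depth, "auto"))
    soma_min_depth <- round(median(soma_depth_v[soma_depth_v > 0]) / 2)
  if (identical(germline_min_depth, "auto"))
    germline_min_depth <- round(median(germ_depth_v[germ_depth_v > 0]) / 2)

  min_count <- if (ignore_singletons) 2L else 1L
  has_s <- sm >= min_count
  has_g <- gm >= min_count
  n_union <- rowSums(has_s | has_g)

  keep <- soma_depth_v >= soma_min_depth &
    germ_depth_v >= germline_min_depth & n_union >= 2L
  if (!any(keep)) {
    return(data.table(contig = character(), pos = integer(),
                      soma_depth = integer(), germline_depth = integer(),
                      soma_alleles = character(),
                      germline_alleles = character(),
                      germline_specific = character(),
                      soma_specific = character(),
                      n_germline_specific = integer(),
                      n_soma_specific = integer(),
                      multiallelic = logical()))
  }

  hs <- has_s[keep, , drop = FALSE]
  hg <- has_g[keep, , drop = FALSE]
  gspec <- hg & !hs
  sspec <- hs & !hg

  out <- data.table(
    contig = counts$contig[keep],
    pos = counts$pos[keep],
    soma_depth = soma_depth_v[keep],
    germline_depth = germ_depth_v[keep],
    soma_alleles = collapse_allele_sets(hs),
    germline_alleles = collapse_allele_sets(hg),
    germline_specific = collapse_allele_sets(gspec),
    soma_specific = collapse_allele_sets(sspec),
    n_germline_specific = as.integer(rowSums(gspec)),
    n_soma_specific = as.integer(rowSums(sspec)),
    multiallelic = n_union[keep] > 2L)
  attr(out, "soma_min_depth") <- soma_min_depth
  attr(out, "germline_min_depth") <- germline_min_depth
  out[]
}

## logical site x base matrix -> "A,G"-style strings
#' @keywords internal
collapse_allele_sets <- function(m) {
  out <- character(nrow(m))
  for (j in seq_along(DNA_BASES))
    out <- paste0(out, ifelse(m[, j], paste0(DNA_BASES[j], ","), ""))
  sub(",$", "", out)
}
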