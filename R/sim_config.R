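#' Simulation configuration
#'
#' Parameters of the ground-truthed synthetic soma/germline dataset. The
#' defaults emulate the coverage structure of a single-individual songbird
#' study design: soma (blood) reads at ~30x on the A-chromosomes, germline
#' (testis) reads at ~88x on the A-chromosomes, and GRC-derived germline
#' reads at ~24x — the GRC being haploid and present only in a fraction of
#' testis cells, its effective depth is well below the A-chromosome depth.
#' Reads are HiFi-like: long (mean 18 kb) with a low substitution error
#' rate.
#'
#' @param seed integer seed; all simulation randomness derives from it.
#' @param n_contigs number of A-chromosome contigs.
#' @param contig_length_bp length of each A-chromosome contig (bp).
#' @param grc_total_bp total length of distinct GRC sequence (bp), split
#'   into `n_grc_segments` donor segments copied from the A-chromosomes.
#' @param n_grc_segments number of GRC donor segments; placed without
#'   overlap across at least two distinct contigs.
#' @param divergence fraction of GRC positions substituted relative to the
#'   A-chromosome donor segment, in (0, 0.2] (0 allowed for the degenerate
#'   identity dataset).
#' @param soma_depth mean fold-coverage of soma reads on the A-chromosomes.
#' @param germline_achr_depth mean fold-coverage of germline reads on the
#'   A-chromosomes.
#' @param grc_cell_fraction_depth mean fold-coverage of germline reads on
#'   the GRC (per GRC copy); must be below `germline_achr_depth`.
#' @param read_length_mean,read_length_sd read length distribution (bp);
#'   lengths are normal, rounded, and clamped to the containing sequence.
#' @param error_rate per-base substitution error rate in [0, 0.02].
#' @param multicopy_region `NULL`, or `list(segment = i, copies = k)`:
#'   segment `i` is present in `k` tandem copies on the GRC. Reads from all
#'   copies map to the single donor locus, producing the coverage pile-up
#'   that copy-number estimation must recover.
#' @param het_rate per-base heterozygosity on the A-chromosomes; soma and
#'   germline share the same diploid genotypes, so heterozygous alleles
#'   appear in both samples and exercise the "shared allele" class of the
#'   specificity classifier.
#' @param cross_map_depth mean fold-coverage of soma reads cross-mapping
#'   onto the GRC assembly under stringent mapping (used by
#'   [simulate_validation_dataset()]); germline cross-mapping scales with
#'   the germline:soma sequencing effort.
#' @param segment_align placement grid for donor segments (bp). Segment
#'   starts snap to multiples of this value so that analysis windows of the
#'   same size have unambiguous truth labels. Set to 1 for unrestricted
#'   placement.
#' @return a `grcscan_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 5L,
                       contig_length_bp = 1000000L,
                       grc_total_bp = 200000L,
                       n_grc_segments = 8L,
                       divergence = 0.01,
                       soma_depth = 30,
                       germline_achr_depth = 88,
                       grc_cell_fraction_depth = 24,
                       read_length_mean = 18000,
                       read_length_sd = 3000,
                       error_rate = 5e-4,
                       multicopy_region = list(segment = 1L, copies = 5L),
                       het_rate = 1e-3,
                       cross_map_depth = 0.4,
                       segment_align = 25000L) {
  cfg <- structure(list(
    seed = as.integer(seed),
    n_contigs = as.integer(n_contigs),
    contig_length_bp = as.integer(contig_length_bp),
    grc_total_bp = as.integer(grc_total_bp),
    n_grc_segments = as.integer(n_grc_segments),
    divergence = divergence,
    soma_depth = soma_depth,
    germline_achr_depth = germline_achr_depth,
    grc_cell_fraction_depth = grc_cell_fraction_depth,
    read_length_mean = read_length_mean,
    read_length_sd = read_length_sd,
    error_rate = error_rate,
    multicopy_region = multicopy_region,
    het_rate = het_rate,
    cross_map_depth = cross_map_depth,
    segment_align = as.integer(segment_align)
  ), class = "grcscan_sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @keywords internal
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "grcscan_sim_config"))
  with(cfg, {
    if (is.na(seed)) stop("sim_config: seed is mandatory")
    stopifnot(n_contigs >= 1L, contig_length_bp >= 1000L,
              grc_total_bp >= 0L, n_grc_segments >= 1L)
    if (!(divergence >= 0 && divergence <= 0.2))
      stop("sim_config: divergence must be in [0, 0.2]")
    if (!(error_rate >= 0 && error_rate <= 0.02))
      stop("sim_config: error_rate must be in [0, 0.02]")
    if (soma_depth < 0 || germline_achr_depth <= 0 ||
        grc_cell_fraction_depth < 0)
      stop("sim_config: depths must be positive")
    if (grc_cell_fraction_depth >= germline_achr_depth)
      stop("sim_config: grc_cell_fraction_depth must be below ",
           "germline_achr_depth (the GRC is haploid and present only in ",
           "a fraction of germline cells)")
    if (het_rate < 0 || het_rate > 0.05)
      stop("sim_config: het_rate out of range")
    if (cross_map_depth < 0)
      stop("sim_config: cross_map_depth must be >= 0")
    if (!is.null(multicopy_region)) {
      stopifnot(is.list(multicopy_region),
                all(c("segment", "copies") %in% names(multicopy_region)))
      if (multicopy_region$segment > n_grc_segments)
        stop("sim_config: multicopy_region$segment exceeds n_grc_segments")
      if (multicopy_region$copies < 1L)
        stop("sim_config: multicopy_region$copies must be >= 1")
    }
    stopifnot(read_length_mean > 0, read_length_sd >= 0, segment_align >= 1L)
  })
  invisible(cfg)
}
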