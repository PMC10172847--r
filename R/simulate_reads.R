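#' Simulate HiFi-like soma and germline read sets
#'
#' Read starts follow a Poisson process matching the target fold-coverage
#' (expected read count per sequence = length x depth / mean read length).
#' Soma reads are drawn from the two A-chromosome haplotypes (50/50);
#' germline reads come from the A-chromosome haplotypes at
#' `germline_achr_depth` plus the single GRC haplotype at
#' `grc_cell_fraction_depth` per GRC copy. GRC reads are sampled wholly
#' within their donor segment so every alignment is a single ungapped
#' block. Per-base substitution errors are applied at `error_rate`. Read
#' ids are assigned after shuffling and encode nothing about origin.
#'
#' @param config a [sim_config()] object.
#' @param ref a [simulate_reference()] result.
#' @return a `grc_sim_reads` list with data.tables `soma` and `germline`
#'   (columns `read_id`, `contig`, `start` (0-based alignment start on the
#'   somatic reference), `length`, `seq`) and `truth_reads` (read_id,
#'   sample, origin A-chr|GRC, segment_id, n_errors).
#' @export
simulate_reads <- function(config, ref) {
  stopifnot(inherits(ref, "grc_sim_reference"))
  set.seed(config$seed + 1L)

  soma <- sim_achr_read_block(config, ref, config$soma_depth)
  germ_a <- sim_achr_read_block(config, ref, config$germline_achr_depth)
  germ_g <- sim_grc_read_block(config, ref, config$grc_cell_fraction_depth)

  finish <- function(dt, sample_name) {
    if (nrow(dt) == 0L) {
      dt[, read_id := character(0)]
      return(dt)
    }
    dt <- dt[sample.int(nrow(dt))] # shuffle: ids carry no origin signal
    dt[, read_id := sprintf("%s_%07d", sample_name, .I)]
    dt
  }
  soma <- finish(soma, "soma")
  germline <- finish(rbind(germ_a, germ_g), "germline")

  truth_reads <- rbind(
    soma[, .(read_id, sample = "soma", origin, segment_id, contig, start,
             length, n_errors)],
    germline[, .(read_id, sample = "germline", origin, segment_id, contig,
                 start, length, n_errors)])

  structure(list(
    soma = soma[, .(read_id, contig, start, length, seq)],
    germline = germline[, .(read_id, contig, start, length, seq)],
    truth_reads = truth_reads,
    config = config
  ), class = "grc_sim_reads")
}

#' @keywords internal
empty_read_block <- function() {
  data.table(contig = character(), start = integer(), length = integer(),
             seq = character(), origin = character(),
             segment_id = character(), n_errors = integer())
}

## Draw reads from one source sequence (0-based target coordinates).
#' @keywords internal
draw_reads_from <- function(config, seq_string, target_contig, offset,
                            depth, origin, segment_id) {
  L <- nchar(seq_string)
  n <- rpois(1L, L * depth / config$read_length_mean)
  if (n == 0L) return(empty_read_block())
  rl <- pmin(pmax(as.integer(round(rnorm(n, config$read_length_mean,
                                         config$read_length_sd))), 200L), L)
  start_local <- as.integer(floor(runif(n, 0, L - rl + 1))) # 0-based
  seqs <- substring(seq_string, start_local + 1L, start_local + rl)
  n_err <- rbinom(n, rl, config$error_rate)
  for (i in which(n_err > 0L)) {
    p <- sample.int(rl[i], n_err[i])
    seqs[i] <- splice_substitutions(seqs[i], p,
                                    mutate_bases(substring(seqs[i], p, p)))
  }
  data.table(contig = target_contig, start = offset + start_local,
             length = rl, seq = seqs, origin = origin,
             segment_id = segment_id, n_errors = n_err)
}

#' @keywords internal
sim_achr_read_block <- function(config, ref, depth) {
  if (depth <= 0) return(empty_read_block())
  blocks <- lapply(names(ref$contigs), function(cn) {
    ## split target depth over the two haplotypes; per-haplotype Poisson
    h1 <- draw_reads_from(config, ref$contigs[[cn]], cn, 0L, depth / 2,
                          "A-chr", NA_character_)
    h2 <- draw_reads_from(config, ref$hap2[[cn]], cn, 0L, depth / 2,
                          "A-chr", NA_character_)
    rbind(h1, h2)
  })
  rbindlist(blocks)
}

#' @keywords internal
sim_grc_read_block <- function(config, ref, depth) {
  seg <- ref$truth$segments
  if (depth <= 0 || nrow(seg) == 0L) return(empty_read_block())
  blocks <- lapply(seq_len(nrow(seg)), function(i) {
    per_copy <- lapply(seq_len(seg$copies[i]), function(k) {
      draw_reads_from(config, ref$grc_segments[[seg$segment_id[i]]],
                      seg$donor_contig[i], seg$donor_start[i], depth,
                      "GRC", seg$segment_id[i])
    })
    rbindlist(per_copy)
  })
  rbindlist(blocks)
}
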