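#' Emit simulated reads as coordinate-sorted SAM records
#'
#' Each read becomes one primary, forward-strand alignment at its true
#' locus on the somatic reference: A-chromosome reads at their sampled
#' position, GRC reads at the homologous coordinates of their donor
#' segment (all copies of a multicopy segment at the single donor locus,
#' producing the coverage pile-up that copy-number estimation detects).
#' CIGARs are a single match run (substitution-only simulation, no
#' indels); NM and MD tags are computed against the reference so that the
#' records are consistent with their mismatches.
#'
#' @param reads one read table from [simulate_reads()] (`$soma` or
#'   `$germline`): columns `read_id`, `contig`, `start` (0-based),
#'   `length`, `seq`.
#' @param ref a [simulate_reference()] result.
#' @param sam_path output SAM path.
#' @param bam convert to a sorted, indexed BAM next to `sam_path`
#'   (default TRUE).
#' @return path to the BAM (or SAM when `bam = FALSE`), invisibly.
#' @export
simulate_alignments <- function(reads, ref, sam_path, bam = TRUE) {
  stopifnot(inherits(ref, "grc_sim_reference"),
            all(c("read_id", "contig", "start", "length", "seq") %in%
                  names(reads)))
  contig_names <- names(ref$contigs)
  if (nrow(reads) && !all(reads$contig %in% contig_names))
    stop("simulate_alignments: read aligned to unknown contig")
  if (nrow(reads) &&
      any(reads$start + reads$length > nchar(ref$contigs[reads$contig])))
    stop("simulate_alignments: read extends beyond its contig ",
         "(segment-boundary violation)")

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", contig_names,
                      nchar(ref$contigs[contig_names])),
              "@PG\tID:grcscan\tPN:grcscan")

  body <- character(0)
  if (nrow(reads)) {
    dt <- reads[order(match(contig, contig_names), start)]
    nm <- integer(nrow(dt))
    md <- character(nrow(dt))
    for (i in seq_len(nrow(dt))) {
      refsub <- substring(ref$contigs[[dt$contig[i]]], dt$start[i] + 1L,
                          dt$start[i] + dt$length[i])
      mm <- string_mismatch_positions(dt$seq[i], refsub)
      nm[i] <- length(mm)
      if (length(mm) == 0L) {
        md[i] <- as.character(dt$length[i])
      } else {
        gaps <- diff(c(0L, mm)) - 1L
        md[i] <- paste0(paste0(gaps, substring(refsub, mm, mm),
                               collapse = ""),
                        dt$length[i] - mm[length(mm)])
      }
    }
    body <- paste(dt$read_id, 0L, dt$contig, dt$start + 1L, 60L,
                  paste0(dt$length, "M"), "*", 0L, 0L, dt$seq, "*",
                  paste0("NM:i:", nm), paste0("MD:Z:", md), sep = "\t")
  }
  writeLines(c(header, body), sam_path)
  out <- sam_path
  if (bam) {
    dest <- sub("\\.sam$", "", sam_path)
    out <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                            indexDestination = TRUE)
  }
  invisible(out)
}
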