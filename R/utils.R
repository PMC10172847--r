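DNA_BASES <- c("A", "C", "G", "T")

#' Apply single-base substitutions to a sequence string
#'
#' Builds the mutated string by splicing around the substituted positions,
#' which is far cheaper than repeated `substr<-` on long strings.
#'
#' @param s character scalar (sequence).
#' @param pos 1-based positions to substitute (unique).
#' @param bases replacement bases, same length as `pos`.
#' @return the mutated string.
#' @keywords internal
splice_substitutions <- function(s, pos, bases) {
  if (length(pos) == 0L) return(s)
  o <- order(pos)
  pos <- pos[o]
  bases <- bases[o]
  n <- nchar(s)
  stopifnot(pos[1L] >= 1L, pos[length(pos)] <= n, !anyDuplicated(pos))
  pieces <- substring(s, c(1L, pos + 1L), c(pos - 1L, n))
  paste0(paste0(pieces[seq_along(pos)], bases, collapse = ""),
         pieces[length(pos) + 1L])
}

#' Mutate bases to a different base, uniformly among the other three
#' @param ref_bases character vector of bases in A/C/G/T.
#' @return character vector of bases, each differing from its input.
#' @keywords internal
mutate_bases <- function(ref_bases) {
  n <- length(ref_bases)
  if (n == 0L) return(character())
  idx <- match(ref_bases, DNA_BASES)
  stopifnot(!anyNA(idx))
  DNA_BASES[((idx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L]
}

#' Positions at which two equal-length strings differ
#' @keywords internal
string_mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

#' Contig lengths of a FASTA file
#'
#' Indexes the FASTA if needed and returns a named integer vector of
#' sequence lengths.
#'
#' @param fasta path to a FASTA file.
#' @return named numeric vector of contig lengths.
#' @export
reference_lengths <- function(fasta) {
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  idx <- Rsamtools::scanFaIndex(fasta)
  stats::setNames(GenomicRanges::width(idx),
                  as.character(GenomicRanges::seqnames(idx)))
}

#' N50 of a set of contig lengths
#'
#' The length L such that contigs of length >= L together cover at least
#' half the total assembly length. When the cumulative sum hits exactly
#' half, the tie is resolved toward the larger contig set (the next,
#' smaller length), so `n50(c(100, 50, 40, 10))` is 50, not 100.
#'
#' @param lengths positive numeric vector of contig lengths.
#' @return the N50 length.
#' @examples
#' n50(c(100, 50, 40, 10)) # 50
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) > 0L, all(lengths > 0))
  l <- sort(as.numeric(lengths), decreasing = TRUE)
  l[which(cumsum(l) > sum(l) / 2)[1L]]
}

## Condition constructors used for typed pipeline errors
grcscan_error <- function(class, message, ...) {
  stop(structure(class = c(class, "grcscan_error", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
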