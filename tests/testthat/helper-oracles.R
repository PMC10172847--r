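## Independent oracles, deliberately implemented by brute force / closed
## form, never via the package's own code paths.

## relspec recomputed per window by looping over the raw allele-set
## strings (the implementation aggregates the count columns instead).
relspec_oracle <- function(sites, windows, min_snvs) {
  n_alleles <- function(s) if (is.na(s) || s == "") 0L else
    length(strsplit(s, ",", fixed = TRUE)[[1L]])
  vapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i]
    rows <- sites[sites$contig == w$contig & sites$pos >= w$start &
                    sites$pos < w$end, ]
    if (nrow(rows) < min_snvs) return(NA_real_)
    gs <- sum(vapply(rows$germline_specific, n_alleles, integer(1L)))
    ss <- sum(vapply(rows$soma_specific, n_alleles, integer(1L)))
    (gs - ss) / nrow(rows)
  }, numeric(1L))
}

## Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
## assignments (valid for tie-free differences).
signed_rank_p_enum <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n >= 1L, n <= 16L, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Vs <= V), mean(Vs >= V)))
}

## Pearson r and two-sided p from the closed form.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

## N50 by scanning candidate lengths: the largest length l in the set such
## that contigs of length >= l cover strictly more than half the total
## (the tie-toward-larger-set convention).
n50_oracle <- function(lengths) {
  total <- sum(lengths)
  for (l in sort(unique(lengths), decreasing = TRUE))
    if (sum(lengths[lengths >= l]) > total / 2) return(l)
  min(lengths)
}

## Random site tables for the relspec oracle: allele-set strings and the
## count columns are generated together so both code paths see the same
## sites.
random_specificity_sites <- function(n_sites, contigs, contig_len) {
  pick <- function() {
    k <- sample(0:2, 1L, prob = c(0.4, 0.5, 0.1))
    if (k == 0L) "" else paste(sample(c("A", "C", "G", "T"), k),
                               collapse = ",")
  }
  gs <- replicate(n_sites, pick())
  ss <- replicate(n_sites, pick())
  nall <- function(s) ifelse(s == "", 0L,
                             lengths(strsplit(s, ",", fixed = TRUE)))
  data.table(
    contig = sample(contigs, n_sites, replace = TRUE),
    pos = sample.int(contig_len, n_sites, replace = TRUE) - 1L,
    soma_depth = 30L, germline_depth = 90L,
    soma_alleles = "A", germline_alleles = "A",
    germline_specific = gs, soma_specific = ss,
    n_germline_specific = nall(gs), n_soma_specific = nall(ss),
    multiallelic = FALSE)
}
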