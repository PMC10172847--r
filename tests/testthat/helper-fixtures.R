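suppressMessages(library(data.table))

## Small, fast study-shaped configuration for unit tests: same structure as
## the default conditions, scaled down (3 x 100 kb contigs, 4 x 5 kb GRC
## segments, 5 kb analysis windows, shorter reads, proportional depths).
tiny_sim_config <- function(seed = 42L, ...) {
  args <- list(
    seed = seed, n_contigs = 3L, contig_length_bp = 100000L,
    grc_total_bp = 20000L, n_grc_segments = 4L, divergence = 0.01,
    soma_depth = 20, germline_achr_depth = 50, grc_cell_fraction_depth = 15,
    read_length_mean = 3000, read_length_sd = 500, error_rate = 5e-4,
    multicopy_region = list(segment = 1L, copies = 5L), het_rate = 1e-3,
    segment_align = 5000L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

tiny_window_size <- 5000L
tiny_soma_min <- 10L
tiny_germline_min <- 25L
tiny_min_snvs <- 4L

.fixtures <- new.env(parent = emptyenv())

## One shared tiny dataset per test run (simulation + BAMs take a few
## seconds; most tests only read from it).
tiny_dataset <- function() {
  if (is.null(.fixtures$tiny)) {
    dir <- file.path(tempdir(), "grcscan-tiny-fixture")
    .fixtures$tiny <- simulate_dataset(tiny_sim_config(), dir,
                                       window_size = tiny_window_size)
  }
  .fixtures$tiny
}

## Pileup + site calls on the tiny dataset, cached.
tiny_sites <- function() {
  if (is.null(.fixtures$tiny_sites)) {
    d <- tiny_dataset()
    counts <- count_alleles(d$paths$soma, d$paths$germline)
    .fixtures$tiny_counts <- counts
    .fixtures$tiny_sites <- call_snv_sites(counts, tiny_soma_min,
                                           tiny_germline_min)
  }
  .fixtures$tiny_sites
}

tiny_counts <- function() {
  tiny_sites()
  .fixtures$tiny_counts
}

## A minimal reference wrapper so tests can emit hand-built reads as SAM.
fake_reference <- function(contigs) {
  structure(list(contigs = contigs), class = "grc_sim_reference")
}

write_test_alignments <- function(reads, contigs, path) {
  simulate_alignments(as.data.table(reads), fake_reference(contigs), path,
                      bam = TRUE)
}

## Build a SiteAlleleCounts-style table from per-base count lists, e.g.
## make_counts(list(c1 = list(`100` = list(soma = c(A = 20),
##                                         germline = c(A = 40, G = 8)))))
make_counts <- function(spec) {
  rows <- list()
  for (cn in names(spec)) for (ps in names(spec[[cn]])) {
    row <- data.table(contig = cn, pos = as.integer(ps))
    for (side in c("soma", "germline")) {
      v <- spec[[cn]][[ps]][[side]]
      for (b in c("A", "C", "G", "T"))
        row[, paste0(side, "_", b) := if (!is.null(v) && b %in% names(v))
          as.integer(v[[b]]) else 0L]
    }
    rows[[length(rows) + 1L]] <- row
  }
  rbindlist(rows)
}

md5_of <- function(files) unname(tools::md5sum(sort(files)))
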