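test_that("unanimous coverage gives unanimous counts", {
  dir <- withr::local_tempdir()
  ctg <- c(c1 = paste(rep("ACGT", 25L), collapse = ""))
  reads <- data.table(read_id = sprintf("r%d", 1:10), contig = "c1",
                      start = 10L, length = 40L,
                      seq = substring(ctg, 11L, 50L))
  soma <- write_test_alignments(reads, ctg, file.path(dir, "s.sam"))
  germ <- write_test_alignments(reads[1:2], ctg, file.path(dir, "g.sam"))
  counts <- count_alleles(soma, germ)
  expect_equal(nrow(counts), 40L)
  expect_equal(counts$pos, 10:49)
  base_cols <- paste0("soma_", c("A", "C", "G", "T"))
  expect_true(all(rowSums(counts[, ..base_cols]) == 10L))
  ## each position unanimous for the reference base
  refb <- substring(ctg, counts$pos + 1L, counts$pos + 1L)
  for (b in c("A", "C", "G", "T"))
    expect_true(all(counts[[paste0("soma_", b)]][refb == b] == 10L))
})

test_that("empty alignment files give an empty stream", {
  dir <- withr::local_tempdir()
  ctg <- c(c1 = strrep("ACGT", 25L))
  empty <- data.table(read_id = character(), contig = character(),
                      start = integer(), length = integer(),
                      seq = character())
  s <- write_test_alignments(empty, ctg, file.path(dir, "es.sam"))
  g <- write_test_alignments(empty, ctg, file.path(dir, "eg.sam"))
  counts <- count_alleles(s, g)
  expect_equal(nrow(counts), 0L)
  expect_equal(nrow(call_snv_sites(counts, 1L, 1L)), 0L)
})

test_that("planted diverged sites show the GRC allele at cell-fraction depth", {
  d <- tiny_dataset()
  counts <- tiny_counts()
  div <- d$reference$truth$diverged_sites
  seg <- d$reference$truth$segments
  single <- div[segment_id %in% seg[copies == 1L, segment_id]]
  m <- counts[single, on = c("contig", "pos"), nomatch = NULL]
  stopifnot(nrow(m) > 100L)
  grc_depth <- vapply(seq_len(nrow(m)), function(i)
    m[[paste0("germline_", m$grc_base[i])]][i], integer(1L))
  cfg <- d$config
  ## mean over sites tracks the configured GRC depth (edge ramps included)
  expect_gt(mean(grc_depth), 0.5 * cfg$grc_cell_fraction_depth)
  expect_lt(mean(grc_depth), 1.5 * cfg$grc_cell_fraction_depth)
  ## soma almost never shows the GRC allele above singleton level
  soma_depth <- vapply(seq_len(nrow(m)), function(i)
    m[[paste0("soma_", m$grc_base[i])]][i], integer(1L))
  expect_gt(mean(soma_depth <= 1L), 0.99)
})

test_that("specificity classification follows the depth and pruning rules", {
  counts <- make_counts(list(c1 = list(
    `100` = list(soma = c(A = 20), germline = c(A = 40, G = 8)),
    `200` = list(soma = c(A = 20), germline = c(A = 44, G = 1)),
    `300` = list(soma = c(A = 14), germline = c(A = 40, G = 8)),
    `400` = list(soma = c(A = 18, C = 5), germline = c(A = 40, G = 8)),
    `500` = list(soma = c(A = 10, G = 10), germline = c(A = 30, G = 30)))))
  sites <- call_snv_sites(counts, 15L, 45L)
  ## textbook germline-specific allele
  s100 <- sites[pos == 100L]
  expect_equal(s100$germline_specific, "G")
  expect_equal(s100$soma_specific, "")
  expect_equal(s100$germline_depth, 48L)
  ## singleton pruned -> monomorphic -> not emitted (depth itself passes)
  expect_equal(nrow(sites[pos == 200L]), 0L)
  ## soma depth below threshold -> not emitted
  expect_equal(nrow(sites[pos == 300L]), 0L)
  ## both directions specific at one site
  s400 <- sites[pos == 400L]
  expect_equal(s400$soma_specific, "C")
  expect_equal(s400$germline_specific, "G")
  expect_true(s400$multiallelic)
  ## shared heterozygous site: polymorphic but nothing specific
  s500 <- sites[pos == 500L]
  expect_equal(nrow(s500), 1L)
  expect_equal(s500$n_germline_specific, 0L)
  expect_equal(s500$n_soma_specific, 0L)
})

test_that("singleton pruning is symmetric and switchable", {
  counts <- make_counts(list(c1 = list(
    `10` = list(soma = c(A = 19, G = 1), germline = c(A = 40, G = 9)))))
  pruned <- call_snv_sites(counts, 15L, 45L, ignore_singletons = TRUE)
  expect_equal(pruned$germline_specific, "G") # soma G pruned
  kept <- call_snv_sites(counts, 15L, 45L, ignore_singletons = FALSE)
  expect_equal(kept$germline_specific, "") # soma G retained
})

test_that("auto thresholds are half the median sample depths", {
  counts <- make_counts(list(c1 = stats::setNames(lapply(1:9, function(i)
    list(soma = c(A = 10L * i), germline = c(A = 20L * i, G = 2L))),
    as.character(seq(10L, 90L, by = 10L)))))
  sites <- call_snv_sites(counts, "auto", "auto")
  expect_equal(attr(sites, "soma_min_depth"), 25) # median 50 / 2
  expect_equal(attr(sites, "germline_min_depth"), 51) # median 102 / 2
})

test_that("site count is monotonically non-increasing in each threshold", {
  set.seed(31L)
  n <- 400L
  counts <- data.table(contig = "c1", pos = seq_len(n))
  for (b in c("A", "C", "G", "T")) {
    counts[, paste0("soma_", b) := rpois(n, 8)]
    counts[, paste0("germline_", b) := rpois(n, 20)]
  }
  n_sites <- function(smin, gmin)
    nrow(call_snv_sites(counts, smin, gmin))
  for (th in list(c(10, 40), c(20, 40), c(10, 70))) {
    expect_lte(n_sites(th[1] + 5, th[2]), n_sites(th[1], th[2]))
    expect_lte(n_sites(th[1], th[2] + 10), n_sites(th[1], th[2]))
  }
})

test_that("error-free zero-divergence data has no specific alleles at all", {
  cfg <- tiny_sim_config(seed = 13L, divergence = 0, error_rate = 0,
                         multicopy_region = NULL)
  d <- simulate_dataset(cfg, file.path(tempdir(), "zerodiv"),
                        window_size = tiny_window_size, annotation = FALSE)
  counts <- count_alleles(d$paths$soma, d$paths$germline)
  sites <- call_snv_sites(counts, tiny_soma_min, tiny_germline_min)
  expect_gt(nrow(sites), 0L) # heterozygous sites are still SNVs
  expect_true(all(sites$n_germline_specific == 0L))
  expect_true(all(sites$n_soma_specific == 0L))
})

test_that("planted sites with adequate depth are recovered as germline-specific", {
  d <- tiny_dataset()
  sites <- tiny_sites()
  counts <- tiny_counts()
  div <- d$reference$truth$diverged_sites
  m <- counts[div, on = c("contig", "pos"), nomatch = NULL]
  grc_depth <- vapply(seq_len(nrow(m)), function(i)
    m[[paste0("germline_", m$grc_base[i])]][i], integer(1L))
  base_cols <- paste0("soma_", c("A", "C", "G", "T"))
  gl_cols <- paste0("germline_", c("A", "C", "G", "T"))
  adequate <- m[grc_depth >= 2L &
                  rowSums(m[, ..base_cols]) >= tiny_soma_min &
                  rowSums(m[, ..gl_cols]) >= tiny_germline_min,
                .(contig, pos, grc_base)]
  hit <- sites[adequate, on = c("contig", "pos"), nomatch = NULL]
  carried <- mapply(function(gs, b) b %in% strsplit(gs, ",")[[1L]],
                    hit$germline_specific, hit$grc_base)
  expect_gte(nrow(hit) / nrow(adequate), 0.98)
  expect_gte(mean(carried), 0.98)
})
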