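test_that("zero divergence yields a GRC identical to its donors", {
  cfg <- tiny_sim_config(seed = 5L, divergence = 0)
  ref <- simulate_reference(cfg)
  seg <- ref$truth$segments
  for (i in seq_len(nrow(seg))) {
    donor <- substring(ref$contigs[[seg$donor_contig[i]]],
                       seg$donor_start[i] + 1L, seg$donor_end[i])
    expect_identical(ref$grc_segments[[seg$segment_id[i]]], donor)
  }
  expect_equal(nrow(ref$truth$diverged_sites), 0L)
})

test_that("diverged-site counts are exact and sites are unique and in-bounds", {
  ref <- tiny_dataset()$reference
  cfg <- ref$config
  seg <- ref$truth$segments
  div <- ref$truth$diverged_sites
  expect_equal(nrow(div), sum(round(cfg$divergence * seg$length)))
  expect_equal(nrow(div), 200L) # 0.01 x 20 kb, sampled without replacement
  expect_false(any(duplicated(div[, .(segment_id, pos)])))
  expect_true(all(div$grc_base != div$ref_base))
  m <- merge(div, seg, by = "segment_id")
  expect_true(all(m$pos >= m$donor_start & m$pos < m$donor_end))
  ## planted base really differs from the written reference
  for (i in sample.int(nrow(div), 20L)) {
    expect_identical(
      substring(ref$contigs[[div$contig[i]]], div$pos[i] + 1L,
                div$pos[i] + 1L), div$ref_base[i])
  }
})

test_that("donor segments are non-overlapping and span >= 2 contigs", {
  seg <- tiny_dataset()$reference$truth$segments
  expect_equal(nrow(seg), 4L)
  expect_gte(length(unique(seg$donor_contig)), 2L)
  setkey(seg, donor_contig, donor_start)
  by_contig <- split(seg, seg$donor_contig)
  for (s in by_contig)
    if (nrow(s) > 1L)
      expect_true(all(head(s$donor_end, -1L) <= tail(s$donor_start, -1L)))
})

test_that("infeasible segment placement fails loudly, not silently", {
  expect_error(
    simulate_reference(tiny_sim_config(grc_total_bp = 99000L,
                                       n_grc_segments = 1L,
                                       multicopy_region = NULL,
                                       segment_align = 100000L)),
    "could not place")
})

test_that("read counts follow the Poisson coverage expectation", {
  d <- tiny_dataset()
  cfg <- d$config
  tr <- d$truth_reads
  lambda_soma <- cfg$n_contigs * cfg$contig_length_bp * cfg$soma_depth /
    cfg$read_length_mean
  n_soma <- nrow(tr[sample == "soma"])
  expect_lt(abs(n_soma - lambda_soma), 3 * sqrt(lambda_soma))
  seg <- d$reference$truth$segments
  lambda_grc <- sum(seg$length * seg$copies) *
    cfg$grc_cell_fraction_depth / cfg$read_length_mean
  n_grc <- nrow(tr[origin == "GRC"])
  expect_lt(abs(n_grc - lambda_grc), 3 * sqrt(lambda_grc))
})

test_that("zero depth for a compartment gives an empty read set", {
  cfg <- tiny_sim_config(seed = 9L, soma_depth = 0,
                         grc_cell_fraction_depth = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  expect_equal(nrow(reads$soma), 0L)
  expect_equal(nrow(reads$truth_reads[origin == "GRC"]), 0L)
  expect_gt(nrow(reads$germline), 0L)
})

test_that("error-free A-chromosome reads are exact haplotype substrings", {
  cfg <- tiny_sim_config(seed = 3L, error_rate = 0)
  ref <- simulate_reference(cfg)
  reads <- simulate_reads(cfg, ref)
  tr <- reads$truth_reads[sample == "soma"][seq_len(50L)]
  sm <- reads$soma[tr$read_id, on = "read_id"]
  for (i in seq_len(nrow(sm))) {
    h1 <- substring(ref$contigs[[sm$contig[i]]], sm$start[i] + 1L,
                    sm$start[i] + sm$length[i])
    h2 <- substring(ref$hap2[[sm$contig[i]]], sm$start[i] + 1L,
                    sm$start[i] + sm$length[i])
    expect_true(sm$seq[i] == h1 || sm$seq[i] == h2)
  }
})

test_that("realized germline GRC:A-chr coverage matches the configured ratio", {
  d <- tiny_dataset()
  cfg <- d$config
  tr <- d$truth_reads[sample == "germline"]
  seg <- d$reference$truth$segments
  grc_cov <- sum(as.numeric(tr[origin == "GRC", length])) /
    sum(seg$length * seg$copies)
  achr_cov <- sum(as.numeric(tr[origin == "A-chr", length])) /
    (cfg$n_contigs * cfg$contig_length_bp)
  target <- cfg$grc_cell_fraction_depth / cfg$germline_achr_depth
  expect_lt(abs(grc_cov / achr_cov - target), 0.15 * target + 0.02)
})

test_that("read ids carry no origin signal and truth covers every read", {
  d <- tiny_dataset()
  tr <- d$truth_reads
  expect_false(any(duplicated(tr$read_id)))
  fa <- Biostrings::readDNAStringSet(d$paths$germline_reads)
  expect_setequal(names(fa), tr[sample == "germline", read_id])
  ## ids are positional; sorting them must not sort by origin
  germ <- tr[sample == "germline"][order(read_id)]
  grc_idx <- which(germ$origin == "GRC")
  expect_gt(var(grc_idx), 0)
  expect_true(min(grc_idx) < nrow(germ) / 4 ||
                max(grc_idx) > 3 * nrow(germ) / 4)
})

test_that("SAM records are coordinate-sorted, in-bounds and mismatch-consistent", {
  d <- tiny_dataset()
  b <- Rsamtools::scanBam(d$paths$germline)[[1L]]
  lens <- nchar(d$reference$contigs)
  expect_true(all(b$flag == 0L))
  expect_true(all(grepl("^[0-9]+M$", b$cigar)))
  expect_true(all(b$pos >= 1L))
  expect_true(all(b$pos + b$qwidth - 1L <= lens[as.character(b$rname)]))
  expect_equal(length(b$qname),
               nrow(d$truth_reads[sample == "germline"]))
  ## NM tag equals the recomputed mismatch count on a sample of reads
  tg <- Rsamtools::scanBam(d$paths$germline, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "seq"), tag = "NM"))[[1L]]
  idx <- sample.int(length(tg$qname), 25L)
  for (i in idx) {
    sq <- as.character(tg$seq[[i]])
    refsub <- substring(d$reference$contigs[[as.character(tg$rname[i])]],
                        tg$pos[i], tg$pos[i] + nchar(sq) - 1L)
    mm <- sum(charToRaw(sq) != charToRaw(refsub))
    expect_equal(tg$tag$NM[i], mm)
  }
})

test_that("GRC reads are placed at donor coordinates with planted alleles", {
  d <- tiny_dataset()
  tr <- d$truth_reads[origin == "GRC"]
  div <- d$reference$truth$diverged_sites
  fa <- Biostrings::readDNAStringSet(d$paths$germline_reads)
  checked <- 0L
  for (i in seq_len(min(10L, nrow(tr)))) {
    r <- tr[i]
    sites <- div[contig == r$contig & pos >= r$start &
                   pos < r$start + r$length]
    if (nrow(sites) == 0L) next
    sq <- as.character(fa[[r$read_id]])
    off <- sites$pos - r$start + 1L
    agree <- substring(sq, off, off) == sites$grc_base
    ## all planted alleles present apart from rare sequencing errors
    expect_gte(mean(agree), 0.95)
    checked <- checked + 1L
  }
  expect_gt(checked, 0L)
})

test_that("regenerating with the same seed is byte-identical", {
  cfg <- tiny_sim_config(seed = 77L)
  d1 <- simulate_dataset(cfg, file.path(tempdir(), "det1"),
                         window_size = tiny_window_size)
  d2 <- simulate_dataset(cfg, file.path(tempdir(), "det2"),
                         window_size = tiny_window_size)
  f1 <- list.files(file.path(tempdir(), "det1"), full.names = TRUE)
  f1 <- f1[grepl("\\.(sam|fa|fasta|tsv|bed)$", f1)]
  f2 <- file.path(file.path(tempdir(), "det2"), basename(f1))
  expect_identical(md5_of(f1), md5_of(f2))
  expect_gte(length(f1), 8L)
})

test_that("annotation truth plants exactly the advertised effects", {
  ann <- simulate_annotation(seed = 11L)
  expect_equal(sum(ann$truth$planted_overexpressed), 1L)
  expect_equal(sum(ann$truth$planted_truncated), 1L)
  ## copy counts in the models match the truth table
  per <- ann$models[, .(copies = uniqueN(gene_id)),
                    by = .(gene_symbol, compartment)]
  m <- merge(per[compartment == "GRC"], ann$truth, by = "gene_symbol")
  expect_equal(m$copies, m$grc_copies)
  ## per-symbol TPM sums equal the planted totals (no double counting)
  sums <- ann$expression[, .(tpm = sum(tpm_male)),
                         by = .(gene_symbol, compartment)]
  chk <- merge(sums[compartment == "GRC"], ann$truth, by = "gene_symbol")
  expect_equal(chk$tpm, chk$base_tpm * chk$grc_expr_mult, tolerance = 1e-12)
  ## block structure is sorted, non-overlapping and in-bounds
  ok <- ann$models[, {
    sz <- as.integer(strsplit(block_sizes, ",")[[1L]])
    st <- as.integer(strsplit(block_starts, ",")[[1L]])
    list(ok = !is.unsorted(st, strictly = TRUE) &&
           all(head(st + sz, -1L) <= tail(st, -1L)) &&
           max(st + sz) == end - start && sum(sz) == spliced_length)
  }, by = isoform_id]
  expect_true(all(ok$ok))
})
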