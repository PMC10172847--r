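## Minimal model-table builder: one row per isoform.
mk_models <- function(df) {
  dt <- as.data.table(df)
  if (!"coding_fraction" %in% names(dt)) dt[, coding_fraction := 90]
  if (!"spliced_length" %in% names(dt)) dt[, spliced_length := 1000L]
  dt[, isoform_id := sprintf("%s_i%d", gene_id, seq_len(.N)), by = gene_id]
  dt[]
}

test_that("paralog pairing partitions symbols by compartment presence", {
  models <- mk_models(data.table(
    gene_symbol = c("S1", "S1", "S1", "S2", "S3", "S3"),
    compartment = c("GRC", "A-chr", "A-chr", "GRC", "A-chr", "A-chr"),
    gene_id = c("g1", "a1", "a2", "g2", "a3", "a3")))
  pp <- pair_paralogs(models)
  expect_equal(pp$pairs$gene_symbol, "S1")
  expect_equal(pp$pairs$grc_copies, 1L)
  expect_equal(pp$pairs$achr_copies, 2L)
  expect_equal(pp$pairs$achr_isoforms, 2L)
  expect_equal(pp$grc_only, "S2")
  expect_equal(pp$achr_only, "S3")
})

test_that("synthetic annotation pairing is recovered exactly", {
  ann <- simulate_annotation(seed = 23L)
  pp <- pair_paralogs(ann$models)
  m <- merge(pp$pairs, ann$truth, by = "gene_symbol")
  expect_equal(nrow(m), nrow(ann$truth))
  expect_equal(m$grc_copies.x, m$grc_copies.y)
  expect_equal(m$achr_copies.x, m$achr_copies.y)
  expect_setequal(pp$grc_only, sprintf("GONLY%02d", 1:5))
})

test_that("architecture deltas and signed-rank test detect planted shortening", {
  set.seed(41L)
  n_sym <- 20L
  achr_len <- round(runif(n_sym, 800, 3000))
  models <- rbind(
    mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n_sym),
                         compartment = "A-chr",
                         gene_id = sprintf("a%02d", 1:n_sym),
                         spliced_length = achr_len)),
    mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n_sym),
                         compartment = "GRC",
                         gene_id = sprintf("g%02d", 1:n_sym),
                         spliced_length = round(achr_len * 0.7))))
  pp <- pair_paralogs(models)
  arch <- suppressWarnings(compare_architecture(pp$pairs, models))
  expect_true(all(arch$per_symbol$delta_length < 0))
  p_len <- arch$tests[metric == "isoform_length", p_value]
  expect_lt(p_len, 0.01)
})

test_that("identical architecture gives null deltas and a null test", {
  set.seed(43L)
  n_sym <- 12L
  len <- round(runif(n_sym, 800, 3000))
  noise <- sample(c(-40L, 40L), n_sym, replace = TRUE) # symmetric
  models <- rbind(
    mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n_sym),
                         compartment = "A-chr",
                         gene_id = sprintf("a%02d", 1:n_sym),
                         spliced_length = len)),
    mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n_sym),
                         compartment = "GRC",
                         gene_id = sprintf("g%02d", 1:n_sym),
                         spliced_length = len + noise)))
  pp <- pair_paralogs(models)
  arch <- suppressWarnings(compare_architecture(pp$pairs, models))
  expect_gt(arch$tests[metric == "isoform_length", p_value], 0.1)
  ## exactly identical values: informative pairs vanish, test is skipped
  models2 <- copy(models)[compartment == "GRC",
                          spliced_length := spliced_length - noise]
  ws <- capture_warnings(arch2 <- compare_architecture(pp$pairs, models2))
  expect_true(any(grepl("skipped", ws)))
  expect_true(all(arch2$per_symbol$delta_length == 0))
})

test_that("single-pair comparison computes deltas but skips the test", {
  models <- mk_models(data.table(
    gene_symbol = c("S1", "S1"), compartment = c("A-chr", "GRC"),
    gene_id = c("a1", "g1"), spliced_length = c(1000L, 700L)))
  pp <- pair_paralogs(models)
  ws <- capture_warnings(arch <- compare_architecture(pp$pairs, models))
  expect_true(any(grepl("skipped", ws)))
  expect_equal(arch$per_symbol$delta_length, -300)
  expect_true(is.na(arch$tests[metric == "isoform_length", p_value]))
})

test_that("signed-rank p agrees with exhaustive enumeration", {
  set.seed(47L)
  for (i in 1:100) {
    n <- sample(4:12, 1L)
    achr <- runif(n, 500, 4000)
    grc <- achr + stats::rcauchy(n, 0, 200) # heavy tails, no ties
    models <- rbind(
      mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n),
                           compartment = "A-chr",
                           gene_id = sprintf("a%02d", 1:n),
                           spliced_length = achr)),
      mk_models(data.table(gene_symbol = sprintf("S%02d", 1:n),
                           compartment = "GRC",
                           gene_id = sprintf("g%02d", 1:n),
                           spliced_length = grc)))
    pp <- pair_paralogs(models)
    arch <- suppressWarnings(compare_architecture(pp$pairs, models))
    expect_equal(arch$tests[metric == "isoform_length", p_value],
                 signed_rank_p_enum(grc, achr), tolerance = 1e-12)
  }
})

test_that("copy-number correlation matches the closed form and finds planted r", {
  set.seed(53L)
  for (i in 1:100) {
    n <- sample(5:30, 1L)
    x <- rpois(n, 3) + 1
    y <- x + rpois(n, 2)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    pairs <- data.table(gene_symbol = sprintf("S%d", 1:n),
                        grc_copies = x, achr_copies = y,
                        grc_isoforms = 1L, achr_isoforms = 1L)
    got <- copy_number_correlation(pairs)
    ora <- pearson_oracle(x, y)
    expect_equal(got$r, ora$r, tolerance = 1e-12)
    expect_equal(got$p_value, ora$p, tolerance = 1e-9)
  }
  ## planted generative correlation 0.5, n = 200
  n <- 200L
  z <- rnorm(n)
  x <- 0.5 * z + sqrt(0.75) * rnorm(n)
  pairs <- data.table(gene_symbol = sprintf("S%d", 1:n), grc_copies = z,
                      achr_copies = x, grc_isoforms = 1L,
                      achr_isoforms = 1L)
  expect_lt(abs(copy_number_correlation(pairs)$r - 0.5), 0.15)
  ## constant copies on one side is undefined
  pairs_const <- copy(pairs)[, grc_copies := 2]
  expect_error(copy_number_correlation(pairs_const),
               class = "grcscan_zero_variance")
})

test_that("expression folds use the TPM floor and flag planted symbols only", {
  models <- mk_models(data.table(
    gene_symbol = rep(c("HI", "NULLX", "LOW"), each = 2L),
    compartment = rep(c("GRC", "A-chr"), 3L),
    gene_id = c("g1", "a1", "g2", "a2", "g3", "a3")))
  expr <- data.table(
    isoform_id = models$isoform_id,
    tpm_female = c(5, 0.4, 0, 0, 1, 2),
    tpm_male = c(0.2, 0.2, 0, 0, 1, 2))
  pp <- pair_paralogs(models)
  es <- expression_summary(pp$pairs, models, expr)
  hi <- es[gene_symbol == "HI"]
  expect_equal(hi$fold_female, 5 / 0.4) # 12.5, above the 10-fold rule
  expect_true(hi$flagged)
  ## both unexpressed: floored to 0.1, fold 1, unflagged
  nl <- es[gene_symbol == "NULLX"]
  expect_equal(nl$fold_female, 1)
  expect_false(nl$flagged)
  expect_false(es[gene_symbol == "LOW", flagged])
  ## TPM totals preserved (no double counting)
  expect_equal(sum(es$grc_tpm_female + es$achr_tpm_female),
               sum(expr$tpm_female))
})

test_that("synthetic annotation flags exactly the planted symbols", {
  ann <- simulate_annotation(seed = 29L)
  pp <- pair_paralogs(ann$models)
  es <- expression_summary(pp$pairs, ann$models, ann$expression)
  expect_setequal(es[flagged == TRUE, gene_symbol],
                  ann$truth[planted_overexpressed == TRUE, gene_symbol])
})

test_that("missing expression rows warn and count as zero TPM", {
  models <- mk_models(data.table(
    gene_symbol = c("S1", "S1"), compartment = c("GRC", "A-chr"),
    gene_id = c("g1", "a1")))
  expr <- data.table(isoform_id = models$isoform_id[2L],
                     tpm_female = 3, tpm_male = 3)
  pp <- pair_paralogs(models)
  expect_warning(es <- expression_summary(pp$pairs, models, expr),
                 "missing")
  expect_equal(es$grc_tpm_female, 0)
  expect_equal(es$fold_female, 0.1 / 3)
})

test_that("comparison outputs are invariant to input row order", {
  ann <- simulate_annotation(seed = 37L)
  perm_m <- ann$models[sample.int(nrow(ann$models))]
  perm_e <- ann$expression[sample.int(nrow(ann$expression))]
  pp1 <- pair_paralogs(ann$models)
  pp2 <- pair_paralogs(perm_m)
  expect_equal(pp1$pairs, pp2$pairs)
  es1 <- expression_summary(pp1$pairs, ann$models, ann$expression)
  es2 <- expression_summary(pp2$pairs, perm_m, perm_e)
  expect_equal(es1, es2)
})
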