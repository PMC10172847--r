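#' Simulate paired GRC/A-chromosome gene models and expression
#'
#' Generates BED12-style isoform models for a set of gene symbols present
#' in both compartments (plus some compartment-exclusive symbols), with
#' per-symbol copy numbers that are positively correlated between
#' compartments (shared latent rate), per-gene isoform counts, lognormal
#' spliced isoform lengths, and per-isoform TPM values for two sexes.
#'
#' Planted effects, recorded in the returned truth table:
#' * a systematic GRC isoform shortening (`grc_length_factor`, default 0.7
#'   = 30 percent shorter), detectable by a paired signed-rank test;
#' * `n_overexpressed` symbols whose GRC expression is `overexpressed_fold`
#'   times the A-chromosome level (default 20-fold, above the 10-fold
#'   flagging rule) — all other symbols have GRC/A-chr expression ratios
#'   bounded inside (0.2, 2.5) x sex jitter, so no unplanted symbol can
#'   cross the 10-fold flag;
#' * `n_truncated` symbols with strongly shortened GRC isoforms and low
#'   GRC coding fraction.
#'
#' @param seed integer seed.
#' @param n_shared_symbols symbols present in both compartments (default 83,
#'   the study scale).
#' @param n_grc_only,n_achr_only compartment-exclusive symbols.
#' @param copy_rate latent rate for extra gene copies (copies = 1 +
#'   Poisson(latent), latent shared between compartments per symbol).
#' @param isoform_lambda mean extra isoforms per gene copy (A-chr).
#' @param grc_isoform_factor multiplier on `isoform_lambda` for GRC genes.
#' @param isoform_length_meanlog,isoform_length_sdlog lognormal spliced
#'   length parameters (bp).
#' @param grc_length_factor multiplier on GRC isoform lengths.
#' @param n_overexpressed,overexpressed_fold planted GRC overexpression.
#' @param n_truncated planted truncated GRC symbols.
#' @param base_tpm_meanlog,base_tpm_sdlog per-symbol total TPM (lognormal,
#'   floored at 2 so unplanted fold-changes stay bounded).
#' @param contig_names A-chromosome contig names used for A-chr models.
#' @return list with data.tables `models`, `expression`, and `truth`
#'   (per-symbol planted values).
#' @export
simulate_annotation <- function(seed = 1L,
                                n_shared_symbols = 83L,
                                n_grc_only = 5L,
                                n_achr_only = 10L,
                                copy_rate = 0.8,
                                isoform_lambda = 3,
                                grc_isoform_factor = 0.8,
                                isoform_length_meanlog = log(1500),
                                isoform_length_sdlog = 0.4,
                                grc_length_factor = 0.7,
                                n_overexpressed = 1L,
                                overexpressed_fold = 20,
                                n_truncated = 1L,
                                base_tpm_meanlog = log(20),
                                base_tpm_sdlog = 0.7,
                                contig_names = sprintf("achr%02d", 1:5)) {
  stopifnot(n_shared_symbols >= n_overexpressed + n_truncated,
            overexpressed_fold > 10)
  set.seed(seed + 2L)

  shared <- sprintf("SYM%03d", seq_len(n_shared_symbols))
  grc_only <- sprintf("GONLY%02d", seq_len(n_grc_only))
  achr_only <- sprintf("AONLY%02d", seq_len(n_achr_only))

  planted_over <- head(shared, n_overexpressed)
  planted_trunc <- shared[seq(n_overexpressed + 1L,
                              n_overexpressed + n_truncated)]

  ## per-symbol copy numbers, correlated via a shared latent rate
  lat <- stats::rexp(n_shared_symbols, rate = 1 / copy_rate)
  truth <- data.table(
    gene_symbol = shared,
    grc_copies = 1L + rpois(n_shared_symbols, lat),
    achr_copies = 1L + rpois(n_shared_symbols, lat),
    grc_expr_mult = runif(n_shared_symbols, 0.2, 2.5),
    planted_overexpressed = shared %in% planted_over,
    planted_truncated = shared %in% planted_trunc)
  truth[planted_overexpressed == TRUE, grc_expr_mult := overexpressed_fold]
  truth[, base_tpm := pmax(2, rlnorm(.N, base_tpm_meanlog, base_tpm_sdlog))]
  ## same-symbol sex jitter per compartment, bounded so only planted
  ## symbols can exceed the 10-fold rule in either sex
  truth[, `:=`(sexratio_grc = runif(.N, 0.85, 1.2),
               sexratio_achr = runif(.N, 0.85, 1.2))]

  model_rows <- list()
  expr_rows <- list()
  cursor <- stats::setNames(rep(10000L, length(contig_names) + 1L),
                            c(contig_names, "grc_ctg01"))

  emit_gene <- function(symbol, compartment, copy_idx, n_iso, len_factor,
                        coding_lo, coding_hi) {
    ctg <- if (compartment == "GRC") "grc_ctg01" else
      contig_names[1L + (sum(utf8ToInt(symbol)) + copy_idx) %%
                     length(contig_names)]
    gene_id <- sprintf("%s_%s_g%d", compartment, symbol, copy_idx)
    lens <- pmax(150L, as.integer(round(
      rlnorm(n_iso, isoform_length_meanlog, isoform_length_sdlog) *
        len_factor)))
    intron_mean <- if (compartment == "GRC") 250 else 500
    rows <- vector("list", n_iso)
    gstart <- cursor[[ctg]]
    for (j in seq_len(n_iso)) {
      n_ex <- 1L + rpois(1L, 3L)
      ex <- split_into_parts(lens[j], n_ex, min_part = 30L)
      introns <- if (n_ex > 1L) 50L + rpois(n_ex - 1L, intron_mean) else
        integer(0)
      block_starts <- cumsum(c(0L, head(ex, -1L) + introns))
      span <- block_starts[n_ex] + ex[n_ex]
      rows[[j]] <- data.table(
        gene_id = gene_id,
        isoform_id = sprintf("%s_i%d", gene_id, j),
        gene_symbol = symbol, compartment = compartment,
        contig = ctg, start = gstart, end = gstart + span, strand = "+",
        n_blocks = n_ex,
        block_sizes = paste(ex, collapse = ","),
        block_starts = paste(block_starts, collapse = ","),
        coding_fraction = round(runif(1L, coding_lo, coding_hi), 1),
        spliced_length = sum(ex))
    }
    cursor[[ctg]] <<- gstart + max(vapply(rows, function(r) r$end - gstart,
                                          numeric(1L))) + 5000L
    rbindlist(rows)
  }

  for (i in seq_len(nrow(truth))) {
    sym <- truth$gene_symbol[i]
    trunc <- truth$planted_truncated[i]
    for (k in seq_len(truth$achr_copies[i])) {
      n_iso <- 1L + rpois(1L, isoform_lambda)
      model_rows[[length(model_rows) + 1L]] <-
        emit_gene(sym, "A-chr", k, n_iso, 1, 85, 100)
    }
    for (k in seq_len(truth$grc_copies[i])) {
      n_iso <- 1L + rpois(1L, isoform_lambda * grc_isoform_factor)
      model_rows[[length(model_rows) + 1L]] <-
        emit_gene(sym, "GRC", k, n_iso,
                  if (trunc) 0.4 else grc_length_factor,
                  if (trunc) 15 else 55, if (trunc) 35 else 95)
    }
  }
  for (sym in grc_only)
    model_rows[[length(model_rows) + 1L]] <-
      emit_gene(sym, "GRC", 1L, 1L + rpois(1L, isoform_lambda), 1, 55, 95)
  for (sym in achr_only)
    model_rows[[length(model_rows) + 1L]] <-
      emit_gene(sym, "A-chr", 1L, 1L + rpois(1L, isoform_lambda), 1, 85, 100)

  models <- rbindlist(model_rows)

  ## expression: symbol-level totals distributed over isoforms so that
  ## per-symbol sums are exactly the planted values
  for (i in seq_len(nrow(truth))) {
    sym <- truth$gene_symbol[i]
    for (cp in c("A-chr", "GRC")) {
      iso <- models[gene_symbol == sym & compartment == cp, isoform_id]
      tot <- truth$base_tpm[i] *
        (if (cp == "GRC") truth$grc_expr_mult[i] else 1)
      sexr <- if (cp == "GRC") truth$sexratio_grc[i] else
        truth$sexratio_achr[i]
      w <- runif(length(iso), 0.2, 1)
      w <- w / sum(w)
      expr_rows[[length(expr_rows) + 1L]] <- data.table(
        isoform_id = iso, gene_symbol = sym, compartment = cp,
        tpm_female = tot * sexr * w, tpm_male = tot * w)
    }
  }
  for (sym in c(grc_only, achr_only)) {
    cp <- if (sym %in% grc_only) "GRC" else "A-chr"
    iso <- models[gene_symbol == sym, isoform_id]
    tot <- pmax(2, rlnorm(1L, base_tpm_meanlog, base_tpm_sdlog))
    w <- runif(length(iso), 0.2, 1)
    w <- w / sum(w)
    expr_rows[[length(expr_rows) + 1L]] <- data.table(
      isoform_id = iso, gene_symbol = sym, compartment = cp,
      tpm_female = tot * w, tpm_male = tot * w)
  }
  expression <- rbindlist(expr_rows)

  list(models = models, expression = expression, truth = truth)
}

## Split `total` into `k` integer parts of at least `min_part`, summing
## exactly to `total` (random proportions).
#' @keywords internal
split_into_parts <- function(total, k, min_part = 1L) {
  if (total < k * min_part) {
    k <- max(1L, total %/% min_part)
  }
  if (k == 1L) return(as.integer(total))
  w <- runif(k)
  extra <- total - k * min_part
  parts <- min_part + floor(w / sum(w) * extra)
  parts[k] <- total - sum(parts[-k])
  as.integer(parts)
}
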