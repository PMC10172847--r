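#' Pipeline configuration
#'
#' Collects input paths and all stage parameters. Defaults are the study
#' constants: 25-kb windows with at least 20 SNVs, soma/germline depth
#' thresholds 15/45 (half the respective median depths of the study
#' samples; `"auto"` recomputes half-median from the data), top 1 percent
#' of eligible windows, at least one germline-specific allele per
#' extracted read, TPM floor 0.1.
#'
#' @param reference somatic reference FASTA.
#' @param soma,germline coordinate-sorted alignments (BAM, or SAM to be
#'   converted) of the soma and germline read sets on `reference`.
#' @param germline_reads optional FASTA of germline read sequences (needed
#'   to emit the extracted-read FASTA).
#' @param models,expression optional gene-model BED12(+4) and expression
#'   TSV enabling the paralog comparison stage.
#' @param outdir output directory.
#' @param window_size,min_snvs,soma_min_depth,germline_min_depth,top_fraction,min_specific,tpm_floor,fold_threshold,min_mapq
#'   stage parameters (see the stage functions).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed matters when the config is used to
#'   generate data).
#' @return a `grcscan_pipeline_config` list.
#' @export
pipeline_config <- function(reference, soma, germline,
                            germline_reads = NULL, models = NULL,
                            expression = NULL, outdir = "grcscan_out",
                            window_size = 25000L, min_snvs = 20L,
                            soma_min_depth = 15L, germline_min_depth = 45L,
                            top_fraction = 0.01, min_specific = 1L,
                            tpm_floor = 0.1, fold_threshold = 10,
                            min_mapq = 0L, seed = 1L) {
  cfg <- structure(list(
    reference = reference, soma = soma, germline = germline,
    germline_reads = germline_reads, models = models,
    expression = expression, outdir = outdir,
    window_size = as.integer(window_size), min_snvs = as.integer(min_snvs),
    soma_min_depth = soma_min_depth,
    germline_min_depth = germline_min_depth,
    top_fraction = top_fraction, min_specific = as.integer(min_specific),
    tpm_floor = tpm_floor, fold_threshold = fold_threshold,
    min_mapq = as.integer(min_mapq), seed = as.integer(seed)
  ), class = "grcscan_pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

#' @keywords internal
validate_pipeline_config <- function(cfg) {
  with(cfg, {
    stopifnot(window_size > 0L, min_snvs >= 1L,
              top_fraction > 0, top_fraction <= 1,
              min_specific >= 1L, tpm_floor > 0, fold_threshold > 1,
              min_mapq >= 0L)
    for (th in list(soma_min_depth, germline_min_depth))
      if (!identical(th, "auto") && (!is.numeric(th) || th < 1))
        stop("pipeline_config: depth thresholds must be >= 1 or \"auto\"")
  })
  invisible(cfg)
}

#' Read / write a pipeline configuration as YAML
#'
#' The YAML round-trips losslessly through [pipeline_config()].
#'
#' @param path YAML file path.
#' @param cfg a [pipeline_config()] object.
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1L))])
}

#' Validate pipeline inputs
#'
#' Checks that files exist and conform: the reference is indexable FASTA,
#' alignments parse and their header contigs agree with the reference,
#' gene models have the BED12+4 layout with sorted, in-bounds blocks, and
#' the expression table covers the model isoforms. Every problem found is
#' listed, not just the first.
#'
#' @param config a [pipeline_config()] object.
#' @return character vector of problems (length 0 when clean).
#' @export
validate_inputs <- function(config) {
  problems <- character(0)
  add <- function(msg) problems <<- c(problems, msg)

  for (f in c("reference", "soma", "germline")) {
    if (!file.exists(config[[f]])) add(sprintf("%s: file not found (%s)",
                                               f, config[[f]]))
  }
  for (f in c("germline_reads", "models", "expression")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      add(sprintf("%s: file not found (%s)", f, config[[f]]))
  }
  if (length(problems)) return(problems)

  ref_len <- tryCatch(reference_lengths(config$reference), error = function(e) {
    add(paste0("reference: not indexable FASTA: ", conditionMessage(e)))
    NULL
  })
  for (f in c("soma", "germline")) {
    hdr <- tryCatch({
      path <- config[[f]]
      if (grepl("\\.sam$", path)) path <- sam_to_bam(path)
      Rsamtools::scanBamHeader(path)[[1L]]$targets
    }, error = function(e) {
      add(sprintf("%s: unreadable alignments: %s", f, conditionMessage(e)))
      NULL
    })
    if (!is.null(hdr) && !is.null(ref_len)) {
      extra <- setdiff(names(hdr), names(ref_len))
      if (length(extra))
        add(sprintf("%s: contig(s) absent from reference: %s", f,
                    paste(extra, collapse = ", ")))
      shared <- intersect(names(hdr), names(ref_len))
      bad <- shared[hdr[shared] != ref_len[shared]]
      if (length(bad))
        add(sprintf("%s: contig length mismatch vs reference: %s", f,
                    paste(bad, collapse = ", ")))
    }
  }
  if (!is.null(config$models)) {
    mod <- tryCatch(read_models_bed12(config$models), error = function(e) {
      add(paste0("models: ", conditionMessage(e)))
      NULL
    })
    if (!is.null(mod)) {
      bad <- mod[mapply(function(bs, bst, s, e) {
        sz <- as.integer(strsplit(bs, ",")[[1L]])
        st <- as.integer(strsplit(bst, ",")[[1L]])
        is.unsorted(st) || any(st + sz > e - s) ||
          any(head(st + sz, -1L) > tail(st, -1L))
      }, block_sizes, block_starts, start, end), isoform_id]
      if (length(bad))
        add(sprintf("models: unsorted/overlapping/out-of-bounds blocks: %s",
                    paste(head(bad, 5L), collapse = ", ")))
      if (!all(mod$compartment %in% c("GRC", "A-chr")))
        add("models: compartment column must be GRC or A-chr")
      if (!is.null(config$expression)) {
        ex <- tryCatch(read_expression_tsv(config$expression),
                       error = function(e) {
                         add(paste0("expression: ", conditionMessage(e)))
                         NULL
                       })
        if (!is.null(ex)) {
          if (any(ex$tpm_female < 0, na.rm = TRUE) ||
              any(ex$tpm_male < 0, na.rm = TRUE))
            add("expression: negative TPM values")
          miss <- setdiff(mod$isoform_id, ex$isoform_id)
          if (length(miss))
            add(sprintf("expression: %d model isoform(s) missing",
                        length(miss)))
        }
      }
    }
  }
  problems
}

#' Run the full detection pipeline
#'
#' Stages: allele pileup, SNV site calling, window relspec, top-window
#' selection, germline-read extraction, coverage/copy-number estimation,
#' and (when gene models and expression are provided) the paralog
#' comparison. All outputs are written under `config$outdir`; a manifest
#' JSON records the package version, every parameter actually used
#' (including auto-derived thresholds), input checksums and stage counts.
#' Rerunning with an identical configuration reproduces byte-identical
#' outputs.
#'
#' Candidate-window coverage labels: selected windows are labelled GRC,
#' all other windows A-chr, for the coverage summary and the
#' corrected-coverage copy-number table.
#'
#' @param config a [pipeline_config()] object.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  problems <- validate_inputs(config)
  if (length(problems))
    grcscan_error("grcscan_invalid_inputs",
                  paste0("run_pipeline: invalid inputs:\n  - ",
                         paste(problems, collapse = "\n  - ")))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)
  stage <- function(name, expr) {
    message("grcscan [", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("grcscan stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  counts <- stage("pileup", count_alleles(config$soma, config$germline,
                                          min_mapq = config$min_mapq))
  sites <- stage("snv_sites",
                 call_snv_sites(counts, config$soma_min_depth,
                                config$germline_min_depth))
  write_sites(sites, p("sites.tsv"))

  ref_len <- reference_lengths(config$reference)
  win <- make_windows(ref_len, config$window_size)
  stats <- stage("windows", window_relspec(sites, win, config$min_snvs))
  write_windows_bed(stats, p("windows.bed"))
  selected <- stage("select",
                    select_top_windows(stats, config$top_fraction))
  write_windows_bed(selected, p("selected.bed"))

  ext <- stage("extract", extract_reads(
    config$germline, selected, sites, min_specific = config$min_specific,
    reads_fasta = config$germline_reads,
    out_fasta = if (!is.null(config$germline_reads)) p("grc_reads.fasta")))
  fwrite(ext$manifest, p("read_manifest.tsv"), sep = "\t")

  cn_summary <- stage("copynumber", {
    lab <- copy(stats[, .(contig, start, end)])
    lab[, label := "A-chr"]
    lab[selected, on = c("contig", "start", "end"), label := "GRC"]
    soma_cov <- window_coverage(config$soma, lab[, .(contig, start, end)],
                                config$min_mapq)
    germ_cov <- window_coverage(config$germline,
                                lab[, .(contig, start, end)],
                                config$min_mapq)
    lab[, `:=`(soma_cov = soma_cov$mean_depth,
               germline_cov = germ_cov$mean_depth)]
    cs <- coverage_summary(lab)
    cn <- estimate_copy_number(
      lab[label == "GRC", .(contig, start, end, soma_cov,
                            germline_cov_raw = germline_cov)],
      cs$ratio_factor)
    fwrite(cn, p("copy_number.tsv"), sep = "\t")
    sz <- size_estimates(selected$end - selected$start, cn_table = cn,
                         min_length = 0)
    list(coverage = unclass(cs), copy_number = cn,
         median_corrected = attr(cn, "median_corrected"),
         candidate_span = sz$raw_length,
         copy_aware_length = sz$copy_aware_length)
  })

  paralogs <- NULL
  if (!is.null(config$models) && !is.null(config$expression)) {
    paralogs <- stage("paralogs", {
      mod <- read_models_bed12(config$models)
      ex <- read_expression_tsv(config$expression)
      pp <- pair_paralogs(mod)
      arch <- compare_architecture(pp$pairs, mod)
      corr <- if (nrow(pp$pairs) >= 3L)
        tryCatch(copy_number_correlation(pp$pairs),
                 grcscan_zero_variance = function(e) NULL) else NULL
      es <- expression_summary(pp$pairs, mod, ex,
                               tpm_floor = config$tpm_floor,
                               fold_threshold = config$fold_threshold)
      fwrite(pp$pairs, p("paralog_pairs.tsv"), sep = "\t")
      fwrite(arch$per_symbol, p("paralog_architecture.tsv"), sep = "\t")
      fwrite(arch$tests, p("paralog_tests.tsv"), sep = "\t")
      fwrite(es, p("paralog_expression.tsv"), sep = "\t")
      list(n_shared_symbols = nrow(pp$pairs),
           n_grc_only = length(pp$grc_only),
           n_achr_only = length(pp$achr_only),
           tests = arch$tests, copy_correlation = corr,
           n_flagged = sum(es$flagged))
    })
  }

  manifest <- list(
    package = "grcscan",
    version = as.character(packageVersion("grcscan")),
    parameters = within(unclass(config), {
      soma_min_depth <- attr(sites, "soma_min_depth")
      germline_min_depth <- attr(sites, "germline_min_depth")
    }),
    inputs_md5 = as.list(tools::md5sum(unlist(config[c(
      "reference", "soma", "germline")]))),
    counts = list(
      n_positions = nrow(counts),
      n_snvs = nrow(sites),
      n_windows = nrow(stats),
      n_windows_eligible = sum(stats$eligible),
      n_selected = nrow(selected),
      n_reads_extracted = ext$summary$n_reads),
    coverage = cn_summary$coverage,
    median_corrected_coverage = cn_summary$median_corrected,
    candidate_span = cn_summary$candidate_span,
    copy_aware_length = cn_summary$copy_aware_length,
    paralogs = if (!is.null(paralogs))
      paralogs[c("n_shared_symbols", "n_grc_only", "n_achr_only",
                 "n_flagged")])
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message("grcscan: done; outputs in ", config$outdir)
  invisible(manifest)
}
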