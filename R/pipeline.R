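# Orchestration: demultiplex -> trim -> merge -> collapse -> assign ->
# annotate -> clonotype -> SHM -> diversity -> tree-map, with a per-stage
# count ledger and standard-format outputs per sample.

pipeline_defaults <- function() {
  list(r1 = NULL, r2 = NULL,
       germline = "builtin",          # "builtin" or list(fasta=, anchors=)
       locus = "IGH",
       barcode_table = NULL,          # data.frame(barcode, sample) or TSV path
       outdir = NULL,                 # NULL = no files written
       window = 2L, qmin = 20L, min_length = 50L,
       min_overlap = 10L, barcode_mate = "R2", max_mismatch = 0L,
       scoring = list(match = 2L, mismatch = -2L, gap_open = -3L,
                      gap_extend = -1L),
       thresholds = list(V = 40L, D = 10L, J = 16L, C = 16L),
       min_copies = 5L, gt_threshold = 5L, weighting = "copy",
       clonotype_key = "vj_cdr3",
       treemap = list(width = 600, height = 400, seed = 1L,
                      corner_radius = 3))
}

#' Validate and resolve a pipeline configuration
#'
#' Accepts a named list or a YAML/JSON file path. Unknown keys are
#' rejected and all validation errors are reported at once.
#'
#' @param cfg named list, or path to a YAML/JSON config file.
#' @return the fully defaulted `run_config` list.
#' @export
validate_config <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) {
    if (!file.exists(cfg)) stopf("config file not found: %s", cfg)
    cfg <- if (grepl("\\.json$", cfg)) jsonlite::read_json(cfg, simplifyVector = TRUE)
    else yaml::read_yaml(cfg)
  }
  stopifnot(is.list(cfg))
  defaults <- pipeline_defaults()
  errs <- character()
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    errs <- c(errs, sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  full <- utils::modifyList(defaults, cfg[setdiff(names(cfg), unknown)])

  need_pos <- c("window", "min_overlap", "min_length")
  for (k in need_pos)
    if (!is.numeric(full[[k]]) || full[[k]] < 1)
      errs <- c(errs, sprintf("%s must be a positive integer", k))
  if (!is.numeric(full$qmin) || full$qmin < 0)
    errs <- c(errs, "qmin must be >= 0")
  if (!is.numeric(full$max_mismatch) || full$max_mismatch < 0)
    errs <- c(errs, "max_mismatch must be >= 0")
  if (!full$locus %in% c("IGH", "TRB"))
    errs <- c(errs, "locus must be IGH or TRB")
  if (!full$barcode_mate %in% c("R1", "R2"))
    errs <- c(errs, "barcode_mate must be R1 or R2")
  if (!full$weighting %in% c("copy", "unique"))
    errs <- c(errs, "weighting must be copy or unique")
  if (!full$clonotype_key %in% c("vj_cdr3", "cdr3"))
    errs <- c(errs, "clonotype_key must be vj_cdr3 or cdr3")
  if (!is.numeric(full$min_copies) || full$min_copies < 1)
    errs <- c(errs, "min_copies must be >= 1")
  for (p in c("r1", "r2")) {
    if (is.null(full[[p]])) errs <- c(errs, sprintf("%s path is required", p))
    else if (!file.exists(full[[p]]))
      errs <- c(errs, sprintf("%s file not found: %s", p, full[[p]]))
  }
  if (is.list(full$germline) && !is.data.frame(full$germline)) {
    for (p in c("fasta", "anchors"))
      if (is.null(full$germline[[p]]) || !file.exists(full$germline[[p]]))
        errs <- c(errs, sprintf("germline %s path missing or not found", p))
  } else if (!identical(full$germline, "builtin") &&
             !inherits(full$germline, "germline_db")) {
    errs <- c(errs, "germline must be \"builtin\", a germline_db, or list(fasta=, anchors=)")
  }
  if (is.character(full$barcode_table)) {
    if (!file.exists(full$barcode_table))
      errs <- c(errs, sprintf("barcode table not found: %s", full$barcode_table))
    else full$barcode_table <- read.delim(full$barcode_table,
                                          stringsAsFactors = FALSE)
  }
  if (!is.data.frame(full$barcode_table) ||
      !all(c("barcode", "sample") %in% names(full$barcode_table %||% list())))
    errs <- c(errs, "barcode_table must have columns barcode, sample")
  if (length(errs))
    stopf("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  class(full) <- "run_config"
  full
}

resolve_germline <- function(cfg) {
  if (inherits(cfg$germline, "germline_db")) cfg$germline
  else if (identical(cfg$germline, "builtin")) builtin_toy_reference(cfg$locus)
  else load_germline(cfg$germline$fasta, cfg$germline$anchors)
}

#' Run the full repertoire pipeline
#'
#' Executes demultiplex -> trim -> merge -> collapse -> assign -> annotate
#' -> clonotype -> SHM -> diversity -> tree-map for every sample in the
#' barcode table. When `outdir` is set, writes per sample an AIRR
#' Rearrangement TSV, a summary JSON, a diversity TSV and a tree-map SVG,
#' plus a run-level demultiplex report. A failing sample is reported and
#' skipped; other samples continue.
#'
#' @param cfg a config list or file accepted by [validate_config()].
#' @return named list of per-sample reports (`sample_report` lists with a
#'   stage-count `ledger`, `isotype`, `shm`, `diversity`, `clonotypes`,
#'   `annotated`, `error` and output `paths`), plus attribute
#'   `"demux_report"`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  db <- resolve_germline(cfg)
  scoring <- do.call(scoring_scheme, cfg$scoring)
  thresholds <- unlist(cfg$thresholds)

  r1 <- read_fastq(cfg$r1)
  r2 <- read_fastq(cfg$r2)
  if (nrow(r1) != nrow(r2)) stopf("R1/R2 read counts differ")
  dmx <- demultiplex(r1, r2, cfg$barcode_table,
                     max_mismatch = cfg$max_mismatch,
                     barcode_mate = cfg$barcode_mate)
  if (!is.null(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
    write.table(dmx$report, file.path(cfg$outdir, "demux_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  reports <- list()
  for (sample in names(dmx$samples)) {
    reports[[sample]] <- tryCatch(
      run_sample(sample, dmx$samples[[sample]], cfg, db, scoring, thresholds),
      error = function(e) {
        message(sprintf("[%s] sample failed: %s", sample, conditionMessage(e)))
        structure(list(sample = sample, error = conditionMessage(e)),
                  class = "sample_report")
      })
  }
  attr(reports, "demux_report") <- dmx$report
  reports
}

run_sample <- function(sample, pair, cfg, db, scoring, thresholds) {
  ledger <- list(input_pairs = nrow(pair$r1))
  t1 <- quality_trim(pair$r1, cfg$window, cfg$qmin)
  t2 <- quality_trim(pair$r2, cfg$window, cfg$qmin)
  mg <- merge_pairs(t1, t2, cfg$min_overlap, cfg$min_length)
  ledger$merged <- nrow(mg$merged)
  ledger$discarded <- as.list(mg$discarded)
  message(sprintf("[%s] %d pairs, %d merged (%s discarded)", sample,
                  ledger$input_pairs, ledger$merged,
                  paste(sprintf("%s=%d", names(mg$discarded), mg$discarded),
                        collapse = ", ")))

  uniq <- collapse_duplicates(mg$merged)
  ledger$unique <- nrow(uniq)

  ann <- annotate_repertoire(uniq, db, cfg$locus, scoring, thresholds)
  annotated <- ann$annotated
  ledger$unassignable <- ann$n_unassignable
  ledger$annotated <- nrow(annotated)
  ledger$with_cdr3 <- sum(!is.na(annotated$cdr3_nt))
  message(sprintf("[%s] %d unique, %d annotated, %d with CDR3", sample,
                  ledger$unique, ledger$annotated, ledger$with_cdr3))

  iso <- isotype_composition(annotated)
  shm <- shm_summary(mutation_records(annotated),
                     min_copies = cfg$min_copies,
                     gt_threshold = cfg$gt_threshold,
                     weighting = cfg$weighting)
  clon <- build_clonotypes(annotated, key = cfg$clonotype_key)
  div <- if (nrow(clon) > 0) d50(rank_abundance(clon, key = cfg$clonotype_key))
  else NULL
  usage <- v_usage(clon)

  paths <- list()
  if (!is.null(cfg$outdir)) {
    base <- file.path(cfg$outdir, sample)
    paths$airr <- paste0(base, "_airr.tsv")
    write_airr(annotated, paths$airr)
    paths$diversity <- paste0(base, "_diversity.tsv")
    topn <- head(clon, 25)
    write.table(topn, paths$diversity, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    if (nrow(clon) > 0 && cfg$clonotype_key == "vj_cdr3") {
      paths$treemap <- paste0(base, "_treemap.svg")
      tm <- layout_treemap(build_hierarchy(clon),
                           width = cfg$treemap$width,
                           height = cfg$treemap$height,
                           seed = cfg$treemap$seed)
      render_svg(tm, paths$treemap, cfg$treemap$corner_radius)
    }
    paths$summary <- paste0(base, "_summary.json")
    jsonlite::write_json(
      list(sample = sample, ledger = ledger,
           isotype_percent = as.list(iso$percent),
           isotype_unknown_copies = iso$unknown_copies,
           shm = shm,
           diversity = div %||% list(),
           v_usage = usage),
      paths$summary, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  structure(list(sample = sample, ledger = ledger, isotype = iso, shm = shm,
                 diversity = div, v_usage = usage, clonotypes = clon,
                 annotated = annotated, error = NULL, paths = paths),
            class = "sample_report")
}

#' @export
print.sample_report <- function(x, ...) {
  cat("sample:", x$sample, "\n")
  if (!is.null(x$error)) { cat("  FAILED:", x$error, "\n"); return(invisible(x)) }
  cat(sprintf("  pairs %d -> merged %d -> unique %d -> annotated %d\n",
              x$ledger$input_pairs, x$ledger$merged, x$ledger$unique,
              x$ledger$annotated))
  if (!is.null(x$diversity))
    cat(sprintf("  S=%d J=%d C=%d D50=%.2f\n", x$diversity$S, x$diversity$J,
                x$diversity$C, x$diversity$D50))
  if (x$shm$defined)
    cat(sprintf("  SHM: %.1f per kb, %.1f%% with >%d changes (n=%d)\n",
                x$shm$rate_per_kb, 100 * x$shm$frac_gt, 5,
                x$shm$n_sequences_used))
  invisible(x)
}
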