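# Germline segment references with CDR anchor annotations.
#
# A germline database is a data.frame of segments (one row per V/D/J/C
# segment) wrapped in class "germline_db". Anchor coordinates are 0-based
# positions into the ungapped segment sequence:
#   cdr2_start  (V only)  first nucleotide of CDR2
#   cdr3_anchor (V)       first nucleotide of the conserved-Cys codon
#   cdr3_anchor (J)       first nucleotide AFTER the conserved Phe/Trp codon
# C segments carry an isotype label (IgH loci only).

IGH_ISOTYPES <- c("IgM", "IgD", "IgG3", "IgG1", "IgG2b", "IgG2c", "IgE", "IgA")

new_germline_db <- function(segments) {
  rownames(segments) <- NULL
  structure(list(segments = segments), class = "germline_db")
}

#' @export
print.germline_db <- function(x, ...) {
  tab <- table(x$segments$locus, x$segments$gene_type)
  cat("germline_db with", nrow(x$segments), "segments\n")
  print(tab)
  invisible(x)
}

#' Look up germline segments by locus and gene type
#'
#' @param db a `germline_db`.
#' @param locus `"IGH"` or `"TRB"`.
#' @param gene_type one of `"V"`, `"D"`, `"J"`, `"C"`, or `NULL` for all.
#' @return data.frame of matching segment rows.
#' @export
db_segments <- function(db, locus, gene_type = NULL) {
  s <- db$segments
  s <- s[s$locus == locus, , drop = FALSE]
  if (!is.null(gene_type)) s <- s[s$gene_type %in% gene_type, , drop = FALSE]
  rownames(s) <- NULL
  s
}

validate_germline <- function(segments) {
  errs <- character()
  req <- c("segment_id", "locus", "gene_type", "sequence",
           "cdr2_start", "cdr3_anchor", "isotype_label")
  miss <- setdiff(req, names(segments))
  if (length(miss))
    stopf("germline table is missing columns: %s", paste(miss, collapse = ", "))

  dup <- segments$segment_id[duplicated(segments$segment_id)]
  if (length(dup))
    errs <- c(errs, sprintf("duplicate segment_id: %s",
                            paste(unique(dup), collapse = ", ")))
  bad_loc <- !segments$locus %in% c("IGH", "TRB")
  if (any(bad_loc))
    errs <- c(errs, sprintf("unknown locus for %s",
                            paste(segments$segment_id[bad_loc], collapse = ", ")))
  bad_gt <- !segments$gene_type %in% c("V", "D", "J", "C")
  if (any(bad_gt))
    errs <- c(errs, sprintf("unknown gene_type for %s",
                            paste(segments$segment_id[bad_gt], collapse = ", ")))
  bad_seq <- !grepl("^[ACGT]+$", segments$sequence)
  if (any(bad_seq))
    errs <- c(errs, sprintf(
      "sequence empty or outside A/C/G/T for %s",
      paste(segments$segment_id[bad_seq], collapse = ", ")))

  len <- nchar(segments$sequence)
  for (i in seq_len(nrow(segments))) {
    gt <- segments$gene_type[i]; id <- segments$segment_id[i]
    c2 <- segments$cdr2_start[i]; c3 <- segments$cdr3_anchor[i]
    if (gt == "V") {
      if (is.na(c2) || is.na(c3))
        errs <- c(errs, sprintf("V segment %s lacks cdr2_start/cdr3_anchor", id))
      else if (!(c2 >= 0 && c2 < c3 && c3 < len[i]))
        errs <- c(errs, sprintf(
          "V segment %s: need 0 <= cdr2_start < cdr3_anchor < length (%d)", id, len[i]))
    } else if (gt == "J") {
      if (is.na(c3))
        errs <- c(errs, sprintf("J segment %s lacks cdr3_anchor", id))
      else if (!(c3 > 0 && c3 < len[i]))
        errs <- c(errs, sprintf(
          "J segment %s: cdr3_anchor must lie strictly inside the sequence", id))
    }
    if (gt == "C") {
      iso <- segments$isotype_label[i]
      if (segments$locus[i] == "IGH") {
        if (is.na(iso) || !iso %in% IGH_ISOTYPES)
          errs <- c(errs, sprintf(
            "C segment %s: IGH constant segments need an isotype label in {%s}",
            id, paste(IGH_ISOTYPES, collapse = ", ")))
      }
    } else if (!is.na(segments$isotype_label[i])) {
      errs <- c(errs, sprintf("segment %s: isotype label only allowed on C", id))
    }
  }
  for (loc in unique(segments$locus)) {
    gt <- segments$gene_type[segments$locus == loc]
    for (need in c("V", "J", "C"))
      if (!need %in% gt)
        errs <- c(errs, sprintf("locus %s has no %s segment", loc, need))
  }
  if (length(errs)) stopf("invalid germline reference:\n  - %s",
                          paste(errs, collapse = "\n  - "))
  invisible(TRUE)
}

#' Load a germline reference from FASTA plus an anchor table
#'
#' The anchor table is tab-separated with columns `segment_id`, `locus`,
#' `gene_type`, `cdr2_start`, `cdr3_anchor`, `isotype_label`; empty fields
#' mean "absent". Every FASTA record must have an anchor row and vice versa.
#'
#' @param fasta_path path to the segment FASTA.
#' @param anchors_path path to the anchor TSV.
#' @return a validated `germline_db`.
#' @export
load_germline <- function(fasta_path, anchors_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  anch <- read.delim(anchors_path, stringsAsFactors = FALSE,
                     colClasses = c(segment_id = "character",
                                    locus = "character",
                                    gene_type = "character",
                                    isotype_label = "character"))
  for (col in c("cdr2_start", "cdr3_anchor"))
    anch[[col]] <- suppressWarnings(as.integer(anch[[col]]))
  anch$isotype_label[is.na(anch$isotype_label) | anch$isotype_label == ""] <-
    NA_character_

  missing_anchor <- setdiff(ids, anch$segment_id)
  if (length(missing_anchor))
    stopf("no anchor row for segment(s): %s", paste(missing_anchor, collapse = ", "))
  missing_fasta <- setdiff(anch$segment_id, ids)
  if (length(missing_fasta))
    stopf("anchor table references segment(s) absent from FASTA: %s",
          paste(missing_fasta, collapse = ", "))
  if (anyDuplicated(ids))
    stopf("duplicate segment_id in FASTA: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))

  segments <- anch[match(ids, anch$segment_id), , drop = FALSE]
  segments$sequence <- toupper(as.character(seqs))
  segments <- segments[, c("segment_id", "locus", "gene_type", "sequence",
                           "cdr2_start", "cdr3_anchor", "isotype_label")]
  validate_germline(segments)
  new_germline_db(segments)
}

#' Write a germline database to FASTA + anchor TSV
#'
#' Inverse of [load_germline()].
#'
#' @param db a `germline_db`.
#' @param fasta_path,anchors_path output paths.
#' @return invisibly, the two paths.
#' @export
write_germline <- function(db, fasta_path, anchors_path) {
  s <- db$segments
  dna <- Biostrings::DNAStringSet(s$sequence)
  names(dna) <- s$segment_id
  Biostrings::writeXStringSet(dna, fasta_path)
  out <- s[, c("segment_id", "locus", "gene_type", "cdr2_start",
               "cdr3_anchor", "isotype_label")]
  write.table(out, anchors_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(c(fasta_path, anchors_path))
}

#' Bundled deterministic toy germline reference
#'
#' A small hand-specified reference used by the simulator and the test
#' suite: for IGH, 3 V, 2 D, 2 J and one C segment per IgH isotype
#' (IgM, IgD, IgG3, IgG1, IgG2b, IgG2c, IgE, IgA); for TRB, 4 V, 2 J and a
#' single unlabeled C. IgG2b/IgG2c constants deliberately share their first
#' 20 nucleotides, mimicking the near-identical 5' ends of real subclass
#' constants. Identical across calls.
#'
#' @param locus `"IGH"` or `"TRB"`.
#' @return a validated `germline_db`.
#' @export
builtin_toy_reference <- function(locus = c("IGH", "TRB")) {
  locus <- match.arg(locus)
  rows <- list()
  add <- function(id, loc, gt, seq, c2 = NA_integer_, c3 = NA_integer_,
                  iso = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      segment_id = id, locus = loc, gene_type = gt, sequence = seq,
      cdr2_start = c2, cdr3_anchor = c3, isotype_label = iso,
      stringsAsFactors = FALSE)
  }
  if (locus == "IGH") {
    # V: 300 nt, CDR2 starts at 150, conserved-Cys codon TGT at 294
    for (k in 1:3)
      add(sprintf("IGHV%d-tst", k), "IGH", "V",
          paste0(toy_nt(294, 1000 + 7 * k), "TGTGCG"),
          c2 = 150L, c3 = 294L)
    add("IGHD1-tst", "IGH", "D", toy_nt(16, 2101))
    add("IGHD2-tst", "IGH", "D", toy_nt(12, 2207))
    # J: 52 nt, conserved Trp codon TGG at 9..12, anchor = 12 (first nt after)
    for (k in 1:2)
      add(sprintf("IGHJ%d-tst", k), "IGH", "J",
          paste0(toy_nt(9, 3300 + 11 * k), "TGG", toy_nt(40, 3400 + 11 * k)),
          c3 = 12L)
    iso_seed <- c(IgM = 41, IgD = 42, IgG3 = 43, IgG1 = 44,
                  IgG2b = 45, IgG2c = 46, IgE = 47, IgA = 48)
    shared <- toy_nt(20, 5900)  # common 5' end of the IgG2b/IgG2c constants
    for (iso in IGH_ISOTYPES) {
      id <- sprintf("IGHC-%s-tst", iso)
      seq <- if (iso %in% c("IgG2b", "IgG2c"))
        paste0(shared, toy_nt(40, 6000 + iso_seed[[iso]]))
      else toy_nt(60, 6000 + iso_seed[[iso]])
      add(id, "IGH", "C", seq, iso = iso)
    }
  } else {
    for (k in 1:4)
      add(sprintf("TRBV%d-tst", k), "TRB", "V",
          paste0(toy_nt(294, 8000 + 13 * k), "TGTGCC"),
          c2 = 150L, c3 = 294L)
    for (k in 1:2)
      add(sprintf("TRBJ%d-tst", k), "TRB", "J",
          paste0(toy_nt(9, 8700 + 17 * k), "TTC", toy_nt(38, 8800 + 17 * k)),
          c3 = 12L)
    add("TRBC-tst", "TRB", "C", toy_nt(60, 9100))
  }
  segments <- do.call(rbind, rows)
  validate_germline(segments)
  new_germline_db(segments)
}
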