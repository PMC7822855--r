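# CDR boundary migration, CDR3 extraction, clonotype aggregation and
# isotype composition.

#' Migrate a germline reference coordinate onto the read
#'
#' Walks the alignment operations from the alignment start until the
#' reference position is reached. Positions outside the aligned reference
#' interval give `NA`; a position inside a deletion maps to the read
#' coordinate immediately 3' of the deletion.
#'
#' @param aln an alignment as returned by [smith_waterman()].
#' @param ref_pos 0-based reference coordinate.
#' @return 0-based read coordinate, or `NA`.
#' @export
migrate_boundary <- function(aln, ref_pos) {
  rs <- aln$ref_interval[1L]; re <- aln$ref_interval[2L]
  if (is.na(ref_pos) || ref_pos < rs || ref_pos >= re) return(NA_integer_)
  q <- aln$query_interval[1L]; r <- rs
  ops <- aln$ops
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$length[k]
    if (op == "M") {
      if (ref_pos < r + len) return(q + (ref_pos - r))
      q <- q + len; r <- r + len
    } else if (op == "I") {
      q <- q + len
    } else {  # D: deletion from the read
      if (ref_pos < r + len) return(q)
      r <- r + len
    }
  }
  NA_integer_
}

#' Extract the CDR3 from V/J calls
#'
#' CDR3 spans from the read projection of the V conserved-Cys anchor to
#' the read projection of the J anchor (first position after the conserved
#' Phe/Trp codon), half-open. The nucleotide CDR3 is translated when its
#' length is a multiple of 3; `productive` requires an in-frame CDR3 with
#' no stop codon.
#'
#' @param sequence the merged transcript sequence.
#' @param calls `segment_calls` with V and J present.
#' @param db the `germline_db` used for assignment.
#' @return list: `cdr3_start`, `cdr3_end`, `cdr3_nt`, `cdr3_aa`,
#'   `productive`, `flag` (`NA` or one of `"v_anchor_uncovered"`,
#'   `"j_anchor_uncovered"`, `"empty_cdr3"`).
#' @export
extract_cdr3 <- function(sequence, calls, db) {
  out <- list(cdr3_start = NA_integer_, cdr3_end = NA_integer_,
              cdr3_nt = NA_character_, cdr3_aa = NA_character_,
              productive = FALSE, flag = NA_character_)
  segs <- db$segments
  v_anchor <- segs$cdr3_anchor[segs$segment_id == calls$v$segment_id]
  j_anchor <- segs$cdr3_anchor[segs$segment_id == calls$j$segment_id]
  s <- migrate_boundary(calls$v, v_anchor)
  if (is.na(s)) { out$flag <- "v_anchor_uncovered"; return(out) }
  # the J anchor is an exclusive end: migrate the last CDR3 base and add 1
  e <- migrate_boundary(calls$j, j_anchor - 1L)
  if (is.na(e)) { out$flag <- "j_anchor_uncovered"; return(out) }
  e <- e + 1L
  if (e <= s) { out$flag <- "empty_cdr3"; return(out) }
  out$cdr3_start <- s; out$cdr3_end <- e
  out$cdr3_nt <- substr(sequence, s + 1L, e)
  aa <- translate_nt(out$cdr3_nt)
  out$cdr3_aa <- aa
  out$productive <- !is.na(aa) && !grepl("\\*", aa)
  out
}

#' Annotate a collection of unique sequences
#'
#' Runs segment assignment, CDR3 extraction and mutation counting over a
#' table of unique transcripts, producing one row per assignable sequence
#' (the annotated repertoire) and counting unassignable inputs.
#'
#' @param uniques data.frame from [collapse_duplicates()].
#' @param db a `germline_db`.
#' @param locus `"IGH"` or `"TRB"`.
#' @param scoring a [scoring_scheme()].
#' @param thresholds per-gene-type minimum scores.
#' @return list with `annotated` (data.frame: sequence, copy_count,
#'   representative_id, v_call, d_call, j_call, c_call, isotype,
#'   isotype_ambiguous, v_score, v_identity, cdr2_start_read, cdr3_start,
#'   cdr3_end, cdr3_nt, cdr3_aa, productive, cdr3_flag, n_mismatch_window,
#'   examined_length, indel_in_window, mutation_flag) and `n_unassignable`.
#' @export
annotate_repertoire <- function(uniques, db, locus = "IGH",
                                scoring = scoring_scheme(),
                                thresholds = default_thresholds()) {
  rows <- vector("list", nrow(uniques))
  n_unassignable <- 0L
  segs <- db$segments
  for (i in seq_len(nrow(uniques))) {
    seqi <- uniques$sequence[i]
    calls <- assign_segments(seqi, db, locus, scoring, thresholds)
    if (calls$unassignable) { n_unassignable <- n_unassignable + 1L; next }
    cdr3 <- extract_cdr3(seqi, calls, db)
    vrow <- segs[segs$segment_id == calls$v$segment_id, ]
    cdr2_read <- migrate_boundary(calls$v, vrow$cdr2_start)
    mut <- count_mutations(calls$v, cdr2_read, cdr3$cdr3_start)
    vlen <- calls$v$query_interval[2L] - calls$v$query_interval[1L]
    rows[[i]] <- data.frame(
      sequence = seqi,
      copy_count = uniques$copy_count[i],
      representative_id = uniques$representative_id[i],
      v_call = calls$v$segment_id,
      d_call = if (is.null(calls$d)) NA_character_ else calls$d$segment_id,
      j_call = calls$j$segment_id,
      c_call = if (is.null(calls$c)) NA_character_ else calls$c$segment_id,
      isotype = calls$isotype,
      isotype_ambiguous = calls$isotype_ambiguous,
      v_score = calls$v$score,
      v_identity = 1 - length(calls$v$mismatch_positions) / max(vlen, 1L),
      cdr2_start_read = cdr2_read,
      cdr3_start = cdr3$cdr3_start,
      cdr3_end = cdr3$cdr3_end,
      cdr3_nt = cdr3$cdr3_nt,
      cdr3_aa = cdr3$cdr3_aa,
      productive = cdr3$productive,
      cdr3_flag = cdr3$flag,
      n_mismatch_window = mut$n_mismatch,
      examined_length = mut$examined_length,
      indel_in_window = mut$indel_in_window,
      mutation_flag = mut$flag,
      stringsAsFactors = FALSE)
  }
  annotated <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(annotated))
    annotated <- data.frame(sequence = character(), copy_count = integer(),
                            representative_id = character(),
                            v_call = character(), d_call = character(),
                            j_call = character(), c_call = character(),
                            isotype = character(),
                            isotype_ambiguous = logical(),
                            v_score = integer(), v_identity = numeric(),
                            cdr2_start_read = integer(),
                            cdr3_start = integer(), cdr3_end = integer(),
                            cdr3_nt = character(), cdr3_aa = character(),
                            productive = logical(), cdr3_flag = character(),
                            n_mismatch_window = integer(),
                            examined_length = integer(),
                            indel_in_window = logical(),
                            mutation_flag = character(),
                            stringsAsFactors = FALSE)
  rownames(annotated) <- NULL
  list(annotated = annotated, n_unassignable = n_unassignable)
}

#' Aggregate annotated sequences into clonotypes
#'
#' Groups by `(v_call, j_call, cdr3_nt)` (or by `cdr3_nt` alone when
#' `key = "cdr3"`), summing copies and tallying per-isotype copies.
#' Sequences without a CDR3 are excluded. Output order is descending total
#' copies, then lexicographic key.
#'
#' @param annotated the annotated data.frame from [annotate_repertoire()].
#' @param key `"vj_cdr3"` (default) or `"cdr3"`.
#' @return data.frame: `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`,
#'   `total_copies`, `n_unique`, plus one `copies_<isotype>` column per
#'   observed isotype.
#' @export
build_clonotypes <- function(annotated, key = c("vj_cdr3", "cdr3")) {
  key <- match.arg(key)
  a <- annotated[!is.na(annotated$cdr3_nt), , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(v_gene = character(), j_gene = character(),
                      cdr3_nt = character(), cdr3_aa = character(),
                      total_copies = integer(), n_unique = integer(),
                      stringsAsFactors = FALSE))
  kv <- if (key == "vj_cdr3")
    paste(a$v_call, a$j_call, a$cdr3_nt, sep = "\r")
  else a$cdr3_nt
  idx <- split(seq_len(nrow(a)), kv)
  isotypes <- sort(unique(a$isotype))
  rows <- lapply(idx, function(ii) {
    sub <- a[ii, , drop = FALSE]
    iso <- vapply(isotypes, function(x)
      sum(sub$copy_count[sub$isotype == x]), integer(1))
    row <- data.frame(
      v_gene = if (key == "vj_cdr3") sub$v_call[1L] else NA_character_,
      j_gene = if (key == "vj_cdr3") sub$j_call[1L] else NA_character_,
      cdr3_nt = sub$cdr3_nt[1L],
      cdr3_aa = sub$cdr3_aa[1L],
      total_copies = sum(sub$copy_count),
      n_unique = nrow(sub),
      stringsAsFactors = FALSE)
    for (x in isotypes) row[[paste0("copies_", x)]] <- iso[[x]]
    row
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$total_copies,
               paste(out$v_gene, out$j_gene, out$cdr3_nt, sep = "\r"))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Copy-weighted isotype composition
#'
#' Percentages of copies per known isotype (summing to 100); the share of
#' copies with unknown isotype is reported separately.
#'
#' @param annotated the annotated data.frame.
#' @return list: `percent` (named numeric, known isotypes),
#'   `unknown_copies`, `total_copies`.
#' @export
isotype_composition <- function(annotated) {
  if (nrow(annotated) == 0)
    return(list(percent = numeric(0), unknown_copies = 0L, total_copies = 0L))
  known <- annotated$isotype != "unknown"
  tot <- sum(annotated$copy_count[known])
  pct <- if (tot > 0) {
    tab <- tapply(annotated$copy_count[known], annotated$isotype[known], sum)
    100 * tab[order(names(tab))] / tot
  } else numeric(0)
  list(percent = setNames(as.numeric(pct), names(pct)),
       unknown_copies = sum(annotated$copy_count[!known]),
       total_copies = sum(annotated$copy_count))
}

#' Write an AIRR Rearrangement TSV
#'
#' Emits the standard columns sequence_id, sequence, v_call, d_call,
#' j_call, c_call, junction, junction_aa, productive, duplicate_count,
#' v_identity.
#'
#' @param annotated the annotated data.frame.
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_airr <- function(annotated, path) {
  out <- data.frame(
    sequence_id = annotated$representative_id,
    sequence = annotated$sequence,
    v_call = annotated$v_call,
    d_call = annotated$d_call,
    j_call = annotated$j_call,
    c_call = annotated$c_call,
    junction = annotated$cdr3_nt,
    junction_aa = annotated$cdr3_aa,
    productive = ifelse(is.na(annotated$productive), "",
                        ifelse(annotated$productive, "T", "F")),
    duplicate_count = annotated$copy_count,
    v_identity = sprintf("%.6f", annotated$v_identity),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
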