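# Somatic hypermutation statistics over the CDR2-start to CDR3-start
# window, under the "more than four copies" filter.

#' Count V-region mutations in the CDR2->CDR3 window
#'
#' Mismatches between the read and its best germline V, restricted to the
#' half-open read interval from the CDR2 start to the CDR3 start.
#' Substitutions only: read positions inside the window that the V
#' alignment does not cover (insertions, uncovered flanks) are excluded
#' from the examined length, and indels touching the window only set
#' `indel_in_window`.
#'
#' @param v_aln the V alignment from [assign_segments()].
#' @param cdr2_start_read,cdr3_start_read 0-based read coordinates of the
#'   window bounds (either may be `NA`).
#' @return list: `n_mismatch`, `examined_length`, `indel_in_window`,
#'   `flag` (`NA` or `"window_undefined"`).
#' @export
count_mutations <- function(v_aln, cdr2_start_read, cdr3_start_read) {
  if (is.na(cdr2_start_read) || is.na(cdr3_start_read) ||
      cdr3_start_read <= cdr2_start_read)
    return(list(n_mismatch = NA_integer_, examined_length = NA_integer_,
                indel_in_window = NA, flag = "window_undefined"))
  w0 <- cdr2_start_read; w1 <- cdr3_start_read
  q <- v_aln$query_interval[1L]
  examined <- 0L
  indel <- FALSE
  ops <- v_aln$ops
  for (k in seq_len(nrow(ops))) {
    op <- ops$op[k]; len <- ops$length[k]
    if (op == "M") {
      examined <- examined + max(0L, min(q + len, w1) - max(q, w0))
      q <- q + len
    } else if (op == "I") {
      if (q < w1 && q + len > w0) indel <- TRUE
      q <- q + len
    } else {  # D: between read positions q-1 and q
      if (q > w0 && q < w1) indel <- TRUE
    }
  }
  mm <- v_aln$mismatch_positions
  list(n_mismatch = sum(mm >= w0 & mm < w1),
       examined_length = examined,
       indel_in_window = indel,
       flag = NA_character_)
}

#' Repertoire-level SHM summary
#'
#' Applies the copy filter (keep records with `copies >= min_copies`,
#' default 5, i.e. more than four copies) and computes the share of
#' transcripts with more than `gt_threshold` nucleotide changes and the
#' mutation rate per 1000 examined bases. Copy weighting treats every copy
#' as one transcript; unique weighting counts each unique sequence once.
#'
#' @param records data.frame with columns `n_mismatch`, `examined_length`,
#'   `copies` (rows with `NA` mismatch counts are dropped as undefined).
#' @param min_copies minimum copy count for inclusion.
#' @param gt_threshold mutation-count threshold for the "highly mutated"
#'   fraction.
#' @param weighting `"copy"` or `"unique"`.
#' @return list: `n_sequences_used`, `n_copies_used`, `frac_gt`,
#'   `rate_per_kb`, `weighting`, `defined` (FALSE when nothing survives
#'   the filter, in which case the statistics are `NA`, not zero).
#' @export
shm_summary <- function(records, min_copies = 5, gt_threshold = 5,
                        weighting = c("copy", "unique")) {
  weighting <- match.arg(weighting)
  r <- records[!is.na(records$n_mismatch) & !is.na(records$examined_length) &
                 records$copies >= min_copies, , drop = FALSE]
  if (nrow(r) == 0)
    return(list(n_sequences_used = 0L, n_copies_used = 0L,
                frac_gt = NA_real_, rate_per_kb = NA_real_,
                weighting = weighting, defined = FALSE))
  w <- if (weighting == "copy") r$copies else rep(1L, nrow(r))
  list(n_sequences_used = nrow(r),
       n_copies_used = sum(r$copies),
       frac_gt = sum(w * (r$n_mismatch > gt_threshold)) / sum(w),
       rate_per_kb = 1000 * sum(w * r$n_mismatch) / sum(w * r$examined_length),
       weighting = weighting, defined = TRUE)
}

#' Per-sequence mutation records from an annotated repertoire
#'
#' @param annotated the annotated data.frame from [annotate_repertoire()].
#' @return data.frame with `n_mismatch`, `examined_length`, `copies`.
#' @export
mutation_records <- function(annotated) {
  data.frame(n_mismatch = annotated$n_mismatch_window,
             examined_length = annotated$examined_length,
             copies = annotated$copy_count,
             stringsAsFactors = FALSE)
}
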