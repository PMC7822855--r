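# Germline segment assignment by affine-gap Smith-Waterman local alignment.

#' Alignment scoring scheme
#'
#' A gap of length L costs `gap_open + L * gap_extend`; `N` bases always
#' score as mismatches.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend per-base gap extension penalty (<= 0).
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2, mismatch = -2, gap_open = -3,
                           gap_extend = -1) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Optimal local alignment of two nucleotide strings
#'
#' Affine-gap Smith-Waterman. Among co-optimal alignments the one with the
#' smallest (query start, ref start) is returned, then smallest endpoint,
#' with a match-state-preferred traceback. Coordinates are 0-based
#' half-open; `mismatch_positions` are query coordinates of substitution
#' columns. An all-negative comparison yields score 0 and empty intervals.
#'
#' @param query,ref nucleotide strings over A/C/G/T/N.
#' @param scoring a [scoring_scheme()].
#' @return list: `score`, `query_interval`, `ref_interval`,
#'   `ops` (data.frame of `op` in M/I/D and `length`), `mismatch_positions`.
#' @export
smith_waterman <- function(query, ref, scoring = scoring_scheme()) {
  stopifnot(is.character(query), is.character(ref),
            nchar(query) > 0, nchar(ref) > 0)
  sw_align_cpp(query, ref, scoring$match, scoring$mismatch,
               scoring$gap_open, scoring$gap_extend)
}

#' Default per-gene-type minimum alignment scores
#' @return named integer vector with entries V, D, J, C.
#' @export
default_thresholds <- function() c(V = 40L, D = 10L, J = 16L, C = 16L)

best_segment_hit <- function(query, segs, scoring, threshold) {
  if (nrow(segs) == 0 || nchar(query) == 0) return(NULL)
  best <- NULL
  for (i in order(segs$segment_id)) {  # lexicographic id order breaks score ties
    a <- smith_waterman(query, segs$sequence[i], scoring)
    if (a$score >= threshold && (is.null(best) || a$score > best$score)) {
      best <- a
      best$segment_id <- segs$segment_id[i]
    }
  }
  best
}

#' Assign germline V, D, J, C segments to a sequence
#'
#' The best-scoring segment per gene type above its minimum score is
#' called; score ties break to the lexicographically smallest segment_id.
#' D is searched only in the window between the read projection of the V
#' CDR3 anchor and the J alignment start. Calls violating the read-order
#' v <= d <= j <= c are demoted to absent (D first, then C). A sequence
#' with no V or no J call is unassignable.
#'
#' @param sequence merged transcript sequence (character scalar).
#' @param db a `germline_db`.
#' @param locus `"IGH"` or `"TRB"`.
#' @param scoring a [scoring_scheme()].
#' @param thresholds named vector of per-gene-type minimum scores.
#' @return a `segment_calls` list: `v`, `d`, `j`, `c` (alignments with
#'   `segment_id`, or `NULL`), `isotype`, `isotype_ambiguous`,
#'   `unassignable`.
#' @export
assign_segments <- function(sequence, db, locus = "IGH",
                            scoring = scoring_scheme(),
                            thresholds = default_thresholds()) {
  vs <- db_segments(db, locus, "V")
  js <- db_segments(db, locus, "J")
  cs <- db_segments(db, locus, "C")
  ds <- db_segments(db, locus, "D")

  v <- best_segment_hit(sequence, vs, scoring, thresholds[["V"]])
  j <- best_segment_hit(sequence, js, scoring, thresholds[["J"]])
  out <- list(v = v, d = NULL, j = j, c = NULL,
              isotype = "unknown", isotype_ambiguous = FALSE,
              unassignable = is.null(v) || is.null(j))
  class(out) <- "segment_calls"
  if (out$unassignable) return(out)

  # C: best constant hit, with a tie flag for shared 5' subclass sequence
  if (nrow(cs) > 0) {
    scores <- rep(NA_integer_, nrow(cs))
    alns <- vector("list", nrow(cs))
    ord <- order(cs$segment_id)
    for (i in ord) {
      a <- smith_waterman(sequence, cs$sequence[i], scoring)
      scores[i] <- a$score
      alns[[i]] <- a
    }
    top <- max(scores)
    if (top >= thresholds[["C"]]) {
      winners <- ord[scores[ord] == top]
      ci <- winners[1L]
      out$c <- alns[[ci]]
      out$c$segment_id <- cs$segment_id[ci]
      out$isotype_ambiguous <- length(winners) > 1L
    }
  }

  # D: only inside the window between V's CDR3-anchor projection and J start
  if (nrow(ds) > 0) {
    vrow <- vs[vs$segment_id == v$segment_id, ]
    wstart <- migrate_boundary(v, vrow$cdr3_anchor)
    wend <- j$query_interval[1L]
    if (!is.na(wstart) && wend - wstart >= 1) {
      win <- substr(sequence, wstart + 1L, wend)
      d <- best_segment_hit(win, ds, scoring, thresholds[["D"]])
      if (!is.null(d)) {
        d$query_interval <- d$query_interval + wstart
        d$mismatch_positions <- d$mismatch_positions + wstart
        out$d <- d
      }
    }
  }

  # enforce v <= d <= j <= c read ordering (demote D first, then C)
  starts <- function(a) if (is.null(a)) NA_integer_ else a$query_interval[1L]
  if (!is.null(out$d) &&
      (starts(out$d) < starts(out$v) || starts(out$d) > starts(out$j)))
    out$d <- NULL
  if (!is.null(out$c) && starts(out$c) < starts(out$j))
    out$c <- NULL
  if (!is.null(out$c)) {
    crow <- cs[cs$segment_id == out$c$segment_id, ]
    out$isotype <- call_isotype_label(crow, locus)
  }
  out
}

call_isotype_label <- function(crow, locus) {
  if (locus == "TRB") return("TRBC")
  if (is.na(crow$isotype_label)) "unknown" else crow$isotype_label
}

#' Isotype call from segment calls
#'
#' The isotype label of the called constant segment; `"unknown"` when no C
#' call survived; `"TRBC"` for TRB.
#'
#' @param calls a `segment_calls` object.
#' @return character scalar.
#' @export
call_isotype <- function(calls) calls$isotype
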