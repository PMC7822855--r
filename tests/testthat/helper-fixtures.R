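# Deterministic fixture builders over the bundled toy reference.

toy_igh <- builtin_toy_reference("IGH")

# Hand-assemble an amplicon exactly the way the assay produces it:
# V flank (from cdr2_start - flank_v) through the trimmed V 3' end, the
# junction (ins1 + D fragment + ins2), the trimmed J, and a C prefix.
# `mutations` are 0-based amplicon coordinates whose base is flipped
# (A->C->G->T->A). Returns the sequence plus truth coordinates.
make_amplicon <- function(db = toy_igh, v_id = "IGHV1-tst",
                          j_id = "IGHJ1-tst", c_id = "IGHC-IgM-tst",
                          vtrim = 0, jtrim = 0, ins1 = "", d_frag = "",
                          ins2 = "", flank_v = 110, c_len = 60,
                          mutations = integer(0)) {
  s <- db$segments
  vrow <- s[s$segment_id == v_id, ]
  jrow <- s[s$segment_id == j_id, ]
  crow <- s[s$segment_id == c_id, ]
  v_from <- vrow$cdr2_start - flank_v
  v_keep <- nchar(vrow$sequence) - vtrim
  v_part <- substr(vrow$sequence, v_from + 1L, v_keep)
  j_part <- substr(jrow$sequence, jtrim + 1L, nchar(jrow$sequence))
  c_part <- substr(crow$sequence, 1L, c_len)
  body <- paste0(v_part, ins1, d_frag, ins2, j_part)
  cdr3_start <- vrow$cdr3_anchor - v_from
  cdr3_end <- nchar(v_part) + nchar(ins1) + nchar(d_frag) + nchar(ins2) +
    (jrow$cdr3_anchor - jtrim)
  cdr3_nt <- substr(body, cdr3_start + 1L, cdr3_end)
  seq <- paste0(body, c_part)
  if (length(mutations)) {
    ch <- strsplit(seq, "")[[1]]
    flip <- c(A = "C", C = "G", G = "T", T = "A")
    for (p in mutations) ch[p + 1L] <- flip[[ch[p + 1L]]]
    seq <- paste(ch, collapse = "")
  }
  list(sequence = seq, cdr2_pos = vrow$cdr2_start - v_from,
       cdr3_start = cdr3_start, cdr3_end = cdr3_end, cdr3_nt = cdr3_nt)
}

as_uniques <- function(seqs, copies = 1L, ids = NULL) {
  data.frame(sequence = seqs,
             copy_count = rep_len(copies, length(seqs)),
             representative_id = ids %||% sprintf("fix%03d", seq_along(seqs)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_reads <- function(seqs, q = 35, prefix = "r") {
  data.frame(read_id = sprintf("%s%03d", prefix, seq_along(seqs)),
             sequence = seqs,
             quality = vapply(nchar(seqs),
                              function(L) intToUtf8(rep(q + 33L, L)),
                              character(1)),
             stringsAsFactors = FALSE)
}
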