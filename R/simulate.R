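# Ground-truthed repertoire and read simulator.
#
# Emulates the amplicon assay the pipeline expects: clonally structured
# repertoires with V(D)J junctional diversity, per-base somatic
# hypermutation confined to the V region 5' of CDR3, class-switched
# isotype mixtures, ~400 bp amplicons read as overlapping paired-end reads
# with a 5' constant-region barcode on the C-side mate, and configurable
# per-base sequencing error.

#' Simulation configuration
#'
#' Defaults describe the emulated assay: MiSeq-style 2 x 250 nt reads over
#' ~400 bp amplicons spanning an FR2-proximal flank 5' of CDR2 through the
#' first 60 nt of the constant segment; a geometric clone-size law (mean
#' 4); a mostly-IgM class-switched mixture; SHM applied per clone, uniform
#' over the V portion 5' of the CDR3 start.
#'
#' @param seed integer seed; every random choice derives from it.
#' @param locus `"IGH"` or `"TRB"`.
#' @param n_clones number of clones.
#' @param clone_size_law `"geometric"`, `"power_law"`, or `"uniform"`.
#' @param clone_size_param geometric success probability, power-law
#'   exponent, or the fixed uniform size.
#' @param v_usage_weights named weights over V segment ids (`NULL` =
#'   uniform).
#' @param isotype_mixture named fractions over isotype labels, summing to
#'   1 (IGH only; ignored for TRB).
#' @param shm_rate_per_base per-base substitution rate in the V portion 5'
#'   of CDR3.
#' @param junction_insert_range integer range (inclusive) for each of the
#'   two junction inserts.
#' @param v_trim_range,j_trim_range integer trim ranges at the V 3' / J 5'
#'   ends.
#' @param amplicon_flank list: `v` = bases retained 5' of CDR2, `c` =
#'   bases of constant segment included.
#' @param read_length read length in nt.
#' @param barcode 5' barcode prepended to R2.
#' @param seq_error_rate per-base sequencing error rate.
#' @param quality_model list: `q` constant Phred value, `tail_len`,
#'   `tail_q` for an optional low-quality 3' tail.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1, locus = "IGH", n_clones = 200,
                              clone_size_law = c("geometric", "power_law",
                                                 "uniform"),
                              clone_size_param = 0.25,
                              v_usage_weights = NULL,
                              isotype_mixture = c(IgM = 0.90, IgG1 = 0.04,
                                                  IgG3 = 0.03, IgA = 0.03),
                              shm_rate_per_base = 0.01,
                              junction_insert_range = c(0L, 6L),
                              v_trim_range = c(0L, 3L),
                              j_trim_range = c(0L, 4L),
                              amplicon_flank = list(v = 110L, c = 60L),
                              read_length = 250L,
                              barcode = "ACGTAC",
                              seq_error_rate = 0.001,
                              quality_model = list(q = 35L, tail_len = 0L,
                                                   tail_q = 10L)) {
  clone_size_law <- match.arg(clone_size_law)
  if (abs(sum(isotype_mixture) - 1) > 1e-9)
    stopf("isotype_mixture must sum to 1")
  if (locus == "IGH" && !all(names(isotype_mixture) %in% IGH_ISOTYPES))
    stopf("unknown isotype in mixture: %s",
          paste(setdiff(names(isotype_mixture), IGH_ISOTYPES), collapse = ", "))
  cfg <- list(seed = as.integer(seed), locus = locus,
              n_clones = as.integer(n_clones),
              clone_size_law = clone_size_law,
              clone_size_param = clone_size_param,
              v_usage_weights = v_usage_weights,
              isotype_mixture = isotype_mixture,
              shm_rate_per_base = shm_rate_per_base,
              junction_insert_range = as.integer(junction_insert_range),
              v_trim_range = as.integer(v_trim_range),
              j_trim_range = as.integer(j_trim_range),
              amplicon_flank = amplicon_flank,
              read_length = as.integer(read_length),
              barcode = barcode,
              seq_error_rate = seq_error_rate,
              quality_model = quality_model)
  class(cfg) <- "sim_config"
  cfg
}

draw_clone_sizes <- function(cfg) {
  n <- cfg$n_clones
  switch(cfg$clone_size_law,
         geometric = rgeom(n, cfg$clone_size_param) + 1L,
         power_law = {
           # discrete Pareto: P(size >= k) ~ k^(1 - alpha)
           u <- runif(n)
           as.integer(pmin(10000, floor(u^(-1 / (cfg$clone_size_param - 1)))))
         },
         uniform = rep(as.integer(cfg$clone_size_param), n))
}

rand_nt <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a ground-truthed repertoire
#'
#' Draws clones (V/D/J/C choice, junction, isotype, clone size), applies
#' per-clone SHM to the V portion 5' of the CDR3 start, and records the
#' clean and mutated amplicon plus the exact CDR3 and mutation positions.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @param db a `germline_db` covering `cfg$locus`.
#' @return a `sim_truth` list: `clones` data.frame (clone_id, v_id, d_id,
#'   j_id, c_id, isotype, copies, cdr3_nt, junction_nt, amplicon,
#'   mutated_amplicon, cdr2_pos, cdr3_start_pos, n_shm, shm_positions
#'   comma-separated amplicon coordinates, n_shm_window), plus `cfg`.
#' @export
simulate_repertoire <- function(cfg, db) {
  vs <- db_segments(db, cfg$locus, "V")
  ds <- db_segments(db, cfg$locus, "D")
  js <- db_segments(db, cfg$locus, "J")
  cs <- db_segments(db, cfg$locus, "C")
  if (nrow(vs) == 0 || nrow(js) == 0 || nrow(cs) == 0)
    stopf("database does not cover locus %s", cfg$locus)

  vw <- if (is.null(cfg$v_usage_weights)) {
    setNames(rep(1, nrow(vs)), vs$segment_id)
  } else {
    miss <- setdiff(names(cfg$v_usage_weights), vs$segment_id)
    if (length(miss)) stopf("v_usage_weights for unknown V: %s",
                            paste(miss, collapse = ", "))
    cfg$v_usage_weights
  }
  iso_names <- if (cfg$locus == "IGH") names(cfg$isotype_mixture) else "TRBC"
  iso_probs <- if (cfg$locus == "IGH") as.numeric(cfg$isotype_mixture) else 1
  c_for_iso <- function(iso) {
    if (cfg$locus == "TRB") return(cs$segment_id[1L])
    cs$segment_id[match(iso, cs$isotype_label)]
  }

  with_local_seed(cfg$seed, {
    sizes <- draw_clone_sizes(cfg)
    rows <- vector("list", cfg$n_clones)
    for (i in seq_len(cfg$n_clones)) {
      v_id <- sample(names(vw), 1L, prob = as.numeric(vw))
      j_id <- sample(js$segment_id, 1L)
      iso <- sample(iso_names, 1L, prob = iso_probs)
      c_id <- c_for_iso(iso)
      if (is.na(c_id)) stopf("no constant segment for isotype %s", iso)
      vrow <- vs[vs$segment_id == v_id, ]
      jrow <- js[js$segment_id == j_id, ]
      crow <- cs[cs$segment_id == c_id, ]

      ok <- FALSE
      for (try in 1:50) {
        vtrim <- sample(cfg$v_trim_range[1]:cfg$v_trim_range[2], 1L)
        jtrim <- sample(cfg$j_trim_range[1]:cfg$j_trim_range[2], 1L)
        n1 <- sample(cfg$junction_insert_range[1]:cfg$junction_insert_range[2], 1L)
        n2 <- sample(cfg$junction_insert_range[1]:cfg$junction_insert_range[2], 1L)
        v_keep <- nchar(vrow$sequence) - vtrim
        if (v_keep > vrow$cdr3_anchor && jtrim < jrow$cdr3_anchor) {
          ok <- TRUE; break
        }
      }
      if (!ok) stopf("could not draw a feasible junction for clone %d", i)

      d_id <- NA_character_; d_frag <- ""
      if (nrow(ds) > 0) {
        d_id <- sample(ds$segment_id, 1L)
        dseq <- ds$sequence[ds$segment_id == d_id]
        dl <- nchar(dseq)
        a <- sample(0:(dl - 4L), 1L)              # keep >= 4 nt of D
        b <- sample((a + 4L):dl, 1L)
        d_frag <- substr(dseq, a + 1L, b)
      }
      ins1 <- rand_nt(n1); ins2 <- rand_nt(n2)

      flank_v <- cfg$amplicon_flank$v
      v_from <- max(0L, vrow$cdr2_start - flank_v)
      v_part <- substr(vrow$sequence, v_from + 1L, v_keep)
      j_part <- substr(jrow$sequence, jtrim + 1L, nchar(jrow$sequence))
      c_part <- substr(crow$sequence, 1L, min(cfg$amplicon_flank$c,
                                              nchar(crow$sequence)))
      amplicon <- paste0(v_part, ins1, d_frag, ins2, j_part)
      junction_nt <- paste0(ins1, d_frag, ins2)
      cdr2_pos <- vrow$cdr2_start - v_from
      cdr3_start_pos <- vrow$cdr3_anchor - v_from
      cdr3_end_pos <- nchar(v_part) + n1 + nchar(d_frag) + n2 +
        (jrow$cdr3_anchor - jtrim)
      cdr3_nt <- substr(amplicon, cdr3_start_pos + 1L, cdr3_end_pos)
      amplicon <- paste0(amplicon, c_part)

      # per-clone SHM: substitutions uniform over the V portion 5' of CDR3
      mut <- amplicon
      shm_pos <- integer(0)
      if (cfg$shm_rate_per_base > 0 && cdr3_start_pos > 0) {
        hit <- which(runif(cdr3_start_pos) < cfg$shm_rate_per_base)
        if (length(hit)) {
          ch <- strsplit(mut, "")[[1]]
          for (p in hit)
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          mut <- paste(ch, collapse = "")
          shm_pos <- hit - 1L
        }
      }
      rows[[i]] <- data.frame(
        clone_id = sprintf("clone%04d", i),
        v_id = v_id, d_id = d_id, j_id = j_id, c_id = c_id, isotype = iso,
        copies = sizes[i],
        cdr3_nt = cdr3_nt, junction_nt = junction_nt,
        amplicon = amplicon, mutated_amplicon = mut,
        cdr2_pos = cdr2_pos, cdr3_start_pos = cdr3_start_pos,
        n_shm = length(shm_pos),
        shm_positions = paste(shm_pos, collapse = ","),
        n_shm_window = sum(shm_pos >= cdr2_pos & shm_pos < cdr3_start_pos),
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    rownames(truth) <- NULL
    structure(list(clones = truth, cfg = cfg), class = "sim_truth")
  })
}

apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(list(seqs = seqs, n_errors = integer(length(seqs))))
  nerr <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    L <- nchar(seqs[i])
    hit <- which(runif(L) < rate)
    if (length(hit)) {
      ch <- strsplit(seqs[i], "")[[1]]
      for (p in hit) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      nerr[i] <- length(hit)
    }
  }
  list(seqs = seqs, n_errors = nerr)
}

quality_string <- function(len, qm) {
  q <- rep(qm$q, len)
  if (qm$tail_len > 0 && len > 0) {
    tail_idx <- max(1L, len - qm$tail_len + 1L):len
    q[tail_idx] <- qm$tail_q
  }
  int_to_phred(q)
}

#' Emit paired-end FASTQ reads for a simulated repertoire
#'
#' Per copy: R1 is the 5' `read_length` nt of the (mutated) amplicon; R2
#' is the reverse complement of the 3' `read_length` nt with the sample
#' barcode prepended. Sequencing errors are injected per base at
#' `seq_error_rate` (barcode bases excluded); qualities follow the
#' constant-plus-tail quality model. Deterministic given the seed.
#'
#' @param truth a `sim_truth` from [simulate_repertoire()].
#' @param r1_path,r2_path output FASTQ paths (`.gz` allowed).
#' @param seed read-level seed; defaults to `cfg$seed + 1`.
#' @return invisibly, a data.frame of per-copy records (`read_id`,
#'   `clone_id`, `copy`, `n_errors_r1`, `n_errors_r2`).
#' @export
emit_reads <- function(truth, r1_path, r2_path, seed = NULL) {
  cfg <- truth$cfg
  seed <- seed %||% (cfg$seed + 1L)
  cl <- truth$clones
  idx <- rep(seq_len(nrow(cl)), cl$copies)
  copy_no <- sequence(cl$copies)
  read_id <- sprintf("%s_copy%04d", cl$clone_id[idx], copy_no)
  amp <- cl$mutated_amplicon[idx]
  L <- nchar(amp)
  rl <- cfg$read_length

  r1 <- substr(amp, 1L, pmin(rl, L))
  r2 <- revcomp(substr(amp, pmax(1L, L - rl + 1L), L))
  with_local_seed(seed, {
    e1 <- apply_seq_errors(r1, cfg$seq_error_rate)
    e2 <- apply_seq_errors(r2, cfg$seq_error_rate)
  })
  r2full <- paste0(cfg$barcode, e2$seqs)

  qm <- cfg$quality_model
  q1 <- vapply(nchar(e1$seqs), quality_string, character(1), qm = qm)
  qbc <- int_to_phred(rep(qm$q, nchar(cfg$barcode)))
  q2 <- paste0(qbc, vapply(nchar(e2$seqs), quality_string, character(1),
                           qm = qm))

  write_fastq(data.frame(read_id = read_id, sequence = e1$seqs,
                         quality = q1, stringsAsFactors = FALSE), r1_path)
  write_fastq(data.frame(read_id = read_id, sequence = r2full,
                         quality = q2, stringsAsFactors = FALSE), r2_path)
  invisible(data.frame(read_id = read_id, clone_id = cl$clone_id[idx],
                       copy = copy_no, n_errors_r1 = e1$n_errors,
                       n_errors_r2 = e2$n_errors, stringsAsFactors = FALSE))
}

#' Truth-level clonotype table
#'
#' Aggregates the simulator's truth records by (V, J, CDR3 nucleotide)
#' exactly as [build_clonotypes()] keys the pipeline output, for
#' end-to-end comparisons.
#'
#' @param truth a `sim_truth`.
#' @return data.frame `v_gene`, `j_gene`, `cdr3_nt`, `total_copies` plus
#'   `copies_<isotype>` columns, ordered like [build_clonotypes()].
#' @export
truth_clonotypes <- function(truth) {
  cl <- truth$clones
  kv <- paste(cl$v_id, cl$j_id, cl$cdr3_nt, sep = "\r")
  idx <- split(seq_len(nrow(cl)), kv)
  isotypes <- sort(unique(cl$isotype))
  rows <- lapply(idx, function(ii) {
    sub <- cl[ii, , drop = FALSE]
    row <- data.frame(v_gene = sub$v_id[1L], j_gene = sub$j_id[1L],
                      cdr3_nt = sub$cdr3_nt[1L],
                      total_copies = sum(sub$copies),
                      stringsAsFactors = FALSE)
    for (x in isotypes)
      row[[paste0("copies_", x)]] <- sum(sub$copies[sub$isotype == x])
    row
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$total_copies,
               paste(out$v_gene, out$j_gene, out$cdr3_nt, sep = "\r"))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
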