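# Read preprocessing: demultiplexing by 5' constant-region barcode, sliding
# window quality trimming, exact-overlap pair merging, duplicate collapsing.
#
# Read sets are plain data.frames with columns read_id, sequence, quality
# (Phred+33 string, same length as sequence).

#' Read a FASTQ file into a read-set data.frame
#'
#' @param path FASTQ path (gzip transparent).
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  # the FASTQ reader attaches a metadata column that later narrowing drops
  # with a warning; it is never used here
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read-set data.frame to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param path output path; `.gz` suffix enables compression.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$sequence)
  names(dna) <- reads$read_id
  q <- Biostrings::PhredQuality(Biostrings::BStringSet(reads$quality))
  x <- Biostrings::QualityScaledDNAStringSet(dna, q)
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

hamming_prefix <- function(prefixes, barcode) {
  bl <- nchar(barcode)
  bc <- strsplit(barcode, "")[[1]]
  pm <- matrix(unlist(strsplit(prefixes, "")), nrow = bl)
  colSums(pm != bc)
}

#' Demultiplex read pairs by 5' barcode
#'
#' Barcodes sit at the 5' end of the constant-region-side mate (`R2` by
#' convention). A pair is assigned to the unique sample whose barcode is
#' within `max_mismatch` of the mate's prefix; the barcode is then removed
#' from that mate. Pairs matching no barcode go to `unassigned`; pairs
#' within `max_mismatch` of two or more barcodes go to `ambiguous`.
#'
#' @param r1,r2 read-set data.frames (same length, pair order).
#' @param barcode_table data.frame with columns `barcode`, `sample`
#'   (equal-length barcodes, unique samples).
#' @param max_mismatch maximum Hamming distance for a barcode hit.
#' @param barcode_mate which mate carries the barcode, `"R2"` or `"R1"`.
#' @return list with `samples` (named list of `list(r1=, r2=)` read sets),
#'   `unassigned`, `ambiguous` (pair index vectors) and a `report`
#'   data.frame of per-bin pair counts.
#' @export
demultiplex <- function(r1, r2, barcode_table, max_mismatch = 0,
                        barcode_mate = c("R2", "R1")) {
  barcode_mate <- match.arg(barcode_mate)
  stopifnot(nrow(r1) == nrow(r2))
  bl <- unique(nchar(barcode_table$barcode))
  if (length(bl) != 1L) stopf("barcodes must all have equal length")
  if (anyDuplicated(barcode_table$barcode)) stopf("duplicate barcodes")

  host <- if (barcode_mate == "R2") r2 else r1
  n <- nrow(host)
  prefixes <- substr(host$sequence, 1L, bl)
  ok_len <- nchar(host$sequence) >= bl

  nb <- nrow(barcode_table)
  dmat <- matrix(Inf, nrow = n, ncol = nb)
  if (n > 0) for (b in seq_len(nb))
    dmat[ok_len, b] <- hamming_prefix(prefixes[ok_len], barcode_table$barcode[b])
  hits <- dmat <= max_mismatch
  nhits <- rowSums(hits)

  assigned_bin <- integer(n)
  one <- nhits == 1L
  assigned_bin[one] <- max.col(hits[one, , drop = FALSE], ties.method = "first")

  trim_host <- function(df, idx) {
    df <- df[idx, , drop = FALSE]
    df$sequence <- substr(df$sequence, bl + 1L, nchar(df$sequence))
    df$quality <- substr(df$quality, bl + 1L, nchar(df$quality))
    rownames(df) <- NULL
    df
  }
  samples <- list()
  for (b in seq_len(nb)) {
    idx <- which(one & assigned_bin == b)
    pair <- if (barcode_mate == "R2")
      list(r1 = r1[idx, , drop = FALSE], r2 = trim_host(r2, idx))
    else
      list(r1 = trim_host(r1, idx), r2 = r2[idx, , drop = FALSE])
    rownames(pair$r1) <- rownames(pair$r2) <- NULL
    samples[[barcode_table$sample[b]]] <- pair
  }
  unassigned <- which(nhits == 0L)
  ambiguous <- which(nhits >= 2L)
  report <- data.frame(
    bin = c(barcode_table$sample, "unassigned", "ambiguous"),
    pairs = c(vapply(samples, function(p) nrow(p$r1), integer(1)),
              length(unassigned), length(ambiguous)),
    stringsAsFactors = FALSE)
  list(samples = samples, unassigned = unassigned, ambiguous = ambiguous,
       report = report)
}

#' Sliding-window quality trimming
#'
#' Windows of `window` bases slide in 1-base steps from the 5' end; at the
#' first window containing any quality below `qmin`, the window's first
#' position and everything 3' of it are removed. Reads shorter than
#' `window` are left untouched. Vectorized over the read set; idempotent.
#'
#' @param reads a read-set data.frame.
#' @param window window width in bases.
#' @param qmin minimum acceptable Phred quality.
#' @return the trimmed read set (possibly zero-length sequences).
#' @export
quality_trim <- function(reads, window = 2, qmin = 20) {
  stopifnot(window >= 1, qmin >= 0)
  window <- as.integer(window)
  n <- nrow(reads)
  if (n == 0) return(reads)
  keep_len <- vapply(seq_len(n), function(i) {
    q <- phred_to_int(reads$quality[i])
    L <- length(q)
    if (L < window) return(L)
    bad <- which(q < qmin)
    if (!length(bad)) return(L)
    p1 <- bad[1L]
    s <- max(1L, p1 - window + 1L)  # first failing window start (1-based)
    as.integer(s - 1L)
  }, integer(1))
  reads$sequence <- substr(reads$sequence, 1L, keep_len)
  reads$quality <- substr(reads$quality, 1L, keep_len)
  reads
}

#' Merge mate pairs by exact-overlap alignment
#'
#' R2 is reverse-complemented, then the best gap-free end-free overlap of
#' R1's 3' end with R2's 5' end is found (score = matches - mismatches over
#' the overlap; ties prefer fewer mismatches, then longer overlap). A pair
#' merges only if the best overlap is a perfect character match of length
#' at least `min_overlap`; otherwise it is discarded with reason
#' `"mismatch"` or `"short_overlap"`. Pairs where either trimmed mate is
#' shorter than `min_length` are discarded first (reason `"too_short"`).
#'
#' @param r1,r2 read-set data.frames in pair order.
#' @param min_overlap minimum overlap length in bases.
#' @param min_length minimum per-mate length after trimming.
#' @return list with `merged` (data.frame `merged_id`, `sequence`,
#'   `overlap_length`, `source_pair`) and `discarded` (named counts by
#'   reason).
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10, min_length = 50) {
  stopifnot(nrow(r1) == nrow(r2), min_overlap >= 1)
  n <- nrow(r1)
  if (n == 0)
    return(list(merged = data.frame(merged_id = character(),
                                    sequence = character(),
                                    overlap_length = integer(),
                                    source_pair = character(),
                                    stringsAsFactors = FALSE),
                discarded = c(too_short = 0L, short_overlap = 0L,
                              mismatch = 0L)))
  long_enough <- nchar(r1$sequence) >= min_length &
    nchar(r2$sequence) >= min_length
  idx <- which(long_enough)
  res <- merge_pairs_cpp(r1$sequence[idx], revcomp(r2$sequence[idx]),
                         as.integer(min_overlap))
  ok <- res$status == 0L
  merged <- data.frame(
    merged_id = r1$read_id[idx][ok],
    sequence = res$merged[ok],
    overlap_length = res$overlap_length[ok],
    source_pair = r1$read_id[idx][ok],
    stringsAsFactors = FALSE)
  discarded <- c(too_short = sum(!long_enough),
                 short_overlap = sum(res$status == 2L),
                 mismatch = sum(res$status == 1L))
  list(merged = merged, discarded = discarded)
}

#' Collapse identical merged sequences into unique transcripts
#'
#' Exact string grouping within one sample; the representative id is the
#' lexicographically smallest contributing read id, so the result is
#' independent of input order.
#'
#' @param merged the `merged` data.frame from [merge_pairs()].
#' @return data.frame `sequence`, `copy_count`, `representative_id`,
#'   ordered by decreasing copy count then sequence.
#' @export
collapse_duplicates <- function(merged) {
  if (nrow(merged) == 0)
    return(data.frame(sequence = character(), copy_count = integer(),
                      representative_id = character(),
                      stringsAsFactors = FALSE))
  grp <- split(merged$merged_id, merged$sequence)
  out <- data.frame(
    sequence = names(grp),
    copy_count = vapply(grp, length, integer(1)),
    representative_id = vapply(grp, function(x) min(x), character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$copy_count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}
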