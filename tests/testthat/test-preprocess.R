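barcodes <- data.frame(barcode = c("AAAAAA", "AAAATT"),
                       sample = c("s1", "s2"), stringsAsFactors = FALSE)

pair_for <- function(prefixes) {
  r2 <- make_reads(paste0(prefixes, strrep("ACGT", 30)), prefix = "m")
  r1 <- make_reads(rep(strrep("TGCA", 30), length(prefixes)), prefix = "m")
  list(r1 = r1, r2 = r2)
}

test_that("demultiplex assigns by barcode prefix and strips it", {
  p <- pair_for("AAAAAA")
  dm <- demultiplex(p$r1, p$r2, barcodes, max_mismatch = 0)
  expect_equal(nrow(dm$samples$s1$r1), 1)
  expect_equal(dm$samples$s1$r2$sequence, strrep("ACGT", 30))
  expect_equal(nchar(dm$samples$s1$r2$quality), 120)

  # one mismatch with max_mismatch = 0 is unassigned
  dm0 <- demultiplex(pair_for("AAAAAC")$r1, pair_for("AAAAAC")$r2,
                     barcodes, max_mismatch = 0)
  expect_equal(length(dm0$unassigned), 1)

  # distance 3 / 1 at max_mismatch 1: uniquely assigned to the closer barcode
  dm1 <- demultiplex(pair_for("AAATTT")$r1, pair_for("AAATTT")$r2,
                     barcodes, max_mismatch = 1)
  expect_equal(nrow(dm1$samples$s2$r1), 1)
  expect_equal(nrow(dm1$samples$s1$r1), 0)

  # distance 1 to both: ambiguous
  dm2 <- demultiplex(pair_for("AAAAAT")$r1, pair_for("AAAAAT")$r2,
                     barcodes, max_mismatch = 1)
  expect_equal(length(dm2$ambiguous), 1)
  expect_equal(nrow(dm2$samples$s1$r1) + nrow(dm2$samples$s2$r1), 0)
})

test_that("demultiplex conserves pairs across bins", {
  set.seed(11)
  prefixes <- vapply(1:60, function(i) random_nt(6), character(1))
  p <- pair_for(prefixes)
  for (mm in 0:2) {
    dm <- demultiplex(p$r1, p$r2, barcodes, max_mismatch = mm)
    assigned <- sum(vapply(dm$samples, function(s) nrow(s$r1), integer(1)))
    expect_equal(assigned + length(dm$unassigned) + length(dm$ambiguous), 60)
  }
})

test_that("quality trimming follows the 2-base sliding window rule", {
  mk <- function(quals) data.frame(
    read_id = "r", sequence = strrep("A", length(quals)),
    quality = intToUtf8(quals + 33L), stringsAsFactors = FALSE)

  expect_equal(nchar(quality_trim(mk(c(30, 30, 30, 30)))$sequence), 4)
  # first failing window covers (30, 10) at 0-based index 2 -> keep 2
  expect_equal(nchar(quality_trim(mk(c(30, 30, 30, 10, 30)))$sequence), 2)
  # failing window at the very start -> keep 0
  expect_equal(nchar(quality_trim(mk(c(10, 30, 30)))$sequence), 0)
  # low quality at the last base: window L-2 fails -> keep L-2
  expect_equal(nchar(quality_trim(mk(c(30, 30, 30, 10)))$sequence), 2)
})

test_that("quality trimming is idempotent", {
  set.seed(7)
  reads <- data.frame(
    read_id = sprintf("r%d", 1:50),
    sequence = vapply(1:50, function(i) random_nt(40), character(1)),
    quality = vapply(1:50, function(i)
      intToUtf8(sample(2:40, 40, TRUE) + 33L), character(1)),
    stringsAsFactors = FALSE)
  once <- quality_trim(reads)
  twice <- quality_trim(once)
  expect_identical(once, twice)
})

test_that("pair merging reconstructs the amplicon and rejects mismatches", {
  set.seed(3)
  amplicon <- random_nt(400)
  r1 <- make_reads(substr(amplicon, 1, 250))
  r2 <- make_reads(revcomp(substr(amplicon, 151, 400)))
  mg <- merge_pairs(r1, r2, min_overlap = 10)
  expect_equal(nrow(mg$merged), 1)
  expect_equal(mg$merged$sequence, amplicon)
  expect_equal(mg$merged$overlap_length, 100)

  # one substitution inside the overlap (R2 side) -> discarded as mismatch
  r2bad <- r2
  ch <- strsplit(r2bad$sequence, "")[[1]]
  # R2 position 200 reverse-complements into the first 100 nt of the
  # reoriented mate, i.e. inside the 100-nt overlap
  ch[200] <- setdiff(c("A", "C", "G", "T"), ch[200])[1]
  r2bad$sequence <- paste(ch, collapse = "")
  mgb <- merge_pairs(r1, r2bad, min_overlap = 10)
  expect_equal(nrow(mgb$merged), 0)
  expect_equal(unname(mgb$discarded["mismatch"]), 1L)

  # disjoint halves with a 4-nt chance overlap -> short overlap
  left <- paste0(strrep("A", 46), "ACGT")
  right <- paste0("ACGT", strrep("C", 46))
  mgs <- merge_pairs(make_reads(left, q = 35),
                     make_reads(revcomp(right), q = 35), min_overlap = 10,
                     min_length = 50)
  expect_equal(nrow(mgs$merged), 0)
  expect_equal(unname(mgs$discarded["short_overlap"]), 1L)
})

test_that("pairs below the minimum length are discarded symmetrically", {
  r1 <- make_reads(random_nt(30))
  r2 <- make_reads(random_nt(250))
  mg <- merge_pairs(r1, r2, min_overlap = 10, min_length = 50)
  expect_equal(nrow(mg$merged), 0)
  expect_equal(unname(mg$discarded["too_short"]), 1L)
})

test_that("duplicate collapsing conserves copies and ignores input order", {
  m <- data.frame(
    merged_id = sprintf("r%02d", 1:9),
    sequence = c(rep("AAAA", 5), rep("CCCC", 4)),
    overlap_length = 10L, source_pair = sprintf("r%02d", 1:9),
    stringsAsFactors = FALSE)
  u <- collapse_duplicates(m)
  expect_equal(u$copy_count, c(5L, 4L))
  expect_equal(sum(u$copy_count), 9)
  expect_equal(u$representative_id, c("r01", "r06"))

  shuffled <- m[sample(nrow(m)), ]
  expect_identical(collapse_duplicates(shuffled), u)
  expect_equal(nrow(collapse_duplicates(m[0, ])), 0)
})

test_that("FASTQ writing and reading round-trips", {
  reads <- make_reads(c("ACGTACGTAC", "GGGGCCCCAA"), q = 30)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back, reads)
})
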