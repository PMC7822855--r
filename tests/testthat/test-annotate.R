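test_that("boundary migration walks matches, insertions and deletions", {
  ungapped <- list(query_interval = c(0L, 100L), ref_interval = c(10L, 110L),
                   ops = data.frame(op = "M", length = 100L),
                   mismatch_positions = integer(0))
  expect_equal(migrate_boundary(ungapped, 40L), 30L)
  expect_equal(migrate_boundary(ungapped, 10L), 0L)
  expect_true(is.na(migrate_boundary(ungapped, 5L)))    # before ref start
  expect_true(is.na(migrate_boundary(ungapped, 110L)))  # at half-open end

  # 2-nt deletion in the read at ref 40..42: later positions shift by -2
  gapped <- list(query_interval = c(0L, 98L), ref_interval = c(10L, 110L),
                 ops = data.frame(op = c("M", "D", "M"),
                                  length = c(30L, 2L, 66L)),
                 mismatch_positions = integer(0))
  expect_equal(migrate_boundary(gapped, 50L), 38L)
  # position inside the deletion maps immediately 3' of it
  expect_equal(migrate_boundary(gapped, 41L), 30L)

  # insertion in the read shifts later positions by +its length
  ins <- list(query_interval = c(0L, 103L), ref_interval = c(10L, 110L),
              ops = data.frame(op = c("M", "I", "M"),
                               length = c(30L, 3L, 70L)),
              mismatch_positions = integer(0))
  expect_equal(migrate_boundary(ins, 50L), 43L)
})

test_that("CDR3 extraction matches construction truth", {
  amp <- make_amplicon(v_id = "IGHV3-tst", j_id = "IGHJ2-tst",
                       vtrim = 2, jtrim = 3, ins1 = "GG",
                       d_frag = "ACGTACGT", ins2 = "TTA")
  ann <- annotate_repertoire(as_uniques(amp$sequence), toy_igh)$annotated
  expect_equal(nrow(ann), 1)
  expect_equal(ann$cdr3_nt, amp$cdr3_nt)
  expect_equal(ann$cdr3_start, amp$cdr3_start)
  expect_equal(ann$cdr3_end, amp$cdr3_end)
  # in-frame CDR3 without stop codons is productive
  if (nchar(amp$cdr3_nt) %% 3 == 0)
    expect_equal(ann$productive, !grepl("\\*", ann$cdr3_aa))
})

test_that("out-of-frame CDR3 is untranslated and unproductive", {
  # junction sized so CDR3 length is not a multiple of 3
  for (extra in c("", "G", "GG")) {
    amp <- make_amplicon(ins1 = extra, d_frag = "ACGTA")
    ann <- annotate_repertoire(as_uniques(amp$sequence), toy_igh)$annotated
    if (nchar(ann$cdr3_nt) %% 3 != 0) {
      expect_true(is.na(ann$cdr3_aa))
      expect_false(ann$productive)
    } else {
      expect_false(is.na(ann$cdr3_aa))
    }
  }
})

test_that("clonotype grouping keys on V, J and CDR3 and conserves copies", {
  # two unique sequences differing by one V-region mutation share a clonotype
  a1 <- make_amplicon(ins1 = "GGC")
  a2 <- make_amplicon(ins1 = "GGC", mutations = 60L)
  # same junction under the other J is a different clonotype
  b <- make_amplicon(j_id = "IGHJ2-tst", ins1 = "GGC")
  uniq <- as_uniques(c(a1$sequence, a2$sequence, b$sequence),
                     copies = c(5L, 3L, 2L))
  ann <- annotate_repertoire(uniq, toy_igh)$annotated
  clon <- build_clonotypes(ann)
  expect_equal(sum(clon$total_copies), sum(uniq$copy_count))
  key_a <- clon[clon$j_gene == "IGHJ1-tst", ]
  expect_equal(nrow(key_a), 1)
  expect_equal(key_a$n_unique, 2L)
  expect_equal(key_a$total_copies, 8L)
  expect_equal(nrow(clon), 2)
})

test_that("cdr3-only keying merges across V/J", {
  amp1 <- make_amplicon(v_id = "IGHV1-tst", ins1 = "CCA")
  clon <- build_clonotypes(
    annotate_repertoire(as_uniques(amp1$sequence), toy_igh)$annotated,
    key = "cdr3")
  expect_true(all(is.na(clon$v_gene)))
})

test_that("isotype composition is copy-weighted and sums to 100", {
  amps <- list(make_amplicon(c_id = "IGHC-IgM-tst", ins1 = "A"),
               make_amplicon(c_id = "IGHC-IgG1-tst", ins1 = "C"))
  uniq <- as_uniques(vapply(amps, `[[`, character(1), "sequence"),
                     copies = c(979L, 21L))
  ann <- annotate_repertoire(uniq, toy_igh)$annotated
  iso <- isotype_composition(ann)
  expect_equal(iso$percent[["IgM"]], 97.9)
  expect_equal(iso$percent[["IgG1"]], 2.1)
  expect_equal(sum(iso$percent), 100, tolerance = 1e-9)

  single <- isotype_composition(ann[1, , drop = FALSE])
  expect_equal(unname(single$percent), 100)
  expect_equal(isotype_composition(ann[0, , drop = FALSE])$percent,
               numeric(0))
})

test_that("AIRR export has the standard columns", {
  amp <- make_amplicon()
  ann <- annotate_repertoire(as_uniques(amp$sequence), toy_igh)$annotated
  path <- withr::local_tempfile(fileext = ".tsv")
  write_airr(ann, path)
  airr <- read.delim(path, stringsAsFactors = FALSE)
  expect_named(airr, c("sequence_id", "sequence", "v_call", "d_call",
                       "j_call", "c_call", "junction", "junction_aa",
                       "productive", "duplicate_count", "v_identity"))
  expect_equal(airr$junction, amp$cdr3_nt)
})
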