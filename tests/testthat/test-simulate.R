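test_that("simulation is deterministic and honors degenerate settings", {
  db <- builtin_toy_reference("IGH")
  cfg <- simulation_config(seed = 5, n_clones = 15, shm_rate_per_base = 0,
                           isotype_mixture = c(IgM = 1.0),
                           seq_error_rate = 0)
  t1 <- simulate_repertoire(cfg, db)
  t2 <- simulate_repertoire(cfg, db)
  expect_identical(t1$clones, t2$clones)
  expect_true(all(t1$clones$n_shm == 0))
  expect_true(all(t1$clones$isotype == "IgM"))
  expect_true(all(t1$clones$amplicon == t1$clones$mutated_amplicon))

  d1 <- withr::local_tempdir()
  emit_reads(t1, file.path(d1, "a1.fastq"), file.path(d1, "a2.fastq"))
  emit_reads(t1, file.path(d1, "b1.fastq"), file.path(d1, "b2.fastq"))
  expect_identical(readLines(file.path(d1, "a1.fastq")),
                   readLines(file.path(d1, "b1.fastq")))
  expect_identical(readLines(file.path(d1, "a2.fastq")),
                   readLines(file.path(d1, "b2.fastq")))
})

test_that("uniform single-copy repertoire has the expected rank abundance", {
  db <- builtin_toy_reference("IGH")
  cfg <- simulation_config(seed = 8, n_clones = 4,
                           clone_size_law = "uniform", clone_size_param = 1,
                           shm_rate_per_base = 0, seq_error_rate = 0)
  tr <- simulate_repertoire(cfg, db)
  expect_equal(tr$clones$copies, rep(1L, 4))
  tc <- truth_clonotypes(tr)
  if (nrow(tc) == 4) {       # distinct junctions (generic case)
    ra <- structure(list(r = sort(tc$total_copies, decreasing = TRUE),
                         S = nrow(tc), J = sum(tc$total_copies)),
                    class = "rank_abundance")
    expect_equal(d50(ra)$D50, 50)
  }
})

test_that("truth CDR3 matches the anchor arithmetic and SHM spares CDR3", {
  db <- builtin_toy_reference("IGH")
  cfg <- simulation_config(seed = 12, n_clones = 30,
                           shm_rate_per_base = 0.03, seq_error_rate = 0)
  tr <- simulate_repertoire(cfg, db)
  cl <- tr$clones
  # mutations confined to the V portion 5' of the CDR3 start
  for (i in which(cl$n_shm > 0)) {
    pos <- as.integer(strsplit(cl$shm_positions[i], ",")[[1]])
    expect_true(all(pos < cl$cdr3_start_pos[i]))
  }
  # CDR3 in the mutated amplicon is intact
  got <- substr(cl$mutated_amplicon, cl$cdr3_start_pos + 1L,
                cl$cdr3_start_pos + nchar(cl$cdr3_nt))
  expect_equal(got, cl$cdr3_nt)
})

test_that("low-quality tails make every read trimmable", {
  db <- builtin_toy_reference("IGH")
  cfg <- simulation_config(seed = 13, n_clones = 5, seq_error_rate = 0,
                           quality_model = list(q = 35L, tail_len = 3L,
                                                tail_q = 10L))
  tr <- simulate_repertoire(cfg, db)
  d <- withr::local_tempdir()
  emit_reads(tr, file.path(d, "r1.fastq"), file.path(d, "r2.fastq"))
  r1 <- read_fastq(file.path(d, "r1.fastq"))
  trimmed <- quality_trim(r1)
  expect_true(all(nchar(trimmed$sequence) <= nchar(r1$sequence) - 3))
})

test_that("configuration validation rejects bad mixtures", {
  expect_error(simulation_config(isotype_mixture = c(IgM = 0.5, IgG1 = 0.4)),
               "sum to 1")
  expect_error(simulation_config(isotype_mixture = c(IgX = 1.0)),
               "IgX")
})

test_that("end-to-end: error-free reads reproduce the truth clonotypes", {
  db <- builtin_toy_reference("IGH")
  cfg <- simulation_config(seed = 17, n_clones = 30, shm_rate_per_base = 0,
                           seq_error_rate = 0)
  tr <- simulate_repertoire(cfg, db)
  d <- withr::local_tempdir()
  emit_reads(tr, file.path(d, "r1.fastq"), file.path(d, "r2.fastq"))
  rep <- run_pipeline(list(r1 = file.path(d, "r1.fastq"),
                           r2 = file.path(d, "r2.fastq"),
                           barcode_table = data.frame(barcode = "ACGTAC",
                                                      sample = "s1")))
  pc <- rep$s1$clonotypes
  tc <- truth_clonotypes(tr)
  expect_equal(pc[, c("v_gene", "j_gene", "cdr3_nt", "total_copies")],
               tc[, c("v_gene", "j_gene", "cdr3_nt", "total_copies")])
  iso_cols <- grep("^copies_", names(tc), value = TRUE)
  for (col in iso_cols) expect_equal(pc[[col]], tc[[col]])
})
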