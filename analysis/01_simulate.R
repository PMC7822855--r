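#!/usr/bin/env Rscript

# Simulate the two repertoire phenotypes the downstream analyses contrast:
#   naive  - polyclonal, IgM-dominated, essentially unmutated (B-1a-like)
#   active - oligoclonal, class-switched, hypermutated (GC/activated-like)
# Each sample gets its own 5' constant-region barcode; the two read sets are
# pooled into one paired FASTQ as a multiplexed sequencing run would be.

suppressPackageStartupMessages(library(vdjmap))

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
db <- builtin_toy_reference("IGH")

cfg_naive <- simulation_config(
  seed = 20260101, n_clones = 150,
  clone_size_law = "geometric", clone_size_param = 0.35,
  isotype_mixture = c(IgM = 0.95, IgD = 0.03, IgG3 = 0.02),
  shm_rate_per_base = 0.001, barcode = "ACGTAC")

cfg_active <- simulation_config(
  seed = 20260102, n_clones = 40,
  clone_size_law = "power_law", clone_size_param = 2.0,
  isotype_mixture = c(IgG1 = 0.45, IgG2b = 0.20, IgG3 = 0.15,
                      IgM = 0.10, IgA = 0.10),
  shm_rate_per_base = 0.02, barcode = "TTGCAA")

emit <- function(cfg, name) {
  tr <- simulate_repertoire(cfg, db)
  r1 <- file.path(outdir, paste0(name, "_R1.fastq"))
  r2 <- file.path(outdir, paste0(name, "_R2.fastq"))
  emit_reads(tr, r1, r2)
  truth_cols <- setdiff(names(tr$clones), c("amplicon", "mutated_amplicon"))
  write.table(tr$clones[, truth_cols],
              file.path(outdir, paste0(name, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("%s: %d clones, %d read pairs, %d clonotypes in truth\n",
              name, nrow(tr$clones), sum(tr$clones$copies),
              nrow(truth_clonotypes(tr))))
  list(r1 = r1, r2 = r2)
}

naive <- emit(cfg_naive, "naive")
active <- emit(cfg_active, "active")

# pool the two samples into one multiplexed pair of FASTQ files
pool <- function(files, out) {
  writeLines(unlist(lapply(files, readLines)), out)
}
pool(c(naive$r1, active$r1), file.path(outdir, "pooled_R1.fastq"))
pool(c(naive$r2, active$r2), file.path(outdir, "pooled_R2.fastq"))

write.table(data.frame(barcode = c("ACGTAC", "TTGCAA"),
                       sample = c("naive", "active")),
            file.path(outdir, "barcodes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("pooled multiplexed FASTQ written under", outdir, "\n")
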