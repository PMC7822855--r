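#!/usr/bin/env Rscript

# Render the V / V-J / V-J-CDR3 tree-maps for the two pipeline samples.
# Each rounded rectangle is one CDR3 nucleotide sequence; area is its share
# of reads; heavy borders delimit V genes, light borders V-J combinations.

suppressPackageStartupMessages(library(vdjmap))

dir.create("results/treemaps", recursive = TRUE, showWarnings = FALSE)
for (sample in c("naive", "active")) {
  airr <- sprintf("results/pipeline/%s_airr.tsv", sample)
  stopifnot(file.exists(airr))
  tab <- read.delim(airr, stringsAsFactors = FALSE)
  ann <- data.frame(v_call = tab$v_call, j_call = tab$j_call,
                    cdr3_nt = tab$junction, cdr3_aa = tab$junction_aa,
                    copy_count = tab$duplicate_count,
                    isotype = "unknown", stringsAsFactors = FALSE)
  clon <- build_clonotypes(ann)
  root <- layout_treemap(build_hierarchy(clon), width = 600, height = 400,
                         seed = 42)
  out <- sprintf("results/treemaps/%s_treemap.svg", sample)
  render_svg(root, out, corner_radius = 3)
  cat(sprintf("%s: %d clonotypes -> %s\n", sample, nrow(clon), out))
}
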