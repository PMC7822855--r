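# Rank-abundance construction, the D50 clonal diversity index, and V-gene
# usage.
#
# For a repertoire of J total CDR3 copies over S distinct CDR3s with ranked
# abundances r_1 >= r_2 >= ... >= r_S, C is the minimum number of top-ranked
# clones whose copies reach at least J/2, and D50 = 100 * C / S. Low D50
# marks an oligoclonal repertoire.

#' Ranked clone-abundance vector
#'
#' @param clonotypes data.frame from [build_clonotypes()].
#' @param key clone key, `"vj_cdr3"` (as built) or `"cdr3"` (re-merge by
#'   CDR3 nucleotide sequence alone).
#' @return a `rank_abundance` list: `r` (non-increasing integer vector),
#'   `S`, `J`.
#' @export
rank_abundance <- function(clonotypes, key = c("vj_cdr3", "cdr3")) {
  key <- match.arg(key)
  if (nrow(clonotypes) == 0) stopf("empty repertoire")
  counts <- if (key == "cdr3")
    tapply(clonotypes$total_copies, clonotypes$cdr3_nt, sum)
  else
    setNames(clonotypes$total_copies,
             paste(clonotypes$v_gene, clonotypes$j_gene, clonotypes$cdr3_nt))
  counts <- counts[order(-counts, names(counts))]  # ties: lexicographic key
  structure(list(r = as.integer(counts), S = length(counts),
                 J = sum(as.integer(counts))),
            class = "rank_abundance")
}

#' D50 clonal diversity index
#'
#' C is the smallest prefix of the ranked abundances whose sum reaches at
#' least half the repertoire (J/2 kept as an exact rational); D50 is
#' 100 * C / S.
#'
#' @param ra a [rank_abundance()] object.
#' @return list: `C`, `D50`, `S`, `J`.
#' @export
d50 <- function(ra) {
  stopifnot(inherits(ra, "rank_abundance"), ra$S >= 1)
  cs <- cumsum(as.numeric(ra$r))
  C <- which(2 * cs >= ra$J)[1L]  # 2*prefix >= J avoids dividing J by 2
  list(C = C, D50 = 100 * C / ra$S, S = ra$S, J = ra$J)
}

#' V-gene usage fractions
#'
#' @param clonotypes data.frame from [build_clonotypes()].
#' @return data.frame `v_gene`, `copy_fraction` (copy-weighted, sums to 1),
#'   `unique_fraction` (per distinct clonotype).
#' @export
v_usage <- function(clonotypes) {
  if (nrow(clonotypes) == 0)
    return(data.frame(v_gene = character(), copy_fraction = numeric(),
                      unique_fraction = numeric(), stringsAsFactors = FALSE))
  cw <- tapply(clonotypes$total_copies, clonotypes$v_gene, sum)
  uw <- table(clonotypes$v_gene)
  genes <- sort(names(cw))
  data.frame(v_gene = genes,
             copy_fraction = as.numeric(cw[genes]) / sum(cw),
             unique_fraction = as.numeric(uw[genes]) / sum(uw),
             stringsAsFactors = FALSE, row.names = NULL)
}
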