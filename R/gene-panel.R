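#' Reference transcript panel: genes co-regulated in cancer and neurodegeneration
#'
#' The GenBank accession panel this package's reference workflow targets:
#' four human genes jointly dysregulated in cancer and neurodegeneration —
#' APP, CCND1 and CCNE1 (up-regulated in both disease classes) and PTPA
#' (down-regulated in both) — with the deposited CDS length of each
#' transcript (nucleotides, ATG through terminal stop). Sequences themselves
#' are not shipped; retrieve them from GenBank and feed them through
#' [read_gene_set()] to reproduce accession-level statistics. The lengths
#' alone already fix all pair-count bookkeeping (a transcript of L nt has
#' L/3 codons and L/3 - 1 adjacent codon pairs).
#'
#' @return Data frame: `gene`, `accession`, `length_nt`, `group`
#'   (`"up"`/`"down"`).
#' @export
gene_panel_transcripts <- function() {
  df <- data.frame(
    gene = c(rep("APP", 11), "CCND1", rep("CCNE1", 4), rep("PTPA", 6)),
    accession = c("NM_000484", "NM_201413", "NM_201414", "NM_001136016",
                  "NM_001136129", "NM_001136131", "NM_001204301",
                  "NM_001204302", "NM_001385253", "NM_001136130",
                  "NM_001204303",
                  "AF511593",
                  "NM_001322262", "NM_001322261", "NM_001322259",
                  "NM_001238",
                  "NM_178001", "NM_001193397", "NM_001271832", "NM_021131",
                  "NM_178003", "NM_178000"),
    length_nt = c(2313, 2256, 2088, 2241, 1920, 1983, 2259, 2202, 2145,
                  2145, 2034,
                  888,
                  1188, 1086, 1098, 1233,
                  1077, 867, 885, 972, 846, 972),
    stringsAsFactors = FALSE
  )
  df$group <- ifelse(df$gene == "PTPA", "down", "up")
  df
}

#' Total codon pairs per gene implied by a length panel
#'
#' Adjacent overlapping pairs with the stop codon included as the 3' member
#' of the final pair give `sum(length_nt / 3) - n_transcripts` pairs per
#' gene.
#'
#' @param panel Data frame with `gene` and `length_nt` columns (default:
#'   the packaged panel).
#' @return Named integer vector: gene -> total pair count N.
#' @export
panel_pair_totals <- function(panel = gene_panel_transcripts()) {
  vapply(split(panel$length_nt, panel$gene), function(l)
    as.integer(sum(l / 3) - length(l)), integer(1))
}

#' Total codons per gene implied by a length panel
#'
#' `sum(length_nt / 3)` per gene, stop codons included: the denominator of
#' the length-adjusted pair score ([adjusted_pair_score()]).
#'
#' @inheritParams panel_pair_totals
#' @return Named integer vector: gene -> total codon count.
#' @export
panel_codon_totals <- function(panel = gene_panel_transcripts()) {
  vapply(split(panel$length_nt, panel$gene), function(l)
    as.integer(sum(l / 3)), integer(1))
}
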