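#' Length-adjusted per-codon percentages
#'
#' Codon frequencies adjusted for transcript length: each codon's percentage
#' occurrence, `100 * count / total codons`. By default the denominator
#' spans sense plus stop codons (the whole deposited CDS); percentages sum
#' to 100.
#'
#' @param counts Codon counts from [codon_counts()].
#' @param include_stop Keep stop codons in the denominator (default TRUE).
#' @return Named numeric vector of percentages (64 codons; stop codons are
#'   reported too when included).
#' @export
codon_percentages <- function(counts, include_stop = TRUE) {
  code <- genetic_code()
  if (!include_stop) counts[code$stop_codons] <- 0L
  tot <- sum(counts)
  if (tot == 0) stop("empty codon count table")
  100 * counts / tot
}

#' Gene-average codon frequencies with rare-codon flags
#'
#' Per-gene average of length-adjusted per-transcript codon percentages
#' (unweighted mean over transcripts, so a long isoform does not dominate),
#' with codons flagged rare when the gene-average percentage falls strictly
#' below the threshold (default 0.5%).
#'
#' @param gs A [gene_set()].
#' @param threshold Rare-codon percentage cutoff (strict `<`; default 0.5).
#' @param include_stop Passed to [codon_percentages()].
#' @param code A [genetic_code()].
#' @return Object of class `rare_codon_table`: a data frame with one row per
#'   gene x sense codon (`gene`, `codon`, `aa`, `degeneracy_class`,
#'   `mean_pct`, `rare`), plus attribute `summary`, a data frame counting
#'   per codon the number of genes in which it is rare.
#' @export
rare_codon_table <- function(gs, threshold = 0.5, include_stop = TRUE,
                             code = genetic_code()) {
  stopifnot(length(gs) > 0)
  fam_deg <- aa_degeneracy(code)
  rows <- list()
  for (g in names(gs)) {
    pcts <- vapply(gs[[g]], function(r)
      codon_percentages(codon_counts(r), include_stop), numeric(64))
    avg <- rowMeans(pcts)
    cods <- code$syn_codons
    rows[[g]] <- data.frame(
      gene = g,
      codon = cods,
      aa = unname(code$aa[cods]),
      degeneracy_class = unname(fam_deg[code$aa[cods]]),
      mean_pct = unname(avg[cods]),
      rare = unname(avg[cods] < threshold),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_rare <- tapply(out$rare, out$codon, sum)
  summary <- data.frame(codon = names(n_rare),
                        genes_rare = as.integer(n_rare),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$genes_rare, summary$codon), ]
  rownames(summary) <- NULL
  structure(out, summary = summary, threshold = threshold,
            class = c("rare_codon_table", "data.frame"))
}

#' Rare codons per gene and across genes
#'
#' @param tab A [rare_codon_table()].
#' @param min_genes Report codons rare in at least this many genes in the
#'   cross-gene summary component.
#' @return List with `per_gene` (named list gene -> rare codon vector) and
#'   `shared` (codons rare in >= `min_genes` genes).
#' @export
flag_rare <- function(tab, min_genes = 1L) {
  per_gene <- lapply(split(tab, tab$gene), function(d)
    sort(d$codon[d$rare]))
  s <- attr(tab, "summary")
  list(per_gene = per_gene,
       shared = s$codon[s$genes_rare >= min_genes])
}

#' Split a codon frequency table into degeneracy-class panels
#'
#' Partitions the 59 synonymous codons into the two-, three-, four- and
#' six-fold degeneracy panels (18/3/20/18 codons; class assigned per
#' amino-acid family, so all six Leu/Ser/Arg codons sit in the six-fold
#' panel).
#'
#' @param tab A [rare_codon_table()] (or any data frame with a
#'   `degeneracy_class` column).
#' @return Named list of data frames: `"2"`, `"3"`, `"4"`, `"6"`.
#' @export
group_by_degeneracy <- function(tab) {
  split(as.data.frame(tab), factor(tab$degeneracy_class, levels = c(2, 3, 4, 6)))
}
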