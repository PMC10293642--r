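#' Count adjacent codon pairs in a set of transcripts
#'
#' Counts overlapping adjacent codon pairs (positions i, i+1) per transcript
#' and pools them, the 5' codon indexing rows and the 3' codon columns. The
#' terminal stop codon participates as the 3' member of the last pair, so a
#' transcript of k codons contributes k - 1 pairs and the pooled total is
#' `N = sum(codons) - n_transcripts`.
#'
#' @param records A list of validated [cds_record()]s (e.g. one `gene_set`
#'   entry), or a single record.
#' @return Object of class `pair_table`: 64 x 64 integer matrix of observed
#'   counts with attributes `N` (total pairs), `n_codons` (total codons,
#'   the denominator of [adjusted_pair_score()]) and `n_transcripts`.
#' @export
count_pairs <- function(records) {
  if (inherits(records, "cds_record")) records <- list(records)
  code <- genetic_code()
  m <- matrix(0L, 64, 64, dimnames = list(code$codons, code$codons))
  n_codons <- 0L
  for (r in records) {
    cods <- split_codons(r)
    k <- length(cods)
    n_codons <- n_codons + k
    if (k < 2L) next
    from <- cods[-k]
    to <- cods[-1L]
    t2 <- table(factor(from, levels = code$codons),
                factor(to, levels = code$codons))
    m <- m + as.integer(t2)
  }
  dim(m) <- c(64L, 64L)
  dimnames(m) <- list(code$codons, code$codons)
  structure(m, N = sum(m), n_codons = n_codons,
            n_transcripts = length(records),
            class = c("pair_table", "matrix"))
}

#' @export
print.pair_table <- function(x, ...) {
  cat("<pair_table:", attr(x, "N"), "pairs,",
      sum(unclass(x) > 0), "distinct>\n")
  invisible(x)
}

#' Length-adjusted codon-pair score
#'
#' A pair's occurrence normalised by transcript length: `100 * count /
#' total_codons`, with the gene's total codon count (stop included) as the
#' denominator. Reported to two decimals in tabular output.
#'
#' @param count Observed pair count (vectorised).
#' @param total_codons The gene's total codon count (the `n_codons`
#'   attribute of [count_pairs()]).
#' @return Percentage score(s).
#' @export
adjusted_pair_score <- function(count, total_codons) {
  if (any(total_codons <= 0)) stop("total_codons must be positive")
  if (any(count > total_codons)) stop("count exceeds total_codons")
  100 * count / total_codons
}

#' Top occurring codon pairs
#'
#' Ranks pairs by count (descending); ties are broken by the codon-pair
#' string in reverse lexicographic order, matching the conventional ordering
#' of equal-count blocks in published tables.
#'
#' @param table A [count_pairs()] table.
#' @param k Number of pairs to return (default 15; fewer if fewer pairs are
#'   populated).
#' @return Data frame: `pair` ("AAA-AAA" style), `codon1`, `codon2`,
#'   `count`, `adjusted_score` (rounded to 2 decimals).
#' @export
top_pairs <- function(table, k = 15L) {
  m <- unclass(table)
  denom <- attr(table, "n_codons")
  if (is.null(denom)) denom <- attr(table, "N")
  idx <- which(m > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(pair = character(0), codon1 = character(0),
                      codon2 = character(0), count = integer(0),
                      adjusted_score = numeric(0)))
  c1 <- rownames(m)[idx[, 1]]
  c2 <- colnames(m)[idx[, 2]]
  cnt <- m[idx]
  pair <- paste0(c1, "-", c2)
  ord <- order(-cnt, pair, decreasing = c(FALSE, TRUE), method = "radix")
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(pair = pair[ord], codon1 = c1[ord], codon2 = c2[ord],
             count = cnt[ord],
             adjusted_score = round(adjusted_pair_score(cnt[ord], denom), 2),
             stringsAsFactors = FALSE)
}

#' Adjusted residuals of the codon-pair contingency table
#'
#' Pearson adjusted residuals of the 64 x 64 pair table under row/column
#' independence: `(O - E) / sqrt(E * (1 - rowsum/N) * (1 - colsum/N))` with
#' `E = rowsum * colsum / N`. Approximately standard normal under
#' independence, so |residual| > 5 marks strong context preference or
#' avoidance. Cells whose row or column total is zero carry no information
#' and are NA (reported "absent" by [classify_context()]).
#'
#' @param table A [count_pairs()] table.
#' @return 64 x 64 numeric matrix of adjusted residuals with attributes
#'   `expected` (matrix E) and `N`.
#' @export
context_residuals <- function(table) {
  m <- unclass(table)
  N <- attr(table, "N")
  if (N <= 0) stop("empty pair table")
  rs <- rowSums(m)
  cs <- colSums(m)
  if (sum(rs > 0) < 2L || sum(cs > 0) < 2L)
    stop("degenerate pair table: a single populated row or column")
  E <- outer(rs, cs) / N
  denom <- sqrt(E * outer(1 - rs / N, 1 - cs / N))
  res <- (m - E) / denom
  res[E == 0 | denom == 0] <- NA_real_
  attr(res, "expected") <- E
  attr(res, "N") <- N
  res
}

#' Classify codon-pair context from adjusted residuals
#'
#' A 3' codon in "good" context follows its 5' codon more often than
#' expected (residual above +band), "bad" context less often (below -band);
#' residuals within the band are not significant, and cells with no data
#' (zero margins) are "absent".
#'
#' @param residuals Matrix from [context_residuals()].
#' @param band Significance half-width (default 5).
#' @return 64 x 64 character matrix over
#'   `{"good", "bad", "not_significant", "absent"}`.
#' @export
classify_context <- function(residuals, band = 5) {
  cls <- matrix("not_significant", nrow(residuals), ncol(residuals),
                dimnames = dimnames(residuals))
  cls[residuals > band] <- "good"
  cls[residuals < -band] <- "bad"
  cls[is.na(residuals)] <- "absent"
  cls
}

#' Codon usage immediately after the initiator ATG
#'
#' Frequency ranking of the codon at position 2 across a gene's transcripts,
#' probing the strongly constrained context right after the start codon.
#' Ties rank lexicographically.
#'
#' @param records List of validated [cds_record()]s.
#' @return Data frame `codon`, `count`, `frequency`, ordered by decreasing
#'   count then codon.
#' @export
start_context <- function(records) {
  if (inherits(records, "cds_record")) records <- list(records)
  second <- vapply(records, function(r) split_codons(r)[2L], character(1))
  tb <- table(second)
  out <- data.frame(codon = names(tb), count = as.integer(tb),
                    stringsAsFactors = FALSE)
  out$frequency <- out$count / sum(out$count)
  out <- out[order(-out$count, out$codon), ]
  rownames(out) <- NULL
  out
}
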