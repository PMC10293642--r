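#' Overall nucleotide composition of a coding sequence
#'
#' Percentages of A, C, G, T over the whole CDS (by default including the
#' terminal stop codon, so that the span matches the deposited transcript
#' length), plus %GC and %AT.
#'
#' @param record A validated [cds_record()] or nucleotide string.
#' @param include_stop Include the terminal stop codon in the span
#'   (default TRUE).
#' @return Named numeric vector: `A`, `C`, `G`, `T`, `GC`, `AT` (percent).
#' @export
base_composition <- function(record, include_stop = TRUE) {
  s <- if (inherits(record, "cds_record")) record$sequence else toupper(record)
  n <- nchar(s)
  if (n == 0L) stop("empty sequence")
  if (!include_stop && n >= 6L && n %% 3L == 0L &&
      substr(s, n - 2L, n) %in% genetic_code()$stop_codons) {
    s <- substr(s, 1L, n - 3L)
    n <- n - 3L
  }
  cnt <- vapply(c("A", "C", "G", "T"),
                function(b) sum(strsplit(s, "")[[1]] == b), numeric(1))
  pct <- 100 * cnt / n
  c(pct, GC = unname(pct["G"] + pct["C"]), AT = unname(pct["A"] + pct["T"]))
}

#' Position-wise nucleotide composition
#'
#' Percent A/C/G/T at codon positions 1, 2 and 3, plus GC content overall and
#' per position (GC1/GC2/GC3). Each positional quadruple sums to 100.
#'
#' @param codons Codon character vector (from [split_codons()]).
#' @param include_stop Include the final codon when it is a stop
#'   (default TRUE).
#' @return Named numeric vector with elements `A1..T1`, `A2..T2`, `A3..T3`,
#'   `GC1`, `GC2`, `GC3` (percent).
#' @export
positional_composition <- function(codons, include_stop = TRUE) {
  if (length(codons) == 0L) stop("empty codon list")
  if (!include_stop && length(codons) > 1L &&
      codons[length(codons)] %in% genetic_code()$stop_codons)
    codons <- codons[-length(codons)]
  out <- numeric(0)
  gc_pos <- numeric(3)
  for (p in 1:3) {
    bases <- substr(codons, p, p)
    pct <- vapply(c("A", "C", "G", "T"),
                  function(b) 100 * sum(bases == b) / length(bases),
                  numeric(1))
    names(pct) <- paste0(c("A", "C", "G", "T"), p)
    gc_pos[p] <- pct[[paste0("C", p)]] + pct[[paste0("G", p)]]
    out <- c(out, pct)
  }
  c(out, GC1 = gc_pos[1], GC2 = gc_pos[2], GC3 = gc_pos[3])
}

#' Synonymous third-position composition (A3s, C3s, G3s, T3s, GC3s)
#'
#' Third-position base fractions restricted to synonymously variable codons
#' (stop codons and the singleton amino acids Met and Trp always excluded).
#' For each base the denominator is the number of codons whose synonymous
#' family contains at least one member ending in that base — the codonW
#' convention — so a Phe codon (TTT/TTC) counts toward T3s and C3s
#' eligibility but not A3s/G3s. GC3s uses all 59 synonymous codons as the
#' denominator (every multi-codon family has a G- or C-ending member).
#'
#' @param codons Codon character vector.
#' @param code A [genetic_code()].
#' @return Named numeric vector `A3s`, `C3s`, `G3s`, `T3s`, `GC3s`
#'   (fractions in \[0, 1\]).
#' @export
synonymous_third_composition <- function(codons, code = genetic_code()) {
  cods <- codons[codons %in% code$syn_codons]
  if (length(cods) == 0L) stop("no eligible codons")
  tb <- third_base(cods)
  fam_bases <- lapply(code$families, third_base)
  out <- numeric(4)
  names(out) <- c("A3s", "C3s", "G3s", "T3s")
  for (b in c("A", "C", "G", "T")) {
    eligible_aa <- names(fam_bases)[vapply(fam_bases, function(x)
      b %in% x, logical(1))]
    eligible_aa <- setdiff(eligible_aa, c("M", "W"))
    elig <- cods[code$aa[cods] %in% eligible_aa]
    out[[paste0(b, "3s")]] <-
      if (length(elig)) sum(third_base(elig) == b) / length(elig) else NA_real_
  }
  c(out, GC3s = sum(tb %in% c("G", "C")) / length(cods))
}

#' Full composition profile for a transcript
#'
#' Bundles [base_composition()], [positional_composition()] and
#' [synonymous_third_composition()] into one named vector, the per-transcript
#' row of the composition report.
#'
#' @inheritParams base_composition
#' @param code A [genetic_code()].
#' @return Named numeric vector.
#' @export
composition_profile <- function(record, include_stop = TRUE,
                                code = genetic_code()) {
  cods <- split_codons(record)
  c(base_composition(record, include_stop),
    positional_composition(cods, include_stop),
    synonymous_third_composition(cods, code))
}
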