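#' The standard genetic code with synonymous-family structure
#'
#' Builds a genetic-code object carrying the codon-to-amino-acid map and the
#' degeneracy (synonymous family) structure that every codon-bias statistic in
#' this package relies on: 9 two-fold, 1 three-fold (Ile), 5 four-fold and 3
#' six-fold (Leu, Ser, Arg) sense families, the two singleton amino acids
#' (Met, Trp), and the 3 stop codons.
#'
#' @param id Genetic code identifier. Only `"standard"` is currently shipped.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   \describe{
#'     \item{codons}{character(64), all codons in fixed T/C/A/G-free
#'       alphabetical order (AAA..TTT).}
#'     \item{aa}{named character(64), one-letter amino acid per codon
#'       (`"*"` for stops).}
#'     \item{degeneracy}{named integer(64), family size of each sense codon
#'       (NA for stops).}
#'     \item{sense_codons}{character(61), codons excluding stops.}
#'     \item{syn_codons}{character(59), sense codons excluding Met and Trp —
#'       the span over which RSCU, CAI_59, SCS and GC3s are defined.}
#'     \item{stop_codons}{character(3).}
#'     \item{families}{named list, amino acid -> codons.}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$degeneracy[["CTG"]]  # leucine, six-fold
#' @export
genetic_code <- function(id = "standard") {
  id <- match.arg(id)
  map <- Biostrings::GENETIC_CODE
  codons <- sort(names(map))
  aa <- map[codons]
  fam <- split(codons, aa)
  deg <- vapply(codons, function(cd) length(fam[[aa[[cd]]]]), integer(1))
  deg[aa == "*"] <- NA_integer_
  sense <- codons[aa != "*"]
  syn <- sense[!aa[sense] %in% c("M", "W")]
  obj <- list(
    id = id,
    codons = codons,
    aa = aa,
    degeneracy = deg,
    sense_codons = sense,
    syn_codons = syn,
    stop_codons = codons[aa == "*"],
    families = fam[setdiff(names(fam), "*")]
  )
  class(obj) <- "genetic_code"
  obj
}

#' @export
print.genetic_code <- function(x, ...) {
  cls <- table(x$degeneracy[x$syn_codons])
  cat("Genetic code:", x$id, "\n")
  cat(" ", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stops\n")
  cat("  family sizes over the 59 synonymously variable codons:\n")
  print(cls)
  invisible(x)
}

#' Degeneracy class of each amino-acid family
#'
#' Amino acids are grouped by total synonymous family size (Leu/Ser/Arg are
#' six-fold even though their codons sit in two codon blocks), the grouping
#' used by Wright's ENc and by the rare-codon degeneracy panels.
#'
#' @param code A [genetic_code()] object.
#' @return Named integer vector: amino acid (one-letter) -> family size, for
#'   the 18 multi-codon amino acids plus Met and Trp (size 1).
#' @export
aa_degeneracy <- function(code = genetic_code()) {
  vapply(code$families, length, integer(1))
}

# internal: third-position base of each codon
third_base <- function(codons) substr(codons, 3L, 3L)
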