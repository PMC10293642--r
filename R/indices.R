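#' Codon count table
#'
#' Counts of all 64 codons for one transcript, several transcripts pooled, or
#' a raw codon vector.
#'
#' @param x A [cds_record()], a list of them, or a codon character vector.
#' @return Named integer vector of length 64 (fixed alphabetical codon order).
#' @export
codon_counts <- function(x) {
  code <- genetic_code()
  cods <- if (inherits(x, "cds_record")) {
    split_codons(x)
  } else if (is.list(x)) {
    unlist(lapply(x, split_codons), use.names = FALSE)
  } else {
    toupper(x)
  }
  cnt <- table(factor(cods, levels = code$codons))
  out <- as.integer(cnt)
  names(out) <- code$codons
  out
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its observed count divided by the count expected if all
#' codons of its synonymous family were used equally:
#' `RSCU(c) = obs(c) / (family_total / degeneracy)`. Values sum to the family
#' degeneracy within each family; 1 means unbiased use. Met, Trp and stop
#' codons are excluded (59-codon convention); families with zero usage get
#' RSCU 0 for every member and are flagged.
#'
#' @param counts Codon counts from [codon_counts()].
#' @param code A [genetic_code()].
#' @return Object of class `rscu`: numeric vector of 59 RSCU values with
#'   attribute `zero_families` (amino acids with no observed codon).
#' @export
rscu <- function(counts, code = genetic_code()) {
  vals <- numeric(length(code$syn_codons))
  names(vals) <- code$syn_codons
  zero <- character(0)
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (aa %in% c("M", "W")) next
    tot <- sum(counts[fam])
    if (tot == 0) {
      vals[fam] <- 0
      zero <- c(zero, aa)
    } else {
      vals[fam] <- counts[fam] / (tot / length(fam))
    }
  }
  structure(vals, zero_families = zero, class = c("rscu", "numeric"))
}

#' @export
print.rscu <- function(x, ...) {
  cat("<rscu: 59 synonymous codons>\n")
  print(round(unclass(x), 3))
  zf <- attr(x, "zero_families")
  if (length(zf)) cat("zero-usage families:", paste(zf, collapse = ","), "\n")
  invisible(x)
}

#' Classify codons by RSCU value
#'
#' Overrepresented above 1.6, underrepresented below 0.6, random use in
#' between (inclusive bounds).
#'
#' @param v An [rscu()] vector (or plain numeric RSCU values).
#' @param over,under Thresholds (defaults 1.6 and 0.6).
#' @return Named character vector: `"overrepresented"`, `"random"` or
#'   `"underrepresented"`.
#' @export
classify_rscu <- function(v, over = 1.6, under = 0.6) {
  x <- unclass(v)
  out <- ifelse(x > over, "overrepresented",
                ifelse(x < under, "underrepresented", "random"))
  names(out) <- names(x)
  out
}

#' Reference relative-adaptiveness weights for CAI
#'
#' Builds per-codon relative adaptiveness `w = count / max(count in family)`
#' from a reference codon-usage table, so the most used codon of each family
#' has `w = 1`. Reference codons with zero count are assigned
#' `0.5 / max(count in family)` before normalisation so the geometric mean
#' stays finite. The packaged default is an aggregate human codon-usage
#' table (GenBank-derived per-thousand frequencies); any reference can be
#' substituted from a two-column TSV (`codon`, `weight`) or (`codon`,
#' `count`).
#'
#' @param x `"human"` for the packaged default, a path to a TSV, or a named
#'   numeric vector of counts/weights over the 64 (or 59) codons.
#' @param code A [genetic_code()].
#' @return Object of class `cai_weights`: named numeric vector of w values
#'   over the 59 synonymous codons, with a `provenance` attribute; every
#'   family has at least one codon with w = 1.
#' @export
cai_weights <- function(x = "human", code = genetic_code()) {
  if (is.character(x) && length(x) == 1L && x == "human") {
    counts <- human_codon_usage()
    prov <- "human aggregate codon usage (GenBank-derived, per-thousand)"
  } else if (is.character(x) && length(x) == 1L) {
    tab <- utils::read.delim(x, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("weights TSV needs two columns (codon, value)")
    counts <- stats::setNames(as.numeric(tab[[2]]), toupper(tab[[1]]))
    if (any(is.na(counts))) stop("non-numeric value in weights file")
    prov <- paste0("file:", x)
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- x
    names(counts) <- toupper(names(counts))
    prov <- "user-supplied vector"
  } else {
    stop("x must be \"human\", a TSV path, or a named numeric vector")
  }
  missing <- setdiff(code$syn_codons, names(counts))
  if (length(missing))
    stop("reference lacks codons: ", paste(missing, collapse = ","))
  if (any(counts < 0)) stop("negative reference values")
  w <- numeric(length(code$syn_codons))
  names(w) <- code$syn_codons
  for (aa in setdiff(names(code$families), c("M", "W"))) {
    fam <- code$families[[aa]]
    cnt <- counts[fam]
    mx <- max(cnt)
    if (mx == 0) stop("reference family ", aa, " has zero total usage")
    cnt[cnt == 0] <- 0.5 / mx
    w[fam] <- cnt / mx
  }
  structure(w, provenance = prov, class = c("cai_weights", "numeric"))
}

#' Codon adaptation index
#'
#' Geometric mean of reference relative-adaptiveness weights over all codon
#' occurrences of a gene, restricted to the 59 synonymous codons (Met, Trp
#' and stops excluded — the CAI_59 convention). 1 means the gene uses only
#' the reference set's preferred codons; values near 1 predict high
#' expression on the reference's terms.
#'
#' @param counts Codon counts from [codon_counts()].
#' @param ref A [cai_weights()] object (default: packaged human reference).
#' @param code A [genetic_code()].
#' @return CAI value in (0, 1].
#' @export
cai <- function(counts, ref = cai_weights(), code = genetic_code()) {
  idx <- code$syn_codons
  n <- counts[idx]
  if (sum(n) == 0) stop("no eligible codons for CAI")
  w <- unclass(ref)[idx]
  exp(sum(n * log(w)) / sum(n))
}

#' Wright's effective number of codons (ENc)
#'
#' Nondirectional codon-bias measure ranging from 20 (one codon per family
#' used exclusively) to 61 (perfectly even synonymous usage). Per family the
#' codon homozygosity is `F = (n * sum(p^2) - 1) / (n - 1)` with `n` the
#' family total and `p` the within-family codon frequencies; F is averaged
#' within each degeneracy class and
#' `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
#'
#' Families with `n < 2` or a non-positive F estimate are imputed from the
#' mean of the defined families of the same class; if an entire class is
#' missing, the three-fold class (Ile only) falls back to the average of the
#' two- and four-fold means and other missing classes to the mean of defined
#' classes, and the result is flagged.
#'
#' @param counts Codon counts from [codon_counts()].
#' @param code A [genetic_code()].
#' @return ENc value, clamped to at most 61, with attribute `imputed_classes`
#'   naming any degeneracy class that needed a fallback.
#' @export
enc <- function(counts, code = genetic_code()) {
  fam_deg <- aa_degeneracy(code)
  classes <- c(2, 3, 4, 6)
  f_by_class <- stats::setNames(vector("list", 4), as.character(classes))
  for (aa in names(code$families)) {
    k <- fam_deg[[aa]]
    if (k < 2) next
    fam <- code$families[[aa]]
    n <- sum(counts[fam])
    if (n < 2) { f <- NA_real_ } else {
      p <- counts[fam] / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f <= 0) f <- NA_real_
    }
    f_by_class[[as.character(k)]] <- c(f_by_class[[as.character(k)]], f)
  }
  fbar <- vapply(f_by_class, function(fs) mean(fs, na.rm = TRUE), numeric(1))
  # within-class imputation happened via na.rm; whole-class fallbacks:
  imputed <- character(0)
  if (is.nan(fbar[["3"]]) && !is.nan(fbar[["2"]]) && !is.nan(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
    imputed <- c(imputed, "3")
  }
  if (any(is.nan(fbar))) {
    ok <- fbar[!is.nan(fbar)]
    if (length(ok) == 0) stop("no synonymous family has enough codons for ENc")
    miss <- names(fbar)[is.nan(fbar)]
    fbar[miss] <- mean(ok)
    imputed <- c(imputed, miss)
  }
  val <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  val <- min(val, 61)
  attr(val, "imputed_classes") <- imputed
  val
}

#' Expected ENc under composition alone
#'
#' The null ENc of a gene whose only source of codon bias is its synonymous
#' GC content at third positions: `2 + s + 29 / (s^2 + (1 - s)^2)`, the
#' solid curve of an ENc-GC3 plot. Observed points on or near the curve are
#' compatible with composition/mutation pressure; points well below indicate
#' selection among synonymous codons.
#'
#' @param s GC3s fraction in \[0, 1\] (vectorised).
#' @return Expected ENc value(s).
#' @export
enc_expected <- function(s) {
  if (any(s < 0 | s > 1)) stop("GC3s must be within [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Classify a gene on the ENc-GC3 plane
#'
#' @param enc_obs Observed ENc.
#' @param s GC3s fraction.
#' @param tol_on,tol_near Absolute ENc distances bounding the `on_curve` and
#'   `near_curve` bands (defaults 1 and 2).
#' @return One of `"on_curve"`, `"near_curve"`, `"below_curve"`,
#'   `"above_curve"`.
#' @export
enc_gc3_classify <- function(enc_obs, s, tol_on = 1, tol_near = 2) {
  d <- enc_obs - enc_expected(s)
  if (abs(d) <= tol_on) return("on_curve")
  if (abs(d) <= tol_near) return("near_curve")
  if (d < 0) "below_curve" else "above_curve"
}

#' Scaled chi-square codon bias
#'
#' Chi-square of observed synonymous codon usage against equal within-family
#' usage, summed over the multi-codon families (Met and Trp excluded) and
#' scaled by the total eligible codon count:
#' `SCS = sum_f sum_c (obs - exp)^2 / exp / N` with `exp = family_total /
#' degeneracy`. Zero under exactly equal usage; larger means more biased.
#'
#' @param counts Codon counts from [codon_counts()].
#' @param code A [genetic_code()].
#' @return SCS value (>= 0).
#' @export
scaled_chi_square <- function(counts, code = genetic_code()) {
  chi <- 0
  n_tot <- 0
  for (aa in setdiff(names(code$families), c("M", "W"))) {
    fam <- code$families[[aa]]
    tot <- sum(counts[fam])
    if (tot == 0) next
    e <- tot / length(fam)
    chi <- chi + sum((counts[fam] - e)^2 / e)
    n_tot <- n_tot + tot
  }
  if (n_tot == 0) stop("no eligible codons for SCS")
  chi / n_tot
}

# Kyte-Doolittle hydropathy scale
.kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
         E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
         M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
         Y = -1.3, V = 4.2)

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over a protein; positive values indicate a
#' hydrophobic protein, negative a hydrophilic one.
#'
#' @param protein One-letter amino-acid string (no stops).
#' @return GRAVY value.
#' @export
gravy <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) == 0L) stop("empty protein")
  unknown <- setdiff(aa, names(.kd))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ","))
  mean(.kd[aa])
}

#' Aromaticity (AROMA)
#'
#' Fraction of aromatic residues (Phe, Tyr, Trp) in a protein.
#'
#' @param protein One-letter amino-acid string.
#' @return Fraction in \[0, 1\].
#' @export
aroma <- function(protein) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (length(aa) == 0L) stop("empty protein")
  sum(aa %in% c("F", "Y", "W")) / length(aa)
}

#' Parity-rule-2 coordinates
#'
#' Within-strand parity (PR2) predicts A = T and G = C at third codon
#' positions in the absence of strand-specific mutation or selection
#' pressure. Coordinates are `x = G3 / (G3 + C3)` and `y = A3 / (A3 + T3)`
#' over third positions of sense codons (stops excluded); (0.5, 0.5) is the
#' no-bias centre. An optional classical mode restricts the span to
#' four-fold-degenerate families only.
#'
#' @param codons Codon character vector.
#' @param code A [genetic_code()].
#' @param fourfold_only Use only codons of four-fold families
#'   (default FALSE: all sense codons).
#' @return Named numeric vector `c(x, y)`; a coordinate whose denominator is
#'   zero is NA.
#' @export
pr2 <- function(codons, code = genetic_code(), fourfold_only = FALSE) {
  cods <- codons[codons %in% code$sense_codons]
  if (fourfold_only) {
    four <- names(which(aa_degeneracy(code) == 4))
    cods <- cods[code$aa[cods] %in% four]
  }
  if (length(cods) == 0L) stop("no eligible codons for PR2")
  tb <- third_base(cods)
  a3 <- sum(tb == "A"); t3 <- sum(tb == "T")
  g3 <- sum(tb == "G"); c3 <- sum(tb == "C")
  c(x = if (g3 + c3 > 0) g3 / (g3 + c3) else NA_real_,
    y = if (a3 + t3 > 0) a3 / (a3 + t3) else NA_real_)
}

#' Per-transcript usage profile
#'
#' Computes the full per-transcript metric bundle: composition, RSCU, CAI,
#' ENc, SCS, GRAVY, AROMA and PR2 coordinates.
#'
#' @param record A validated [cds_record()].
#' @param ref A [cai_weights()] reference.
#' @param code A [genetic_code()].
#' @param include_stop Composition span flag (see [base_composition()]).
#' @return A list of class `usage_profile` with elements `transcript_id`,
#'   `gene`, `n_codons`, `composition`, `rscu`, `cai`, `enc`, `scs`,
#'   `gravy`, `aroma`, `pr2`, `gc3s`.
#' @export
usage_profile <- function(record, ref = cai_weights(), code = genetic_code(),
                          include_stop = TRUE) {
  cods <- split_codons(record)
  cnt <- codon_counts(record)
  comp <- composition_profile(record, include_stop, code)
  prot <- translate_cds(record, code)
  structure(list(
    transcript_id = record$transcript_id,
    gene = record$gene,
    n_codons = length(cods),
    composition = comp,
    rscu = rscu(cnt, code),
    cai = cai(cnt, ref, code),
    enc = as.numeric(enc(cnt, code)),
    scs = scaled_chi_square(cnt, code),
    gravy = gravy(prot),
    aroma = aroma(prot),
    pr2 = pr2(cods, code),
    gc3s = comp[["GC3s"]]
  ), class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile %s [%s]>\n", x$transcript_id, x$gene))
  cat(sprintf("  %d codons | CAI %.3f | ENc %.2f | SCS %.4f | GC3s %.3f\n",
              x$n_codons, x$cai, x$enc, x$scs, x$gc3s))
  cat(sprintf("  GRAVY %.3f | AROMA %.3f | PR2 (%.3f, %.3f)\n",
              x$gravy, x$aroma, x$pr2[["x"]], x$pr2[["y"]]))
  invisible(x)
}
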