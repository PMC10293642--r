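# Approximate human protein amino-acid frequencies, used as the default
# amino-acid stream of the generator.
.aa_freq_human <- c(A = 7.0, R = 5.6, N = 3.6, D = 4.7, C = 2.3, Q = 4.8,
                    E = 7.1, G = 6.6, H = 2.6, I = 4.3, L = 9.9, K = 5.7,
                    M = 2.1, F = 3.6, P = 6.3, S = 8.3, T = 5.3, W = 1.2,
                    Y = 2.7, V = 6.0)

# deterministic 31-bit substream seed from (master, gene idx, transcript idx):
# adding a transcript or a gene never perturbs the streams of existing ones.
.substream_seed <- function(master, g, t) {
  as.integer((master %% 100000) * 20011 + g * 131071 + t * 8191) %% 2147483647L
}

#' Specification for the synthetic coding-sequence generator
#'
#' Defines gene-set structure (transcripts per gene, nucleotide length
#' range) and the codon-sampling model: an amino-acid composition, per-family
#' synonymous codon weights (explicit, Dirichlet-drawn, or uniform), an
#' optional GC3 skew that multiplies the weight of G/C-ending codons, stop
#' codon weights, optional forced codon-pair motifs, and a master seed that
#' fixes every output bit.
#'
#' @param genes Named list; each element a list with `n` (transcript count)
#'   and optional `length_nt = c(min, max)` (defaults to the global range),
#'   `syn_weights`, `gc3` overriding the global settings for that gene.
#' @param length_nt Global transcript length range in nucleotides; lengths
#'   are drawn uniformly and rounded to a multiple of 3 within the range.
#' @param aa_weights Named amino-acid sampling weights (default: approximate
#'   human protein composition).
#' @param syn_weights Named list amino acid -> named codon weight vector.
#'   Families not listed use uniform weights. Ignored for families drawn by
#'   `dirichlet_alpha`.
#' @param dirichlet_alpha If non-NULL, synonymous weights for every family
#'   are drawn once (at spec construction, from the master seed) from a
#'   symmetric Dirichlet with this concentration; small alpha = strong skew.
#' @param gc3 Optional target-ish GC3 skew in (0, 1): codon weights of
#'   G/C-ending codons are multiplied by `gc3 / (1 - gc3)`; 0.5 is neutral.
#' @param stop_weights Named weights over TAA/TAG/TGA for the terminal stop.
#' @param pair_motifs Optional list of lists `list(pair = c("GAG","GAG"),
#'   times = k)`: each motif is written over k random internal positions of
#'   every transcript, creating planted codon-pair context.
#' @param seed Master seed (integer).
#' @return Object of class `generator_spec` with resolved per-gene weights.
#' @export
generator_spec <- function(genes,
                           length_nt = c(846, 2313),
                           aa_weights = NULL,
                           syn_weights = NULL,
                           dirichlet_alpha = NULL,
                           gc3 = NULL,
                           stop_weights = c(TAA = 0.3, TAG = 0.24, TGA = 0.46),
                           pair_motifs = NULL,
                           seed = 1L) {
  stopifnot(is.list(genes), length(names(genes)) == length(genes))
  code <- genetic_code()
  if (is.null(aa_weights)) aa_weights <- .aa_freq_human
  if (any(aa_weights < 0)) stop("negative amino-acid weights")
  aa_weights <- aa_weights / sum(aa_weights)

  base_weights <- lapply(code$families, function(fam)
    stats::setNames(rep(1, length(fam)), fam))
  if (!is.null(dirichlet_alpha)) {
    set.seed(.substream_seed(seed, 0L, 0L))
    base_weights <- lapply(base_weights, function(w) {
      g <- stats::rgamma(length(w), shape = dirichlet_alpha)
      stats::setNames(g / sum(g), names(w))
    })
  }
  if (!is.null(syn_weights)) {
    for (aa in names(syn_weights)) {
      w <- syn_weights[[aa]]
      fam <- code$families[[aa]]
      if (is.null(fam)) stop("unknown amino acid: ", aa)
      if (!all(names(w) %in% fam))
        stop("weights for ", aa, " name codons outside its family")
      full <- stats::setNames(rep(0, length(fam)), fam)
      full[names(w)] <- w
      if (all(full == 0)) stop("all-zero weights for family ", aa)
      base_weights[[aa]] <- full
    }
  }
  apply_gc3 <- function(wl, gc3v) {
    if (is.null(gc3v)) return(wl)
    if (gc3v <= 0 || gc3v >= 1) stop("gc3 must be in (0, 1)")
    odds <- gc3v / (1 - gc3v)
    lapply(wl, function(w) {
      gcend <- third_base(names(w)) %in% c("G", "C")
      w[gcend] <- w[gcend] * odds
      if (all(w == 0)) stop("gc3 skew zeroed a family") else w
    })
  }
  gene_weights <- list()
  for (g in names(genes)) {
    wl <- base_weights
    if (!is.null(genes[[g]]$syn_weights)) {
      for (aa in names(genes[[g]]$syn_weights)) {
        fam <- code$families[[aa]]
        w <- genes[[g]]$syn_weights[[aa]]
        full <- stats::setNames(rep(0, length(fam)), fam)
        full[names(w)] <- w
        wl[[aa]] <- full
      }
    }
    gcv <- if (!is.null(genes[[g]]$gc3)) genes[[g]]$gc3 else gc3
    wl <- apply_gc3(wl, gcv)
    gene_weights[[g]] <- lapply(wl, function(w) w / sum(w))
  }
  if (any(stop_weights < 0) || sum(stop_weights) == 0)
    stop("invalid stop weights")
  structure(list(genes = genes, length_nt = length_nt,
                 aa_weights = aa_weights, gene_weights = gene_weights,
                 stop_weights = stop_weights / sum(stop_weights),
                 pair_motifs = pair_motifs, seed = as.integer(seed)),
            class = "generator_spec")
}

#' Table-1-like generator preset
#'
#' A four-gene set mirroring the structure of the study design this package
#' targets: genes with 11, 1, 4 and 6 transcripts and nucleotide lengths in
#' \[846, 2313\].
#'
#' @param seed Master seed.
#' @param ... Passed on to [generator_spec()] (e.g. `gc3`,
#'   `dirichlet_alpha`).
#' @return A `generator_spec`.
#' @export
table1_like_spec <- function(seed = 1L, ...) {
  generator_spec(
    genes = list(GENE_A = list(n = 11L), GENE_B = list(n = 1L),
                 GENE_C = list(n = 4L), GENE_D = list(n = 6L)),
    length_nt = c(846, 2313), seed = seed, ...
  )
}

#' Generate one synthetic coding sequence
#'
#' Draws a transcript for `gene` under the spec's sampling model: ATG start,
#' body codons drawn amino-acid-first then synonymous-weight within family,
#' a single terminal stop, length divisible by 3, no internal stop (stop
#' codons are never in any family's weight support). Output is a function of
#' (spec seed, gene index, transcript index) only.
#'
#' @param spec A [generator_spec()].
#' @param gene Gene label (must be in `spec$genes`).
#' @param transcript_index Which transcript of the gene to generate
#'   (1-based; determines the substream).
#' @return A validated [cds_record()].
#' @export
generate_cds <- function(spec, gene, transcript_index = 1L) {
  gidx <- match(gene, names(spec$genes))
  if (is.na(gidx)) stop("unknown gene: ", gene)
  set.seed(.substream_seed(spec$seed, gidx, transcript_index))
  gcfg <- spec$genes[[gene]]
  rng <- if (!is.null(gcfg$length_nt)) gcfg$length_nt else spec$length_nt
  len_nt <- 3L * as.integer(round(stats::runif(1, rng[1], rng[2]) / 3))
  len_nt <- min(max(len_nt, 3L * (ceiling(rng[1] / 3))), 3L * floor(rng[2] / 3))
  k <- len_nt %/% 3L  # codons incl. start and stop
  if (k < 2L) stop("infeasible length range")
  wl <- spec$gene_weights[[gene]]
  n_body <- k - 2L
  aas <- sample(names(spec$aa_weights), n_body, replace = TRUE,
                prob = spec$aa_weights)
  body <- character(n_body)
  for (aa in unique(aas)) {
    i <- which(aas == aa)
    w <- wl[[aa]]
    body[i] <- if (length(w) == 1L) names(w)
               else sample(names(w), length(i), replace = TRUE, prob = w)
  }
  stop_cod <- sample(names(spec$stop_weights), 1L, prob = spec$stop_weights)
  cods <- c("ATG", unname(body), stop_cod)
  if (!is.null(spec$pair_motifs) && n_body >= 4L) {
    for (mf in spec$pair_motifs) {
      times <- if (is.null(mf$times)) 1L else mf$times
      # internal slots only: positions 2..k-2 for the 5' member
      pos <- sample(seq(2L, k - 2L), min(times, k - 3L))
      for (p in pos) {
        cods[p] <- mf$pair[1]
        cods[p + 1L] <- mf$pair[2]
      }
    }
  }
  cds_record(sprintf("%s_t%02d", gene, transcript_index), gene,
             paste(cods, collapse = ""))
}

#' Generate a full synthetic gene set
#'
#' @param spec A [generator_spec()].
#' @return A [gene_set()] whose every record passes [validate_cds()]
#'   (pair-motif injection can introduce internal stops only if a motif
#'   contains one, which is rejected).
#' @export
generate_gene_set <- function(spec) {
  if (!is.null(spec$pair_motifs)) {
    for (mf in spec$pair_motifs)
      if (any(mf$pair %in% genetic_code()$stop_codons))
        stop("pair motifs may not contain stop codons")
  }
  records <- list()
  for (g in names(spec$genes)) {
    n <- spec$genes[[g]]$n
    if (is.null(n) || n < 1L) stop("gene ", g, " needs n >= 1 transcripts")
    for (t in seq_len(n))
      records[[length(records) + 1L]] <- generate_cds(spec, g, t)
  }
  gene_set(records)
}

#' Analytic expectations implied by a generator spec
#'
#' The truth table against which parameter-recovery tests compare observed
#' statistics: for each gene, the expected RSCU of every synonymous codon
#' (`degeneracy * w / sum(family w)`), the preferred (max-weight) codon per
#' family, and the expected GC3s implied by the amino-acid and codon
#' weights. Pair-motif injection is ignored (it perturbs a vanishing
#' fraction of codons at realistic lengths).
#'
#' @param spec A [generator_spec()].
#' @return Named list per gene: `rscu` (named numeric over 59 codons),
#'   `preferred` (named character per amino acid), `gc3s` (numeric).
#' @export
known_truth <- function(spec) {
  code <- genetic_code()
  out <- list()
  for (g in names(spec$genes)) {
    wl <- spec$gene_weights[[g]]
    ex <- numeric(0)
    pref <- character(0)
    num_gc <- 0; den <- 0
    for (aa in names(wl)) {
      w <- wl[[aa]] / sum(wl[[aa]])
      if (!aa %in% c("M", "W")) {
        ex <- c(ex, stats::setNames(length(w) * w, names(w)))
        p_aa <- spec$aa_weights[[aa]]
        num_gc <- num_gc +
          p_aa * sum(w[third_base(names(w)) %in% c("G", "C")])
        den <- den + p_aa
      }
      pref[aa] <- names(w)[which.max(w)]
    }
    out[[g]] <- list(rscu = ex[code$syn_codons], preferred = pref,
                     gc3s = num_gc / den)
  }
  out
}
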