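#' Transcript-by-codon RSCU matrix
#'
#' One row per transcript, one column per synonymous codon (fixed order of
#' the 59 codons), the input for RSCU-based ordination.
#'
#' @param gs A [gene_set()], or a list of [cds_record()]s.
#' @param genes Optional character vector restricting to a subset of genes.
#' @param code A [genetic_code()].
#' @return Numeric matrix (transcripts x 59) with transcript ids as row
#'   names and attribute `gene` (gene label per row).
#' @export
rscu_matrix <- function(gs, genes = NULL, code = genetic_code()) {
  recs <- if (inherits(gs, "gene_set")) {
    if (!is.null(genes)) {
      miss <- setdiff(genes, names(gs))
      if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ","))
      gs <- gs[genes]
    }
    unlist(unname(gs), recursive = FALSE)
  } else gs
  if (length(recs) < 2L) stop("need at least 2 transcripts")
  m <- t(vapply(recs, function(r)
    unclass(rscu(codon_counts(r), code)), numeric(length(code$syn_codons))))
  rownames(m) <- vapply(recs, `[[`, character(1), "transcript_id")
  colnames(m) <- code$syn_codons
  attr(m, "gene") <- vapply(recs, `[[`, character(1), "gene")
  m
}

#' Principal component analysis of an RSCU matrix
#'
#' Deterministic SVD-based PCA. Columns are centred by default and left
#' unscaled (RSCU is already normalised within each family); a correlation
#' (scaled) mode is available. Axis signs follow a fixed convention — the
#' codon with the largest absolute loading on each axis has a positive
#' loading — so results are reproducible across linear-algebra backends.
#'
#' @param m Matrix from [rscu_matrix()] (entities x variables).
#' @param center,scale. Passed to [stats::prcomp()]; zero-variance columns
#'   are dropped before a scaled PCA.
#' @return Object of class `rscu_pca`: list with `scores` (entities x axes),
#'   `loadings` (variables x axes), `inertia` (percent explained per axis,
#'   non-increasing), `center`, `sdev`.
#' @export
rscu_pca <- function(m, center = TRUE, scale. = FALSE) {
  if (nrow(m) < 2L) stop("need at least 2 rows")
  keep <- colnames(m)
  if (scale.) {
    v <- apply(m, 2, stats::var)
    keep <- colnames(m)[v > 0]
    if (length(keep) < 2L) stop("matrix has (near) constant columns only")
    m <- m[, keep, drop = FALSE]
  } else if (all(apply(m, 2, stats::var) == 0)) {
    stop("constant matrix: no variance to decompose")
  }
  p <- stats::prcomp(m, center = center, scale. = scale.)
  scores <- p$x
  loadings <- p$rotation
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  inertia <- 100 * p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 inertia = inertia[seq_len(ncol(scores))],
                 center = p$center, sdev = p$sdev,
                 gene = attr(m, "gene")),
            class = "rscu_pca")
}

#' @export
print.rscu_pca <- function(x, ...) {
  cat("<rscu_pca:", nrow(x$scores), "entities,",
      nrow(x$loadings), "codons>\n")
  k <- min(4, length(x$inertia))
  cat("  inertia (%):",
      paste(sprintf("axis%d=%.2f", seq_len(k), x$inertia[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Most influential codons on a PCA axis
#'
#' @param result An [rscu_pca()] object.
#' @param axis Axis index (1-based).
#' @param k Number of codons (default 5; capped at the number available).
#' @return Data frame `codon`, `loading`, ranked by |loading| descending.
#' @export
top_loadings <- function(result, axis = 1L, k = 5L) {
  if (axis < 1L || axis > ncol(result$loadings))
    stop("axis out of range")
  l <- result$loadings[, axis]
  ord <- order(-abs(l), names(l))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(codon = names(l)[ord], loading = unname(l[ord]),
             stringsAsFactors = FALSE)
}

#' Correlation with significance label
#'
#' Two-tailed correlation test with the conventional star labels:
#' NS (p >= 0.05), `*` (p < 0.05), `**` (p < 0.01), `***` (p < 0.001).
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List of class `cor_report`: `r`, `p`, `label`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  p <- ct$p.value
  label <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "NS"
  structure(list(r = unname(ct$estimate), p = p, label = label,
                 method = method, n = length(x)),
            class = "cor_report")
}

#' @export
print.cor_report <- function(x, ...) {
  cat(sprintf("r = %.3f, p = %.4g (%s, %s, n = %d)\n",
              x$r, x$p, x$label, x$method, x$n))
  invisible(x)
}

#' Length-versus-feature correlation table
#'
#' Correlates transcript length (nt) with each per-transcript feature
#' (composition, positional composition, CAI, SCS, GRAVY, AROMA, and PCA
#' axis scores when supplied), reproducing the shape of published
#' length-correlation tables.
#'
#' @param profiles List of [usage_profile()]s (one transcript group).
#' @param pca Optional [rscu_pca()] with rows matching the profiles, whose
#'   first two axis scores are included as `PC1`, `PC2`.
#' @param method Correlation method, see [correlate()].
#' @return Data frame: `variable`, `r`, `p`, `label`.
#' @export
length_correlations <- function(profiles, pca = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  len <- vapply(profiles, function(p) 3 * p$n_codons, numeric(1))
  feats <- list(
    pct_A = vapply(profiles, function(p) p$composition[["A"]], numeric(1)),
    pct_C = vapply(profiles, function(p) p$composition[["C"]], numeric(1)),
    pct_T = vapply(profiles, function(p) p$composition[["T"]], numeric(1)),
    pct_G = vapply(profiles, function(p) p$composition[["G"]], numeric(1)),
    pct_A3 = vapply(profiles, function(p) p$composition[["A3"]], numeric(1)),
    pct_C3 = vapply(profiles, function(p) p$composition[["C3"]], numeric(1)),
    pct_T3 = vapply(profiles, function(p) p$composition[["T3"]], numeric(1)),
    pct_G3 = vapply(profiles, function(p) p$composition[["G3"]], numeric(1)),
    pct_GC = vapply(profiles, function(p) p$composition[["GC"]], numeric(1)),
    pct_GC1 = vapply(profiles, function(p) p$composition[["GC1"]], numeric(1)),
    pct_GC2 = vapply(profiles, function(p) p$composition[["GC2"]], numeric(1)),
    pct_GC3 = vapply(profiles, function(p) p$composition[["GC3"]], numeric(1)),
    CAI = vapply(profiles, `[[`, numeric(1), "cai"),
    SCS = vapply(profiles, `[[`, numeric(1), "scs"),
    GRAVY = vapply(profiles, `[[`, numeric(1), "gravy"),
    AROMA = vapply(profiles, `[[`, numeric(1), "aroma")
  )
  if (!is.null(pca)) {
    feats$PC1 <- pca$scores[, 1]
    if (ncol(pca$scores) >= 2) feats$PC2 <- pca$scores[, 2]
  }
  rows <- lapply(names(feats), function(v) {
    res <- tryCatch(correlate(len, feats[[v]], method),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(variable = v, r = NA_real_, p = NA_real_, label = "NA",
                 stringsAsFactors = FALSE)
    else
      data.frame(variable = v, r = res$r, p = res$p, label = res$label,
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
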