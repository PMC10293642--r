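#' Run configuration for a full codon-usage report
#'
#' Collects every tunable of the analysis pipeline. Thresholds default to
#' the conventional values used throughout this package: RSCU
#' over/under-representation at 1.6/0.6, rare codons below 0.5%, codon-pair
#' context significance at adjusted residual +/-5, ENc-GC3 curve bands of
#' 1 and 2 ENc units.
#'
#' @param manifest Path to a gene-set manifest TSV (see [read_gene_set()]),
#'   or NULL when a `gene_set` is passed straight to
#'   [codon_usage_report()].
#' @param output_dir Directory for the TSV/JSON outputs.
#' @param reference `"human"` or a reference-weights TSV path (see
#'   [cai_weights()]).
#' @param rscu_over,rscu_under,rare_threshold,context_band,enc_tol_on,enc_tol_near
#'   Analysis thresholds.
#' @param include_stop Include the terminal stop codon in composition and
#'   codon-percentage denominators (default TRUE).
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param pca_scale Use correlation (scaled) PCA instead of covariance PCA.
#' @param top_k Pairs reported in the top-pair table.
#' @param seed Seed recorded in the summary (the pipeline itself is
#'   deterministic; the seed matters when the input set is generated).
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(manifest = NULL, output_dir = tempfile("codonkit_"),
                       reference = "human",
                       rscu_over = 1.6, rscu_under = 0.6,
                       rare_threshold = 0.5, context_band = 5,
                       enc_tol_on = 1, enc_tol_near = 2,
                       include_stop = TRUE,
                       correlation_method = "pearson",
                       pca_scale = FALSE, top_k = 15L, seed = 1L) {
  thr <- c(rscu_over, rscu_under, rare_threshold, context_band,
           enc_tol_on, enc_tol_near)
  if (any(thr <= 0)) stop("all thresholds must be positive")
  structure(list(manifest = manifest, output_dir = output_dir,
                 reference = reference, rscu_over = rscu_over,
                 rscu_under = rscu_under, rare_threshold = rare_threshold,
                 context_band = context_band, enc_tol_on = enc_tol_on,
                 enc_tol_near = enc_tol_near, include_stop = include_stop,
                 correlation_method = correlation_method,
                 pca_scale = pca_scale, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Field names match the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  do.call(run_config, yaml::read_yaml(path))
}

# fixed-format TSV writer: full precision via format(..., digits = 15),
# byte-stable across runs
.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num))
    df[[j]] <- vapply(df[[j]], function(v)
      if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE),
      character(1))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Full per-gene codon-usage report
#'
#' Runs the whole pipeline on a gene set and writes the machine-readable
#' report files: per-transcript/per-gene composition, codon-bias indices,
#' RSCU with classification, PR2 coordinates, ENc-GC3 plot data,
#' rare-codon tables, codon-pair tables (sparse pair list with adjusted
#' scores, residuals and context classes, plus the top-k table and the
#' post-ATG start context), the RSCU PCA, transcript-length correlations,
#' and a JSON summary of the per-gene headline averages. Any stage failure
#' aborts the run and removes partial outputs. Reruns with identical input
#' and config are byte-identical.
#'
#' @param gs A [gene_set()]; if NULL, loaded from `config$manifest`.
#' @param config A [run_config()].
#' @return Object of class `codon_usage_report`: list with `profiles`,
#'   `gene_summary`, `rscu_gene`, `rare`, `pairs`, `pca`, `correlations`,
#'   `files` (paths written), `config`.
#' @export
codon_usage_report <- function(gs = NULL, config = run_config()) {
  code <- genetic_code()
  ref <- cai_weights(config$reference, code)
  if (is.null(gs)) {
    if (is.null(config$manifest)) stop("no gene set and no manifest")
    gs <- read_gene_set(config$manifest)
  }
  if (length(gs) == 0L) stop("empty gene set")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  written <- function(p) { files <<- c(files, p); p }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(files)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  profiles <- stage("profiles", {
    recs <- unlist(unname(gs), recursive = FALSE)
    lapply(recs, usage_profile, ref = ref, code = code,
           include_stop = config$include_stop)
  })
  genes_of <- vapply(profiles, `[[`, character(1), "gene")

  comp <- stage("composition", {
    rows <- lapply(profiles, function(p)
      data.frame(entity = p$transcript_id, gene = p$gene, level = "transcript",
                 t(p$composition), stringsAsFactors = FALSE))
    df <- do.call(rbind, rows)
    for (g in unique(genes_of)) {
      sub <- df[df$gene == g, -(1:3), drop = FALSE]
      df <- rbind(df, data.frame(entity = g, gene = g, level = "gene",
                                 t(colMeans(sub)), stringsAsFactors = FALSE))
    }
    .write_tsv(df, written(file.path(config$output_dir, "composition.tsv")))
    df
  })

  idx <- stage("indices", {
    df <- do.call(rbind, lapply(profiles, function(p)
      data.frame(entity = p$transcript_id, gene = p$gene, level = "transcript",
                 length_nt = 3 * p$n_codons, n_codons = p$n_codons,
                 CAI = p$cai, ENc = p$enc, SCS = p$scs, GRAVY = p$gravy,
                 AROMA = p$aroma, GC3s = p$gc3s,
                 PR2x = p$pr2[["x"]], PR2y = p$pr2[["y"]],
                 stringsAsFactors = FALSE)))
    for (g in unique(genes_of)) {
      sub <- df[df$gene == g, -(1:3), drop = FALSE]
      df <- rbind(df, data.frame(entity = g, gene = g, level = "gene",
                                 t(colMeans(sub)), stringsAsFactors = FALSE))
    }
    .write_tsv(df, written(file.path(config$output_dir, "indices.tsv")))
    df
  })

  rscu_gene <- stage("rscu", {
    rows <- list()
    for (g in names(gs)) {
      pooled <- rscu(codon_counts(gs[[g]]), code)
      cls <- classify_rscu(pooled, config$rscu_over, config$rscu_under)
      rows[[g]] <- data.frame(gene = g, codon = names(unclass(pooled)),
                              aa = unname(code$aa[names(unclass(pooled))]),
                              rscu = as.numeric(pooled), class = unname(cls),
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows); rownames(df) <- NULL
    .write_tsv(df, written(file.path(config$output_dir, "rscu.tsv")))
    df
  })

  stage("pr2", {
    df <- idx[idx$level == "transcript",
              c("entity", "gene", "PR2x", "PR2y")]
    .write_tsv(df, written(file.path(config$output_dir, "pr2.tsv")))
  })

  stage("enc_gc3", {
    df <- idx[idx$level == "transcript", c("entity", "gene", "GC3s", "ENc")]
    df$ENc_expected <- enc_expected(df$GC3s)
    df$class <- mapply(enc_gc3_classify, df$ENc, df$GC3s,
                       MoreArgs = list(tol_on = config$enc_tol_on,
                                       tol_near = config$enc_tol_near))
    .write_tsv(df, written(file.path(config$output_dir, "enc_gc3.tsv")))
  })

  rare <- stage("rare_codons", {
    tab <- rare_codon_table(gs, config$rare_threshold, config$include_stop,
                            code)
    .write_tsv(as.data.frame(tab),
               written(file.path(config$output_dir, "rare_codons.tsv")))
    .write_tsv(attr(tab, "summary"),
               written(file.path(config$output_dir, "rare_codons_summary.tsv")))
    tab
  })

  pairs <- stage("codon_pairs", {
    out <- list()
    sparse_rows <- list(); top_rows <- list(); start_rows <- list()
    for (g in names(gs)) {
      pt <- count_pairs(gs[[g]])
      res <- context_residuals(pt)
      cls <- classify_context(res, config$context_band)
      m <- unclass(pt)
      nz <- which(m > 0, arr.ind = TRUE)
      sparse_rows[[g]] <- data.frame(
        gene = g,
        codon1 = rownames(m)[nz[, 1]], codon2 = colnames(m)[nz[, 2]],
        count = m[nz],
        adjusted_score = round(adjusted_pair_score(m[nz],
                                                   attr(pt, "n_codons")), 2),
        residual = res[nz], class = cls[nz], stringsAsFactors = FALSE)
      tp <- top_pairs(pt, config$top_k)
      top_rows[[g]] <- cbind(gene = g, tp)
      sc <- start_context(gs[[g]])
      start_rows[[g]] <- cbind(gene = g, sc)
      out[[g]] <- list(table = pt, residuals = res, classes = cls,
                       top = tp, start = sc)
    }
    sp <- do.call(rbind, sparse_rows)
    sp <- sp[order(sp$gene, -sp$count, sp$codon1, sp$codon2), ]
    .write_tsv(sp, written(file.path(config$output_dir, "pairs.tsv")))
    .write_tsv(do.call(rbind, top_rows),
               written(file.path(config$output_dir, "top_pairs.tsv")))
    .write_tsv(do.call(rbind, start_rows),
               written(file.path(config$output_dir, "start_context.tsv")))
    out
  })

  pca <- stage("pca", {
    if (length(profiles) >= 2L) {
      m <- rscu_matrix(gs, code = code)
      p <- rscu_pca(m, scale. = config$pca_scale)
      sc <- data.frame(kind = "score", name = rownames(p$scores),
                       gene = p$gene,
                       axis1 = p$scores[, 1],
                       axis2 = if (ncol(p$scores) >= 2) p$scores[, 2] else NA,
                       stringsAsFactors = FALSE)
      ld <- data.frame(kind = "loading", name = rownames(p$loadings),
                       gene = NA_character_,
                       axis1 = p$loadings[, 1],
                       axis2 = if (ncol(p$loadings) >= 2) p$loadings[, 2]
                               else NA,
                       stringsAsFactors = FALSE)
      inr <- data.frame(kind = "inertia",
                        name = paste0("axis", seq_along(p$inertia)),
                        gene = NA_character_, axis1 = p$inertia, axis2 = NA,
                        stringsAsFactors = FALSE)
      .write_tsv(rbind(sc, ld, inr),
                 written(file.path(config$output_dir, "pca.tsv")))
      p
    } else NULL
  })

  correlations <- stage("correlations", {
    if (length(profiles) >= 3L) {
      ct <- length_correlations(profiles, pca,
                                method = config$correlation_method)
      .write_tsv(ct, written(file.path(config$output_dir,
                                       "correlations.tsv")))
      ct
    } else NULL
  })

  gene_summary <- stage("summary", {
    gsum <- idx[idx$level == "gene", ]
    summ <- list(
      genes = stats::setNames(lapply(seq_len(nrow(gsum)), function(i)
        as.list(gsum[i, setdiff(names(gsum), c("entity", "gene", "level"))])),
        gsum$gene),
      thresholds = list(rscu_over = config$rscu_over,
                        rscu_under = config$rscu_under,
                        rare_threshold = config$rare_threshold,
                        context_band = config$context_band),
      include_stop = config$include_stop,
      reference = attr(ref, "provenance"),
      seed = config$seed,
      n_transcripts = length(profiles)
    )
    jsonlite::write_json(summ,
                         written(file.path(config$output_dir, "summary.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    gsum
  })

  structure(list(profiles = profiles, gene_summary = gene_summary,
                 rscu_gene = rscu_gene, rare = rare, pairs = pairs,
                 pca = pca, correlations = correlations,
                 composition = comp, files = files, config = config),
            class = "codon_usage_report")
}

#' @export
print.codon_usage_report <- function(x, ...) {
  cat("<codon_usage_report:", length(x$profiles), "transcripts,",
      nrow(x$gene_summary), "genes>\n")
  cat("  outputs in", x$config$output_dir, "\n")
  invisible(x)
}

#' @export
summary.codon_usage_report <- function(object, ...) {
  cat("Per-gene averages:\n")
  print(object$gene_summary[, c("gene", "n_codons", "CAI", "ENc", "SCS",
                                "GC3s")], row.names = FALSE)
  if (!is.null(object$pca))
    cat(sprintf("PCA inertia: axis1 %.2f%%, axis2 %.2f%%\n",
                object$pca$inertia[1],
                if (length(object$pca$inertia) > 1)
                  object$pca$inertia[2] else NA))
  invisible(object)
}

#' Grouped comparison of gene sets
#'
#' Splits the genes into named groups (e.g. up- versus down-regulated),
#' and reports per group: transcript count, PR2 mean +/- SD, group-wise
#' RSCU PCA (when the group has >= 2 transcripts) and the transcript-length
#' correlation table (when >= 3).
#'
#' @param gs A [gene_set()].
#' @param groups Named list: group label -> character vector of gene labels.
#'   Every gene must appear in exactly one group; groups may not be empty.
#' @param config A [run_config()].
#' @return Named list of class `group_comparison`, one element per group
#'   with `n_transcripts`, `pr2_mean`, `pr2_sd`, `pca`, `correlations`.
#' @export
compare_groups <- function(gs, groups, config = run_config()) {
  all_assigned <- unlist(groups)
  if (any(vapply(groups, length, integer(1)) == 0L)) stop("empty group")
  if (anyDuplicated(all_assigned))
    stop("gene assigned to more than one group: ",
         paste(unique(all_assigned[duplicated(all_assigned)]), collapse = ","))
  un <- setdiff(names(gs), all_assigned)
  if (length(un)) stop("unassigned gene(s): ", paste(un, collapse = ","))
  code <- genetic_code()
  ref <- cai_weights(config$reference, code)
  out <- list()
  for (grp in names(groups)) {
    sub <- gs[groups[[grp]]]
    class(sub) <- "gene_set"
    recs <- unlist(unname(sub), recursive = FALSE)
    profiles <- lapply(recs, usage_profile, ref = ref, code = code,
                       include_stop = config$include_stop)
    pr2s <- t(vapply(profiles, `[[`, numeric(2), "pr2"))
    pca <- if (length(recs) >= 2L)
      rscu_pca(rscu_matrix(sub, code = code), scale. = config$pca_scale)
    else NULL
    cors <- if (length(recs) >= 3L)
      length_correlations(profiles, pca, method = config$correlation_method)
    else NULL
    out[[grp]] <- list(
      n_transcripts = length(recs),
      pr2_mean = colMeans(pr2s),
      pr2_sd = apply(pr2s, 2, function(v)
        if (length(v) > 1) stats::sd(v) else 0),
      pca = pca, correlations = cors)
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (grp in names(x)) {
    g <- x[[grp]]
    cat(sprintf("%s: %d transcripts | PR2 x %.3f+/-%.3f, y %.3f+/-%.3f\n",
                grp, g$n_transcripts,
                g$pr2_mean[["x"]], g$pr2_sd[["x"]],
                g$pr2_mean[["y"]], g$pr2_sd[["y"]]))
    if (!is.null(g$pca))
      cat(sprintf("  PCA inertia axis1 %.2f%% axis2 %.2f%%\n",
                  g$pca$inertia[1],
                  if (length(g$pca$inertia) > 1) g$pca$inertia[2] else NA))
  }
  invisible(x)
}
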