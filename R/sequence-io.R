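#' Construct a coding-sequence record
#'
#' A `cds_record` holds one coding transcript: its identifier, the gene it
#' belongs to, and the nucleotide sequence (uppercase A/C/G/T). Validation
#' against the reading-frame rules (ATG start, terminal stop, length a
#' multiple of three, no internal stop) is a separate step, [validate_cds()],
#' so that invalid records can be inspected rather than silently dropped.
#'
#' @param transcript_id Transcript identifier (e.g. a GenBank-style accession).
#' @param gene Gene label used for per-gene pooling and averaging.
#' @param sequence Nucleotide string; case-insensitive on input.
#' @return An object of class `cds_record`.
#' @export
cds_record <- function(transcript_id, gene, sequence) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene), length(gene) == 1L,
            is.character(sequence), length(sequence) == 1L)
  obj <- list(transcript_id = transcript_id, gene = gene,
              sequence = toupper(sequence))
  class(obj) <- "cds_record"
  obj
}

#' @export
print.cds_record <- function(x, ...) {
  cat(sprintf("<cds_record %s [%s], %d nt>\n",
              x$transcript_id, x$gene, nchar(x$sequence)))
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a multi-record FASTA and returns unvalidated [cds_record()]s.
#' The gene label and transcript id are parsed from each header with
#' `header_pattern`, by default the `gene|transcript_id` convention; headers
#' that do not match use the whole header as transcript id and gene label.
#'
#' @param path Path to a FASTA file.
#' @param header_pattern Regex with two capture groups (gene, transcript id)
#'   applied to the FASTA header line.
#' @param alphabet Either `"strict"` (reject any non-ACGT character with an
#'   error) or `"drop_n"` (drop records containing other IUPAC characters,
#'   with a warning naming them).
#' @return A list of `cds_record` objects (possibly empty).
#' @export
read_cds_fasta <- function(path, header_pattern = "^([^|]+)\\|(.+)$",
                           alphabet = c("strict", "drop_n")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) return(list())
  headers <- names(seqs)
  out <- vector("list", length(seqs))
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    s <- toupper(as.character(seqs[[i]]))
    hdr <- headers[[i]]
    m <- regmatches(hdr, regexec(header_pattern, hdr))[[1]]
    if (length(m) == 3L) {
      gene <- m[[2]]; tid <- m[[3]]
    } else {
      gene <- hdr; tid <- hdr
    }
    bad <- gsub("[ACGT]", "", s)
    if (nzchar(bad)) {
      if (alphabet == "strict")
        stop("non-ACGT characters in record '", hdr, "': ",
             paste(unique(strsplit(bad, "")[[1]]), collapse = ","))
      warning("dropping record '", hdr, "' (non-ACGT characters: ",
              paste(unique(strsplit(bad, "")[[1]]), collapse = ","), ")")
      next
    }
    out[[i]] <- cds_record(tid, gene, s)
    keep[i] <- TRUE
  }
  out[keep]
}

#' Validate a coding sequence against reading-frame rules
#'
#' A transcript is accepted when its sequence length is at least 6 nt and
#' divisible by 3, the first codon is ATG, the final codon is a stop
#' (TAA/TAG/TGA), and — under the default strict policy — no internal codon
#' is a stop. The verdict carries machine-readable reason codes rather than
#' raising, so a gene set can report everything it rejected.
#'
#' @param record A [cds_record()].
#' @param code A [genetic_code()].
#' @param strict_internal_stop Treat an internal stop codon as invalid
#'   (default TRUE; curated CDS should not contain one).
#' @return A list of class `cds_validation`: `valid` (logical) and `reasons`
#'   (character vector drawn from `"empty"`, `"too_short"`, `"not_triplet"`,
#'   `"no_atg_start"`, `"no_terminal_stop"`, `"internal_stop"`).
#' @export
validate_cds <- function(record, code = genetic_code(),
                         strict_internal_stop = TRUE) {
  s <- record$sequence
  reasons <- character(0)
  n <- nchar(s)
  if (n == 0L) reasons <- c(reasons, "empty")
  if (n > 0L && n %% 3L != 0L) reasons <- c(reasons, "not_triplet")
  if (n > 0L && n %% 3L == 0L && n < 6L) reasons <- c(reasons, "too_short")
  if (n >= 3L && substr(s, 1L, 3L) != "ATG")
    reasons <- c(reasons, "no_atg_start")
  if (n >= 6L && n %% 3L == 0L) {
    cods <- substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
    if (!cods[length(cods)] %in% code$stop_codons)
      reasons <- c(reasons, "no_terminal_stop")
    if (strict_internal_stop && length(cods) > 2L &&
        any(cods[seq_len(length(cods) - 1L)][-1L] %in% code$stop_codons))
      reasons <- c(reasons, "internal_stop")
    if (strict_internal_stop && length(cods) > 1L &&
        cods[1L] %in% code$stop_codons)
      reasons <- c(reasons, "internal_stop")
  }
  structure(list(valid = length(reasons) == 0L, reasons = unique(reasons)),
            class = "cds_validation")
}

#' Split a coding sequence into codons
#'
#' @param record A [cds_record()] (or a plain nucleotide string) whose length
#'   is divisible by 3.
#' @return Character vector of codons; concatenating it reproduces the
#'   sequence.
#' @export
split_codons <- function(record) {
  s <- if (inherits(record, "cds_record")) record$sequence else toupper(record)
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length ", n, " is not divisible by 3")
  if (n == 0L) return(character(0))
  substring(s, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}

#' Translate a validated coding sequence
#'
#' Translates codons to one-letter amino acids, dropping the terminal stop.
#'
#' @inheritParams validate_cds
#' @param strict Error on an internal stop codon (default TRUE); otherwise
#'   internal stops are emitted as `*`.
#' @return Amino-acid string of length (codon count - 1) when the record ends
#'   in a stop.
#' @export
translate_cds <- function(record, code = genetic_code(), strict = TRUE) {
  cods <- split_codons(record)
  if (length(cods) && cods[length(cods)] %in% code$stop_codons)
    cods <- cods[-length(cods)]
  aa <- code$aa[cods]
  if (strict && any(aa == "*"))
    stop("internal stop codon at codon position ",
         which(aa == "*")[1], " of ", record$transcript_id)
  paste(aa, collapse = "")
}

#' Assemble records into a gene set
#'
#' Groups validated transcripts by gene label. Transcript ids must be unique
#' within the set and every gene has at least one transcript.
#'
#' @param records List of [cds_record()]s.
#' @param code,strict_internal_stop Passed to [validate_cds()].
#' @param on_invalid `"error"` (default) or `"drop"` (drop with a warning
#'   naming the record and reasons).
#' @return Object of class `gene_set`: named list gene -> list of records.
#' @export
gene_set <- function(records, code = genetic_code(),
                     strict_internal_stop = TRUE,
                     on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (length(records) == 0L)
    return(structure(list(), class = "gene_set"))
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    v <- validate_cds(records[[i]], code, strict_internal_stop)
    if (v$valid) {
      keep[i] <- TRUE
    } else {
      msg <- paste0("invalid CDS '", records[[i]]$transcript_id, "': ",
                    paste(v$reasons, collapse = ", "))
      if (on_invalid == "error") stop(msg) else warning(msg)
    }
  }
  records <- records[keep]
  ids <- vapply(records, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  genes <- vapply(records, `[[`, character(1), "gene")
  out <- split(records, factor(genes, levels = unique(genes)))
  structure(out, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set:", length(x), "genes,",
      sum(vapply(x, length, integer(1))), "transcripts>\n")
  for (g in names(x))
    cat(sprintf("  %s: %d transcript(s)\n", g, length(x[[g]])))
  invisible(x)
}

#' Read a gene-set manifest
#'
#' A manifest is a TSV with columns `gene`, `transcript_id` and `path`
#' (FASTA file containing the transcript, looked up by matching either the
#' `gene|transcript_id` header or the bare transcript id). It reproduces a
#' published gene/transcript grouping from per-file or pooled FASTA input.
#'
#' @param manifest_path Path to the TSV manifest.
#' @param base_dir Directory against which relative `path` entries resolve;
#'   defaults to the manifest's directory.
#' @param ... Passed to [gene_set()].
#' @return A `gene_set`.
#' @export
read_gene_set <- function(manifest_path, base_dir = dirname(manifest_path),
                          ...) {
  man <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript_id", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  records <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, man$path[i])
    recs <- read_cds_fasta(p)
    ids <- vapply(recs, `[[`, character(1), "transcript_id")
    j <- match(man$transcript_id[i], ids)
    if (is.na(j))
      stop("transcript ", man$transcript_id[i], " not found in ", p)
    rec <- recs[[j]]
    rec$gene <- man$gene[i]
    records[[i]] <- rec
  }
  gene_set(records, ...)
}

#' Write a gene set to FASTA plus manifest
#'
#' Writes all transcripts to one multi-FASTA (headers `gene|transcript_id`)
#' and a TSV manifest consumable by [read_gene_set()].
#'
#' @param gs A `gene_set`.
#' @param fasta_path,manifest_path Output paths.
#' @return Invisibly, the manifest data frame.
#' @export
write_gene_set <- function(gs, fasta_path, manifest_path) {
  recs <- unlist(unname(gs), recursive = FALSE)
  seqs <- Biostrings::DNAStringSet(vapply(recs, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(recs, function(r)
    paste0(r$gene, "|", r$transcript_id), character(1))
  Biostrings::writeXStringSet(seqs, fasta_path)
  man <- data.frame(
    gene = vapply(recs, `[[`, character(1), "gene"),
    transcript_id = vapply(recs, `[[`, character(1), "transcript_id"),
    path = basename(fasta_path),
    stringsAsFactors = FALSE
  )
  utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(man)
}
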