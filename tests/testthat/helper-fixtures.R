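# shared fixtures, all built in code

# a minimal valid CDS: ATG + body codons + stop
make_cds <- function(body, id = "t1", gene = "G1", stop = "TAA") {
  cds_record(id, gene, paste(c("ATG", body, stop), collapse = ""))
}

# valid CDS of n codons total whose body repeats the given codon(s)
repeat_cds <- function(codon, n_codons, id = "t1", gene = "G1") {
  make_cds(rep(codon, length.out = n_codons - 2L), id = id, gene = gene)
}

# codon count table from a named vector of nonzero counts
counts_of <- function(...) {
  x <- c(...)
  cnt <- integer(64)
  names(cnt) <- genetic_code()$codons
  cnt[names(x)] <- as.integer(x)
  cnt
}

# brute-force scaled chi-square oracle, coded independently of the package:
# straight per-family chisq.test-style summation over expected equal usage
scs_oracle <- function(cnt) {
  code <- genetic_code()
  total <- 0
  chi <- 0
  for (aa in names(code$families)) {
    fam <- code$families[[aa]]
    if (length(fam) < 2 || aa %in% c("M", "W")) next
    obs <- cnt[fam]
    n <- sum(obs)
    if (n == 0) next
    e <- rep(n / length(fam), length(fam))
    chi <- chi + sum((obs - e)^2 / e)
    total <- total + n
  }
  chi / total
}

# random nonzero codon count table over the 59 synonymous codons
random_counts <- function() {
  code <- genetic_code()
  cnt <- integer(64)
  names(cnt) <- code$codons
  cnt[code$syn_codons] <- rpois(59, lambda = 20) + 1L
  cnt
}

# fabricate a pair_table from a sparse specification
fake_pair_table <- function(pairs, counts) {
  code <- genetic_code()
  m <- matrix(0L, 64, 64, dimnames = list(code$codons, code$codons))
  for (i in seq_along(counts)) {
    p <- strsplit(pairs[i], "-", fixed = TRUE)[[1]]
    m[p[1], p[2]] <- m[p[1], p[2]] + as.integer(counts[i])
  }
  structure(m, N = sum(m), class = c("pair_table", "matrix"))
}
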