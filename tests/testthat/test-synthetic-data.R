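test_that("generation is seed-deterministic with independent substreams", {
  spec <- table1_like_spec(seed = 5)
  a <- generate_cds(spec, "GENE_A", 1)
  b <- generate_cds(spec, "GENE_A", 1)
  expect_identical(a$sequence, b$sequence)
  # a different transcript index gives a different stream
  expect_false(identical(a$sequence, generate_cds(spec, "GENE_A", 2)$sequence))
  # adding transcripts or genes does not perturb existing streams
  spec_plus <- generator_spec(
    genes = list(GENE_A = list(n = 20L), GENE_B = list(n = 1L),
                 GENE_C = list(n = 4L), GENE_D = list(n = 6L),
                 GENE_E = list(n = 2L)),
    length_nt = c(846, 2313), seed = 5)
  expect_identical(generate_cds(spec_plus, "GENE_A", 1)$sequence, a$sequence)
  # full set determinism
  gs1 <- generate_gene_set(spec)
  gs2 <- generate_gene_set(table1_like_spec(seed = 5))
  expect_identical(gs1, gs2)
})

test_that("table1-like preset matches the target study structure", {
  gs <- generate_gene_set(table1_like_spec(seed = 19))
  expect_equal(vapply(gs, length, integer(1)),
               c(GENE_A = 11L, GENE_B = 1L, GENE_C = 4L, GENE_D = 6L))
  for (g in names(gs)) for (r in gs[[g]]) {
    n <- nchar(r$sequence)
    expect_true(n >= 846 && n <= 2313)
    expect_equal(n %% 3, 0)
    v <- validate_cds(r)
    expect_true(v$valid)
  }
})

test_that("one-hot synonymous weights force the planted codon", {
  spec <- generator_spec(genes = list(G = list(n = 1L)),
                         length_nt = c(3000, 3000),
                         syn_weights = list(L = c(CTG = 1)), seed = 7)
  r <- generate_cds(spec, "G", 1)
  cods <- split_codons(r)
  leu <- cods[genetic_code()$aa[cods] == "L"]
  expect_gt(length(leu), 50)
  expect_true(all(leu == "CTG"))
})

test_that("GC3 skew moves third-position composition in the requested direction", {
  lo <- generator_spec(genes = list(G = list(n = 1L)),
                       length_nt = c(9000, 9000), gc3 = 0.2, seed = 83)
  hi <- generator_spec(genes = list(G = list(n = 1L)),
                       length_nt = c(9000, 9000), gc3 = 0.8, seed = 83)
  g_lo <- synonymous_third_composition(split_codons(generate_cds(lo, "G", 1)))
  g_hi <- synonymous_third_composition(split_codons(generate_cds(hi, "G", 1)))
  expect_lt(g_lo[["GC3s"]], 0.5)
  expect_gt(g_hi[["GC3s"]], 0.5)
  expect_gt(g_hi[["GC3s"]], g_lo[["GC3s"]] + 0.3)
})

test_that("analytic truth table follows from the weights", {
  one_hot <- generator_spec(genes = list(G = list(n = 1L)),
                            syn_weights = list(L = c(CTG = 1)), seed = 1)
  tr <- known_truth(one_hot)$G
  expect_equal(tr$rscu[["CTG"]], 6)
  expect_equal(tr$rscu[["CTT"]], 0)
  expect_equal(tr$preferred[["L"]], "CTG")
  uniform <- generator_spec(genes = list(G = list(n = 1L)), seed = 1)
  expect_equal(unname(known_truth(uniform)$G$rscu),
               rep(1, 59))
  skew <- generator_spec(genes = list(G = list(n = 1L)),
                         syn_weights = list(K = c(AAA = 3, AAG = 1)),
                         seed = 1)
  tr <- known_truth(skew)$G
  expect_equal(tr$rscu[["AAA"]], 1.5)
  expect_equal(tr$rscu[["AAG"]], 0.5)
})

test_that("observed RSCU recovers the planted weights at large codon counts", {
  spec <- generator_spec(
    genes = list(G = list(n = 1L)),
    length_nt = c(600000, 600000),  # 200k codons
    syn_weights = list(L = c(CTG = 3, CTT = 1, CTC = 1, CTA = 1,
                             TTA = 1, TTG = 1),
                       K = c(AAA = 3, AAG = 1)),
    seed = 89)
  r <- generate_cds(spec, "G", 1)
  obs <- unclass(rscu(codon_counts(r)))
  truth <- known_truth(spec)$G$rscu
  expect_lt(max(abs(obs - truth)), 0.1)
})

test_that("uniform and one-hot sampling drive ENc to Wright's limits", {
  uni <- generator_spec(genes = list(G = list(n = 1L)),
                        length_nt = c(90000, 90000), seed = 97)
  e_uni <- as.numeric(enc(codon_counts(generate_cds(uni, "G", 1))))
  expect_gte(e_uni, 60)
  expect_lte(e_uni, 61)
  code <- genetic_code()
  hot <- generator_spec(
    genes = list(G = list(n = 1L)),
    length_nt = c(90000, 90000),
    syn_weights = stats::setNames(
      lapply(names(code$families), function(aa)
        stats::setNames(1, code$families[[aa]][1])),
      names(code$families)),
    seed = 97)
  e_hot <- as.numeric(enc(codon_counts(generate_cds(hot, "G", 1))))
  expect_equal(e_hot, 20, tolerance = 0.05)
})

test_that("planted preferred codons are recovered as overrepresented", {
  hits <- 0L
  for (i in 1:100) {
    spec <- generator_spec(
      genes = list(G = list(n = 1L)), length_nt = c(1800, 1800),
      syn_weights = list(L = c(CTG = 0.6, CTT = 0.08, CTC = 0.08,
                               CTA = 0.08, TTA = 0.08, TTG = 0.08)),
      seed = 1000L + i)
    r <- generate_cds(spec, "G", 1)
    cls <- classify_rscu(rscu(codon_counts(r)))
    if (cls[["CTG"]] == "overrepresented") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})
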