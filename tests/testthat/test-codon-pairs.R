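test_that("pair counting is overlapping-adjacent with the stop as final 3' member", {
  pt <- count_pairs(cds_record("t", "g", "ATGAAATAA"))
  expect_equal(attr(pt, "N"), 2L)
  m <- unclass(pt)
  expect_equal(m["ATG", "AAA"], 1L)
  expect_equal(m["AAA", "TAA"], 1L)
  expect_equal(sum(m), 2L)
})

test_that("pair totals satisfy N = total codons - transcript count", {
  gs <- generate_gene_set(generator_spec(
    genes = list(P = list(n = 3L)), length_nt = c(300, 900), seed = 29))
  pt <- count_pairs(gs$P)
  total_codons <- sum(vapply(gs$P, function(r) length(split_codons(r)),
                             integer(1)))
  expect_equal(attr(pt, "N") + length(gs$P), total_codons)
})

test_that("length panel reproduces published pair-score arithmetic", {
  n_pairs <- panel_pair_totals()
  expect_equal(unname(n_pairs[c("APP", "CCND1", "CCNE1", "PTPA")]),
               c(7851L, 295L, 1531L, 1867L))
  n_cod <- panel_codon_totals()
  expect_equal(unname(n_cod[c("APP", "CCND1", "CCNE1", "PTPA")]),
               c(7862L, 296L, 1535L, 1873L))
  expect_equal(round(adjusted_pair_score(11, n_cod[["CCND1"]]), 2), 3.72)
  expect_equal(round(adjusted_pair_score(77, n_cod[["APP"]]), 2), 0.98)
  expect_equal(round(adjusted_pair_score(18, n_cod[["PTPA"]]), 2), 0.96)
  expect_equal(round(adjusted_pair_score(13, n_cod[["CCNE1"]]), 2), 0.85)
  expect_equal(adjusted_pair_score(0, 100), 0)
  expect_error(adjusted_pair_score(5, 0), "positive")
  expect_error(adjusted_pair_score(11, 10), "exceeds")
})

test_that("top pairs rank by count with reverse-lexicographic tie-break", {
  pt <- fake_pair_table(
    c("GAA-GCC", "GTG-GAA", "ACC-ACC", "GCA-GAA"),
    c(44, 44, 77, 44))
  tp <- top_pairs(pt, k = 4)
  expect_equal(tp$pair,
               c("ACC-ACC", "GTG-GAA", "GCA-GAA", "GAA-GCC"))
  expect_equal(tp$count, c(77, 44, 44, 44))
  # k larger than populated pairs returns all
  expect_equal(nrow(top_pairs(pt, k = 100)), 4)
  # dominant pair always first
  gs <- generate_gene_set(generator_spec(
    genes = list(D = list(n = 2L)), length_nt = c(600, 900),
    pair_motifs = list(list(pair = c("GAG", "GAG"), times = 25L)),
    seed = 37))
  tp <- top_pairs(count_pairs(gs$D))
  expect_equal(tp$pair[1], "GAG-GAG")
})

test_that("adjusted residuals have zero row margins and behave under independence", {
  # independence: a long iid codon stream keeps almost all cells within +/-5
  set.seed(41)
  code <- genetic_code()
  body <- sample(setdiff(code$sense_codons, "ATG"), 20000, replace = TRUE,
                 prob = runif(60, 0.5, 1.5))
  r <- make_cds(body, "big", "G")
  pt <- count_pairs(r)
  res <- context_residuals(pt)
  E <- attr(res, "expected")
  m <- unclass(pt)
  # margin identity per populated row
  rs <- rowSums(m)
  for (i in which(rs > 0))
    expect_equal(sum(m[i, ] - E[i, ]), 0, tolerance = 1e-8)
  populated <- !is.na(res)
  frac_within <- mean(abs(res[populated]) <= 5)
  expect_gte(frac_within, 0.99)
})

test_that("planted co-occurring pairs produce residuals beyond +5", {
  gs <- generate_gene_set(generator_spec(
    genes = list(M = list(n = 4L)), length_nt = c(1200, 2000),
    pair_motifs = list(list(pair = c("CAC", "TGT"), times = 20L)),
    seed = 43))
  pt <- count_pairs(gs$M)
  res <- context_residuals(pt)
  expect_gt(res["CAC", "TGT"], 5)
})

test_that("context classes map residual bands and transpose consistently", {
  res <- matrix(c(6.2, -7, 4.9, NA), 2, 2)
  cls <- classify_context(res)
  expect_equal(as.vector(cls),
               c("good", "bad", "not_significant", "absent"))
  gs <- generate_gene_set(generator_spec(
    genes = list(Tt = list(n = 2L)), length_nt = c(900, 1200), seed = 47))
  pt <- count_pairs(gs$Tt)
  tpt <- structure(t(unclass(pt)), N = attr(pt, "N"),
                   class = c("pair_table", "matrix"))
  expect_equal(classify_context(context_residuals(tpt)),
               t(classify_context(context_residuals(pt))))
})

test_that("start context ranks the codon after the initiator ATG", {
  recs <- list(make_cds(c("AAG", "CCC"), "t1"),
               make_cds(c("AAG", "GGG"), "t2"),
               make_cds(c("AAG", "TTT"), "t3"))
  sc <- start_context(recs)
  expect_equal(sc$codon[1], "AAG")
  expect_equal(sc$frequency[1], 1)
  # deterministic lexicographic tie-break
  tie <- start_context(list(make_cds(c("TTC", "AAA"), "a"),
                            make_cds(c("AAG", "AAA"), "b")))
  expect_equal(tie$codon, c("AAG", "TTC"))
})
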