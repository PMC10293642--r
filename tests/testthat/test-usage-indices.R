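test_that("RSCU matches hand computation and conserves family sums", {
  v <- rscu(counts_of(TTT = 10, TTC = 10))
  expect_equal(v[["TTT"]], 1)
  expect_equal(v[["TTC"]], 1)
  # Leu: CTG=2, CTT=1 over a six-fold family
  v <- rscu(counts_of(CTG = 2, CTT = 1))
  expect_equal(v[["CTG"]], 4)
  expect_equal(v[["CTT"]], 2)
  expect_true("F" %in% attr(v, "zero_families"))

  code <- genetic_code()
  set.seed(101)
  for (i in 1:50) {
    cnt <- random_counts()
    v <- unclass(rscu(cnt))
    for (aa in setdiff(names(code$families), c("M", "W"))) {
      fam <- code$families[[aa]]
      if (sum(cnt[fam]) > 0)
        expect_equal(sum(v[fam]), length(fam))
    }
    expect_true(all(v >= 0))
  }
})

test_that("RSCU agrees with an independent implementation on a random CDS", {
  skip_if_not_installed("seqinr")
  set.seed(7)
  r <- generate_cds(table1_like_spec(seed = 7), "GENE_A", 4)
  ours <- unclass(rscu(codon_counts(r)))
  theirs <- seqinr::uco(strsplit(tolower(r$sequence), "")[[1]],
                        index = "rscu")
  names(theirs) <- toupper(names(theirs))
  common <- names(ours)
  expect_equal(unname(ours[common]), unname(theirs[common]), tolerance = 1e-9)
})

test_that("RSCU classification uses the 1.6/0.6 thresholds inclusively", {
  cls <- classify_rscu(c(a = 1.7, b = 1.6, c = 1.0, d = 0.6, e = 0.5))
  expect_equal(unname(cls),
               c("overrepresented", "random", "random", "random",
                 "underrepresented"))
})

test_that("CAI is the geometric mean of reference weights over the 59 codons", {
  ref <- cai_weights()
  # a gene using only w = 1 codons scores exactly 1
  w <- unclass(ref)
  best <- names(w)[w == 1]
  expect_equal(cai(counts_of(stats::setNames(rep(5, length(best)), best))), 1)
  # uniform reference: every codon has w = 1
  uni <- cai_weights(stats::setNames(rep(1, 64), genetic_code()$codons))
  expect_equal(cai(random_counts(), uni), 1)
  # constant-w gene: geometric mean of a constant
  half <- names(w)[w < 1][1]
  single <- counts_of(stats::setNames(30, half))
  expect_equal(cai(single, ref), w[[half]])
  # scale invariance: duplicating a transcript leaves CAI unchanged
  r <- generate_cds(table1_like_spec(seed = 13), "GENE_B", 1)
  one <- cai(codon_counts(r), ref)
  two <- cai(codon_counts(list(r, r)), ref)
  expect_equal(one, two)
})

test_that("reference weights give every family a w = 1 codon", {
  ref <- cai_weights()
  code <- genetic_code()
  for (aa in setdiff(names(code$families), c("M", "W"))) {
    fam <- code$families[[aa]]
    expect_equal(max(unclass(ref)[fam]), 1)
    expect_true(all(unclass(ref)[fam] > 0))
  }
  # TSV substitution round-trip
  tsv <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(codon = names(human_codon_usage()),
               count = unname(human_codon_usage())),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(unclass(cai_weights(tsv)), unclass(ref),
               ignore_attr = TRUE)
})

test_that("ENc hits Wright's limits and stays within [20, 61]", {
  # exclusive use of one codon per family, large n -> exactly 20
  code <- genetic_code()
  one_hot <- counts_of(stats::setNames(
    rep(1000, length(code$families)),
    vapply(code$families, `[`, character(1), 1)))
  expect_equal(as.numeric(enc(one_hot)), 20)
  # perfectly uniform usage of all 59 codons, large n -> 61 (clamped)
  uniform <- counts_of(stats::setNames(rep(500, 59), code$syn_codons))
  expect_equal(as.numeric(enc(uniform)), 61, tolerance = 1e-6)
  # sampled uniform usage at 30k codons stays within 1 of 61
  set.seed(31)
  cnt <- counts_of(stats::setNames(
    as.vector(table(factor(sample(code$syn_codons, 30000, replace = TRUE),
                           levels = code$syn_codons))), code$syn_codons))
  expect_gt(as.numeric(enc(cnt)), 60)
  expect_lte(as.numeric(enc(cnt)), 61)
})

test_that("ENc imputes missing degeneracy classes and flags them", {
  # no Ile codons at all: three-fold class imputed from classes 2 and 4
  code <- genetic_code()
  cnt <- random_counts()
  cnt[c("ATT", "ATC", "ATA")] <- 0L
  e <- enc(cnt)
  expect_true("3" %in% attr(e, "imputed_classes"))
  expect_true(as.numeric(e) >= 20 && as.numeric(e) <= 61)
})

test_that("expected-ENc curve matches its closed form and is symmetric", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  s <- seq(0.05, 0.45, by = 0.05)
  expect_equal(enc_expected(s) - 2 - s, enc_expected(1 - s) - 2 - (1 - s))
  grid <- seq(0, 1, by = 0.01)
  expect_equal(grid[which.max(enc_expected(grid))], 0.5)
  expect_error(enc_expected(1.2), "within")
})

test_that("ENc-GC3 classification bands behave as documented", {
  s <- 0.5
  e <- enc_expected(s)
  expect_equal(enc_gc3_classify(e, s), "on_curve")
  expect_equal(enc_gc3_classify(e - 1.5, s), "near_curve")
  expect_equal(enc_gc3_classify(e - 10, s), "below_curve")
  expect_equal(enc_gc3_classify(e + 10, s), "above_curve")
})

test_that("scaled chi-square matches the brute-force oracle", {
  # exactly equal usage in every family -> 0
  code <- genetic_code()
  equal <- counts_of(stats::setNames(rep(12, 59), code$syn_codons))
  expect_equal(scaled_chi_square(equal), 0)
  # a two-fold family using one codon exclusively, nothing else -> 1
  expect_equal(scaled_chi_square(counts_of(TTT = 37)), 1)
  # random tables equal the independent per-family chi-square / n oracle
  set.seed(55)
  for (i in 1:200) {
    cnt <- random_counts()
    expect_equal(scaled_chi_square(cnt), scs_oracle(cnt), tolerance = 1e-12)
  }
})

test_that("GRAVY and AROMA match the Kyte-Doolittle and aromatic definitions", {
  expect_equal(gravy("AG"), 0.7)       # (1.8 - 0.4) / 2
  expect_equal(gravy("III"), 4.5)
  expect_lt(gravy("KKK"), 0)
  expect_error(gravy("AXZ"), "unknown")
  expect_equal(aroma("FYW"), 1)
  expect_equal(aroma("AAAA"), 0)
  expect_equal(aroma("AAAF"), 0.25)
})

test_that("PR2 coordinates centre at (0.5, 0.5) and handle degenerate spans", {
  cods <- c("GGA", "GGT", "GGG", "GGC")  # one each of A/T/G/C at position 3
  expect_equal(unname(pr2(cods)), c(0.5, 0.5))
  expect_equal(pr2(c("GGG", "AGG", "CGG"))[["x"]], 1)
  allA <- pr2(c("GGA", "CCA", "AAA"))
  expect_equal(allA[["y"]], 1)
  expect_true(is.na(allA[["x"]]))
  # four-fold-only mode drops non-four-fold families
  mixed <- c("TTT", "TTT", "GGA", "GGT", "GGC", "GGG")
  expect_equal(unname(pr2(mixed, fourfold_only = TRUE)), c(0.5, 0.5))
  expect_error(pr2(c("TAA")), "no eligible")
})
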