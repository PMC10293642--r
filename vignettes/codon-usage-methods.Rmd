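---
title: "Methods: codon usage, bias and context statistics in codonkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon usage, bias and context statistics in codonkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`codonkit` analyses codon usage in sets of protein-coding transcripts grouped
by gene — the setting of comparative studies that ask whether a small panel of
disease-relevant genes shows compositional, mutational or selective codon-level
signatures. This vignette documents the statistical machinery, its
assumptions, the tunable parameters, and the design decisions behind the
implementation.

## Input model and validation

A coding sequence is accepted when it is a clean reading frame: length at
least 6 nt and divisible by 3, ATG start, terminal stop (TAA/TAG/TGA), and —
under the default strict policy — no internal stop. Curated RefSeq-style CDS
satisfy these rules; an internal stop almost always indicates a frame or
curation error, which is why rejection (not silent repair) is the default and
a lax mode merely demotes it. The alphabet is strict A/C/G/T: IUPAC ambiguity
codes are never translated silently, because downstream composition
percentages are required to sum to exactly 100. An N-tolerant reader mode
drops (with a named warning) rather than patches affected records.

Transcripts are grouped by gene, and *every* per-gene statistic in the
package is an unweighted mean over the gene's transcripts (never a
count-pooled estimate, except where pooling is the statistic — RSCU
classification per gene and the codon-pair table). This keeps a gene with one
long isoform comparable to a gene with eleven.

## Composition

Overall and positional composition are percentages over the full deposited
CDS including the terminal stop codon, matching how transcript lengths are
reported in sequence databases; a flag excludes the stop, and toggling it can
move any base's count by at most 3. The synonymous third-position fractions
(A3s, C3s, G3s, T3s, GC3s) exclude stops, Met and Trp and use the codonW
convention: the denominator for base *b* is the number of codons whose
synonymous family has at least one member ending in *b*. Tools differ on this
definition, which is why it is spelled out and tested; GC3s uses all 59
synonymously variable codons (every multi-codon family has a G- or C-ending
member).

## Codon-bias indices

**RSCU.** `RSCU(c) = obs(c) / (family_total / degeneracy)` over the 59
synonymous codons; family values sum to the family's degeneracy, 1 is
unbiased. Codons are classified overrepresented above 1.6 and
underrepresented below 0.6 (inclusive band in between) — the conventional
cutoffs for calling preferred and avoided codons.

**CAI.** The geometric mean of relative adaptiveness weights
`w = f(c) / max f` over codon occurrences, restricted to the 59 codons
(CAI_59: Met, Trp and stops carry no synonymous information). The packaged
default reference is the widely reproduced aggregate human codon-usage table
(GenBank-derived per-thousand frequencies); because published studies often
use tool-specific highly-expressed-gene references whose weights are not
printed, any reference can be substituted from a two-column TSV
(codon, weight-or-count). Reference codons with zero count receive
`0.5 / max_count` before normalisation so that the geometric mean stays
finite; CAI values computed against different references are comparable in
rank but not in absolute value.

**ENc.** Wright's estimator. Per family, codon homozygosity
`F = (n * sum(p^2) - 1) / (n - 1)`; F is averaged within each degeneracy
class (9 two-fold, Ile alone three-fold, 5 four-fold, Leu/Ser/Arg six-fold)
and `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped at 61. Families with
fewer than 2 codons observed, or a non-positive F, are excluded from their
class mean; a wholly missing three-fold class is imputed as the average of
the two- and four-fold means, other missing classes as the mean of defined
classes, and the result is flagged. Short transcripts (the target panel's
minimum is 846 nt, 282 codons) can genuinely miss the Ile class, so
imputation is a practical necessity rather than an edge case. The expected
curve under composition alone, `ENc* = 2 + s + 29 / (s^2 + (1-s)^2)` with
`s = GC3s`, is maximised at s = 0.5 (ENc* = 60.5); observed points are
classified on/near/below/above the curve with default bands of 1 and 2 ENc
units — on/near is compatible with mutational-compositional pressure, well
below indicates selection among synonymous codons.

**SCS.** Scaled chi-square: per family, chi-square of observed counts
against equal synonymous usage, summed over the 18 multi-codon families and
divided by the total eligible codon count. Zero under exactly equal usage.
Although sometimes described as ranging to 1, the statistic exceeds 1 for
strongly biased families of degeneracy above 2 (a two-fold family used
one-sidedly contributes exactly chi-square = n); the range is therefore not
enforced.

**GRAVY and AROMA.** Mean Kyte–Doolittle hydropathy and the aromatic
residue fraction (Phe, Tyr, Trp) of the translated protein. The
Kyte–Doolittle scale spans −4.5 to +4.5, so GRAVY means lie in that range
(a narrower −2..+2 range is sometimes asserted in the literature but does
not hold for the standard scale and is not enforced).

**PR2.** Parity-rule-2 coordinates `x = G3/(G3+C3)`, `y = A3/(A3+T3)` over
third positions of sense codons (stops excluded); (0.5, 0.5) is the no-bias
centre. The default span is all sense codons because published panel
analyses state only "at the third codon position"; a classical
four-fold-family-only mode is provided. A coordinate with a zero denominator
is reported NA rather than forced.

## Rare codons

Per transcript, each codon's occurrence is length-adjusted to a percentage
(`100 * count / total codons`, stop codons in the denominator by default to
match deposited lengths; a flag excludes them). Gene averages are unweighted
transcript means, and a codon is rare when the gene average is strictly
below 0.5%. The strict inequality matters at panel scale: one occurrence in
a 296-codon transcript is 0.338% (rare), two are 0.676% (not). Rare-codon
panels group the 59 codons by amino-acid family degeneracy — 18 two-fold, 3
three-fold, 20 four-fold and 18 six-fold codons — assigning Leu/Ser/Arg
codons to the six-fold panel even though their codons sit in two codon
blocks, because rarity is compared within the full synonymous family.

## Codon pairs and context

Pairs are overlapping adjacent codons (i, i+1) pooled over a gene's
transcripts, the terminal stop participating as the 3' member of the final
pair: a transcript of k codons contributes k − 1 pairs. Two denominators
coexist deliberately:

* the **contingency table** uses N = total pairs (codons − transcripts),
  the structurally correct total for independence statistics;
* the **length-adjusted pair score** reported in top-pair tables is
  `100 * count / total codon count` — occurrences per 100 codons — which is
  the arithmetic that published per-gene pair tables print.

Top-pair tables rank by count, ties broken by the pair string in reverse
lexicographic order, reproducing the deterministic ordering of equal-count
blocks in published tables. Context is classified by Pearson adjusted
residuals on the 64×64 table,
`(O − E) / sqrt(E (1 − rowsum/N)(1 − colsum/N))`, approximately standard
normal under independence; following the convention of codon-context
software, residuals above +5 are "good" context, below −5 "bad", the band
in between not significant, and cells with empty margins "absent". The ±5
band is far beyond the ±1.96 of a single cell's 5% test because 64×64 cells
are scanned simultaneously; it is exposed as a parameter. A companion
statistic ranks the codon immediately after the initiator ATG across a
gene's transcripts, where context effects are strongest.

## Multivariate analysis and correlations

RSCU values (transcripts × 59 codons) feed a deterministic SVD-based PCA.
The default is column-centred, unscaled covariance PCA: RSCU is already
normalised within families, so rescaling each codon to unit variance would
up-weight codons of rare amino acids whose RSCU estimates are noisiest. A
correlation-mode PCA is available since published panel analyses do not
state their choice; axis inertia percentages should therefore be read
qualitatively (axis 1 > axis 2, two axes dominating) when comparing to
published figures. Axis signs follow a fixed convention — the largest
absolute loading on each axis is made positive — so loadings are
reproducible across linear-algebra backends.

Transcript length is correlated against composition, positional
composition, CAI, SCS, GRAVY, AROMA and the first two PCA scores
(Pearson by default, Spearman optionally), with two-tailed p-values and the
conventional NS/*/**/*** labels at 0.05/0.01/0.001. Panel-sized groups (6
to 16 transcripts) give these tests little power; the labels are reported,
not interpreted.

## The synthetic generator

The generator exists so that every stage is testable without downloads. It
emulates the *statistical* structure the analysis assumes: gene sets with a
configurable number of transcripts and nucleotide lengths drawn uniformly in
a range (the packaged preset mirrors the target panel: 4 genes with
11/1/4/6 transcripts, lengths in [846, 2313] nt), ATG start, a single
weighted terminal stop, and bodies sampled amino-acid-first (approximate
human protein composition by default) then synonymous-codon within family.
Controls: explicit per-family weight vectors, symmetric Dirichlet draws
(small alpha = strong skew), a GC3 odds multiplier on G/C-ending codons,
and pair-motif injection that overwrites random internal positions to plant
codon-pair context. One master seed drives per-gene/per-transcript
substreams derived by a fixed integer hash, so adding a transcript or gene
never perturbs existing ones.

`known_truth()` returns the analytic expectations implied by the weights
(expected RSCU `degeneracy * w / sum(w)`, preferred codon per family,
expected GC3s), the oracle for parameter-recovery tests.

What the generator does **not** emulate: codon autocorrelation beyond the
injected motifs, exon structure and UTRs, amino-acid composition differences
between real genes, CpG-related mutational asymmetries, and isoform overlap
(real transcript isoforms share exonic runs; generated "isoforms" are
independent draws). Passing recovery tests therefore demonstrates that the
estimators measure what they claim on data matching their assumptions — not
that real transcripts satisfy those assumptions.

## Numerical choices and problem sizes

Tests and the acceptance script run at deliberately chosen sizes: RSCU
parameter recovery uses a 200,000-codon gene, where sampling noise puts the
worst-case per-codon RSCU deviation comfortably under 0.1 (the six-fold Arg
family is the binding constraint — its RSCU standard error is about 0.02 at
this size); Wright-limit checks use 30,000 codons, where uniform sampling
keeps ENc within 1 of 61; overrepresentation recovery uses 100 replicates
of 600-codon transcripts with a planted 0.6-weight Leu codon (expected RSCU
3.6, about 5 standard errors above the 1.6 cutoff). Report TSVs are written
with fixed 15-significant-digit formatting and JSON with full precision, so
reruns under the same seed and configuration are byte-identical — which is
itself a tested contract.

## Interfaces

The package is library-first: `gene_set()` construction from FASTA plus a
TSV manifest, `codon_usage_report()` for the full per-gene report (13
machine-readable TSV/JSON outputs mirroring the tables and figure data of
comparative codon-usage studies), and `compare_groups()` for grouped
(e.g. up- versus down-regulated) summaries. Validation, generation, running
and comparison are R function calls; `scripts/acceptance.R` shows the
headline pipeline as a worked non-interactive script. GenBank retrieval is
deliberately out of scope — users supply FASTA, and the packaged accession
panel (`gene_panel_transcripts()`) documents which records to retrieve to
reproduce accession-level results.

## Known limitations

* CAI values depend on the reference; the packaged aggregate human table is
  a genome-wide, not a highly-expressed-gene, reference, so absolute CAI
  values will differ from tool-specific references even though rankings are
  stable.
* ENc imputation at panel transcript lengths introduces small biases when a
  degeneracy class is sparsely observed; imputed classes are flagged.
* Adjusted-residual context classes on small genes (a single 888-nt
  transcript gives N = 295 pairs) are dominated by the "absent" and
  "not significant" classes; the ±5 band is conservative by design.
* The PCA inertia split is sensitive to the centring/scaling choice; only
  the qualitative pattern is comparable across implementations.
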