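---
title: "Models and methods behind srnadeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind srnadeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`srnadeg` packages the desk-side analysis of a plant phosphate-starvation
sequencing study: small RNA annotation and differential expression,
degradome-guided target prediction, transcript quantification with DEG
selection, and promoter-motif plus GO enrichment analysis — all exercised
against a synthetic-data generator with planted truth. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the simulation-based verification does and does not show.

## Read preprocessing

Quality trimming implements the modified-Mott rule: every base
contributes `limit − P_error` to a running sum, where
`P_error = 10^(−Q/10)` from the Phred+33 score and `limit` is an error
probability (default **0.02**). The maximal-scoring contiguous segment is
kept; when several segments tie, the leftmost wins, so trimming is
deterministic. A read whose best segment is empty is discarded and
logged.

The 3′ adapter is then removed at the leftmost read position where the
adapter prefix matches the read suffix, allowing one mismatch per ten
aligned bases and requiring at least a 5-nt overlap (shorter chance
overlaps would truncate inserts spuriously). Quality trimming runs
*before* adapter matching so that a low-quality tail downstream of the
adapter — a toggle the simulator can produce — is gone before the
suffix-match is attempted. Finally, inserts outside **18–25 nt** are
discarded; counts of discarded reads are logged by reason.

The per-million (CPM) normalisation divides by the library size *after*
the length filter. Whether the denominator should include reads later
removed by that filter is genuinely ambiguous; the post-filter denominator
was chosen because it makes per-sample CPM sum exactly to 10^6 over the
sequences actually reported.

## Annotation layers

Unique sequences are annotated in a strict cascade — exact sense-strand
substring of a mature or precursor miRNA reference; else exact substring
(either strand, strand recorded) of a class-labelled cDNA; else miRNA
reference match with 1–3 substitutions; else unannotated — so the final
report is a partition. Only the miRNA step is strand-specific; cDNA
matching accepts antisense hits and flags them. When a sequence matches
transcripts of several classes in combined mode, one class is assigned by
a fixed priority (rRNA > tRNA > snoRNA > snRNA > SRP-RNA > non-translating
> protein-coding > pseudogene, configurable). The priority is a
convention: structural-RNA fragments are overwhelmingly the true origin of
sequences that also happen to occur inside an mRNA, and the order makes
the assignment invariant to transcript input order.

isomiR calls locate both the small RNA and its annotated mature miRNA in
the precursor; the signed start/end offsets (positive = extension,
negative = shortening) classify the variant, with (0, 0) reserved for the
exact mature sequence.

## Differential expression

The two-group test is the classic exact negative-binomial test with a
common dispersion:

* **Effective library sizes.** Counts are scaled to a common depth before
  conditioning. Plain column totals are badly biased here: when a fifth
  of features carry 8–64-fold planted changes, totals shift by factors of
  2–3 and the test loses both calibration and power. Effective sizes are
  therefore computed by median-of-ratios against a geometric-mean
  reference (over features observed in every sample), rescaled to the
  geometric mean of the totals — the standard composition-robust
  estimator. The same situation arises in the real data, where the large
  majority of responsive small RNAs move in one direction.
* **Dispersion.** A single dispersion `phi` is estimated by maximising the
  conditional likelihood of the within-group splits given the group
  totals on the equalised pseudo-counts, optimised on the
  `delta = phi/(1+phi)` scale; boundary solutions collapse to 0. On
  simulated data with `phi = 0.1` the estimate is accurate to about the
  third decimal at 5000 features.
* **Exact test.** For each feature the group-A total given the overall
  total follows the NB split `S_A ~ NB(n_A mu, phi/n_A)` (binomial in the
  Poisson limit `phi = 0`); the two-sided p-value sums the probabilities
  of all splits no more likely than the observed one, so `p = 1` when the
  observed split is the mode and `p` is never 0.
* **Selection.** Bonferroni uses `m` = features passing the nonzero
  filter; selection is strict (`p_adj < alpha`, default 0.05). Features
  annotated exactly to a miRNA reference become DEMs, all other
  significant features DESs. A feature expressed in only one condition
  has no finite log2 fold change; it is flagged (NaN) as exclusively
  expressed rather than given a pseudocount.

The DEG test for mRNA counts is an NB likelihood-ratio test (per-group
means vs a common mean, known shared dispersion, chi-square with 1 df).
With a single two-level factor it agrees with the exact test's decisions
to within simulation error, and its Bonferroni selections control the
family-wise error in null simulations.

## Degradome analysis

**Profiles.** Tags are length-filtered at 15 nt, collapsed, and matched
exactly to the sense strand of each transcript; a tag counts its 5′ end at
every locus it matches (multimapping multiplicity is logged). Raw counts
are normalised two ways: per 10^7 total mapped tags (the
depth-of-sequencing scale; 10^7 was chosen over 10^6 because single-site
counts would otherwise round to small fractions at typical depths, and the
scale is configurable), and as the fraction of each transcript's total
signal.

**Duplex search.** Candidate sites come from explicit window alignment
rather than a thermodynamic screen: each transcript window of length
`len(srna) ± max_bulge` is aligned globally against the small RNA (match
+1, G:U +0.5, mismatch 0, gap −2; ties broken deterministically toward
pairing). Windows sharing the same cleavage anchor — the transcript
position paired to small RNA nucleotide 10 — are deduplicated keeping the
best pairing. The alignment route makes every pairing inventory exactly
recountable by brute force, which the tests exploit; the thermodynamic
role is preserved through the MFE-ratio filter below. The inner loop is
compiled (Rcpp), so permutation nulls remain affordable.

**Scoring.** Two tracks:

* *Allen rule*: mismatch 1, bulged nucleotide 1, G:U 0.5, doubled at
  small RNA positions 2–13; with the position-10 relaxation a mismatch or
  wobble exactly at position 10 incurs the undoubled penalty. Candidates
  above the threshold (default 4.0) are dropped. A bulged transcript
  nucleotide takes the position of the next aligned small RNA nucleotide
  for the core-doubling decision — a convention, documented here because
  the rule's original statement does not address bulges between positions.
* *MFE-filtered penalty schema*: reject unless `mfe_ratio ≥ 0.6`, bulged
  nucleotides ≤ 3 and overhangs ≤ 2; then score
  `2·mismatch + 1·G:U + 3·bulge_nt + 1·loop` (weights configurable).
  The duplex energy is a simplified nearest-neighbour model: stacks
  between consecutive paired positions sum additive per-pair half
  energies (G:C −1.6, A:U −0.55, G:U −0.25 kcal/mol), each internal
  loop/bulge event costs +2.0 plus +0.5 per skipped nucleotide, and the
  initiation constant defaults to 0. Absolute kcal/mol values are *not*
  meaningful against published duplex energies; only the ratio to the
  perfect-complement energy and orderings are contractual, which is all
  the filter uses.

**Peak categories.** At a position with raw count `c`, transcript maximum
`M` and mean `A` over positions with signal: category 4 if `c = 1`; 0 if
`c > 1` is the unique maximum; 1 if it ties the maximum; 2 if
`A < c < M`; 3 if `1 < c ≤ A`. Zero-count positions are unscorable. A
prediction requires degradome signal within ±1 of the anchor (cleavage in
vivo occurs between the nucleotides paired to small RNA positions 10 and
11, and single-nucleotide slippage is common in real libraries), category
at most `category_max` (default 4 — report everything, filter
downstream), and a passing score.

**Permutation p-values.** The published analyses report per-site p-values
without a stated null, so the package defines one: mononucleotide shuffles
of the small RNA (dinucleotide shuffles by flag), re-screened against the
same transcript; `p = (1 + k)/(n_perm + 1)` where `k` shuffles achieve a
score and category no worse than observed. This is a replacement null,
not a reproduction of any external tool's p-value.

## Quantification, motifs, enrichment

TPM and RPKM follow the printed equations verbatim, per sample (the ΣRPKM
denominator is per-sample; a pooled denominator would break the per-sample
10^6 identity the definition implies). Scaling a sample's counts by a
constant leaves TPM unchanged, and the RPKM→TPM route equals direct
rate normalisation — both identities are tested.

Motif scanning reports every occurrence of the IUPAC consensus, overlaps
included, on both strands by default (reverse-complement scan, reported at
the plus-strand footprint); ambiguous bases in the scanned sequence never
match. Note that P1BS (`GNATATNC`) is its own reverse complement up to the
ambiguity codes, so every plus-strand site also appears as a minus-strand
hit at the same footprint; gene-level tallies deduplicate, so this
strandedness choice cannot change gene counts, only raw hit counts. Bins
are `[−500,−1]`, `[−1000,−501]`, `[−1500,−1001]`, `[−2000,−1501]`, keyed
by hit start, split by the sign of the gene's log2 fold change.

GO over-representation uses the upper-tail binomial test (not
hypergeometric — matching the analysis style being reproduced) with
success probability `term_size / background_size` and `n = input_size`,
Bonferroni-adjusted over tested terms; fold enrichment is
`(k / term_size) / (input_size / background_size)`.

## The synthetic-data generator

The generator emulates the statistical structure the downstream stages
assume: two conditions × three replicates; unique 18–25-nt small RNAs
composed of exact mature miRNAs, precursor-templated isomiRs (±1–2-nt end
shifts), cDNA fragments of all eight classes, and random unannotatable
sequences; negative-binomial counts (dispersion default **0.1**, a typical
three-replicate value — the emulated libraries' true dispersion is
unknown, so this is an explicitly free parameter); planted log2 fold
changes drawn from ±[3, 6] with planted features re-assigned baseline
means in [50, 200] so effects are detectable by design; degradome tags
whose 5′ ends sit exactly at the coordinate paired to small RNA nucleotide
10 of planted targets, at `signal_to_noise` (default 50) times a uniform
background (a 5′-biased background is available by flag; uniform is the
default because it is the simplest null for the peak-category rules);
promoters of the configured length with planted, position-recorded
P1BS/PHO instances; and a GO map with two terms biased toward the planted
DEGs.

What it does **not** emulate: sequencing error substitutions, genome
coordinates (everything lives in transcript space), 5′-biased degradation
in the default background, adapter dimers, or compositional artefacts
beyond those induced by the planted changes themselves. Passing
planted-truth tests therefore demonstrates correctness of the
implementation under the stated model, not robustness to every artefact
of real libraries.

Determinism: a configuration's seed fixes every output byte-for-byte;
sub-stages derive fixed offsets from it (keep seeds below 2^31 − 16).

## Verification sizes and limitations

The test suite and the acceptance script run at deliberately modest sizes
chosen to make the Monte-Carlo bands tight enough to be meaningful while
keeping a full run in the low minutes: ~140-sequence small RNA populations
over six libraries of 8–20 thousand reads, 10 planted targets over ~60
transcripts, 5000 null features for type-I calibration, 500 random
duplexes and 200 random 2-kb sequences for the brute-force oracles, and
60 null runs for family-wise error control.

Known limitations: the common-dispersion model has no tagwise shrinkage,
so features with atypical variability are tested at the shared value; the
duplex search is exhaustive within `± max_bulge` windows but does not
model G:U-rich asymmetric loops beyond the gap penalty; MFE values are
model-internal quantities; and the permutation null conditions on the
observed transcript, not on the transcriptome-wide search space.
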