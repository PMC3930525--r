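---
title: "kakspipe: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kakspipe: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kakspipe)
```

`kakspipe` implements a comparative molecular-evolution workflow for de novo
transcriptome assemblies: reciprocal translated homologue pairing, codon
alignment, Nei–Gojobori Ka/Ks estimation, tiered SNP discovery from
pileups, and regression-based tests of whether sex- and morph-biased gene
expression predicts relaxed or positive selection (the "developmental
decoupling" hypothesis: genes expressed in only a subset of individuals
each generation — one sex, or one male morph — experience weakened
purifying selection). This vignette records the models, the conventions
adopted where the underlying methods leave choices open, and the numerical
behaviour of the implementation.

## Translated search and reciprocal best hits

Two transcript sets are compared in protein space: every query/subject pair
is evaluated over all 36 combinations of the six reading frames, each
combination scored by an optimal Smith–Waterman local alignment (BLOSUM62,
affine gap open 11 / extend 1, via `Biostrings::pairwiseAlignment`). Two
residues outside the twenty amino acids arise in six-frame translation and
are scored specially: `*` (stop) at −4 against everything, `X`
(codon containing `N`) at 0 against everything; in the single conflicting
cell (`*` vs `X`) the X-neutrality wins. Only the best-scoring frame
combination per sequence pair is retained — downstream trimming uses one
overlapping region per pair, so secondary HSPs would be unused.

Reported E-values use the Karlin–Altschul form
$E = K m n e^{-\lambda S}$ with fixed gapped-BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$), where $m$ and $n$ are the summed protein
frame lengths of query and subject. This is an explicit approximation —
composition-based adjustments and sum statistics of a full BLAST
implementation are out of scope — and a raw-score threshold can be used
instead (`min_score`). The default reporting threshold is `max_evalue =
1e-5`, the conventional transcriptome-screening stringency.

Pairing is by reciprocal best hit: `(a, b)` is emitted only if `b` is `a`'s
single best subject and `a` is `b`'s single best subject. An exact
raw-score tie between distinct best subjects is treated conservatively: the
sequence is dropped from pairing, with a warning. Tie behaviour is a
genuine design choice (best-hit methods rarely specify it); dropping never
fabricates a homologue, and ties are essentially confined to degenerate
inputs. The result is a matching — no transcript occurs in two pairs.

## From pair to codon alignment

The A→B hit defines the overlapping region. Each sequence is cut to its hit
coordinates, re-oriented to the hit frame's strand, and snapped to codon
boundaries of that frame by advancing the start and receding the end —
never extending beyond the hit, so no unaligned sequence is fabricated.
Whether to trim to the A→B hit, the B→A hit, or their intersection is
underdetermined; the A→B hit is used and recorded in the pair's origin
metadata. Fragments shorter than one codon after snapping discard the pair
with reason code `short_after_snap`.

The two in-frame fragments are translated and globally aligned
(Needleman–Wunsch, same scoring; end gaps penalised). Because exactly two
sequences are aligned per pair, a pairwise optimum replaces a multiple
aligner; externally aligned protein FASTA can be supplied instead
(`aligned_proteins`) for replication against a specific external tool.
Codons are then threaded back through the protein alignment
(PAL2NAL-style): each residue column becomes its source codon, each gap
residue `---`, and the threading refuses to proceed if a protein row does
not equal the translation of its fragment (that would indicate an upstream
bug, not bad data).

Cleaning removes every column in which either row holds a stop codon (TAA,
TAG, TGA) or a *nonsense codon*, read broadly as any codon containing a
character outside `{A,C,G,T}` and therefore untranslatable. Cleaning is
idempotent. Finally, alignments with fewer than `min_aln_bp = 150`
comparable bp are discarded: distances from under ~50 codons are too noisy
for a stable ratio. Gap columns are excluded from this count, since only
ungapped codon pairs contribute sites or differences.

## Nei–Gojobori Ka/Ks

For each sense codon, the synonymous site count is the fraction of its nine
single-nucleotide neighbours that preserve the amino acid, summed per
position and divided by 3, so that $s + n = 3$ exactly; a change that
produces a stop codon counts as nonsynonymous (e.g. TGG has $s = 0$).
Between two codons differing at $k$ positions, the $k$ single-base steps
are classified along each of the $k!$ orderings and averaged; orderings
passing through a stop codon are excluded, and if every ordering is
excluded, all are used (the fallback keeps $s_d + n_d = k$ exact in all
cases). Site totals are averaged between the two rows, the standard
convention. Proportions $p_S = S_d/S$ and $p_N = N_d/N$ are corrected with
Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, which is undefined
at $p \ge 0.75$: such estimates carry status `saturated_s`/`saturated_n`
and no ratio. `Ks = 0` with any `Ka` gives status `ks_zero` and an `NA`
ratio (matching how such homologue pairs are conventionally tabulated,
rather than reporting infinity); `Ka = 0` with `Ks > 0` gives ratio 0.
Classification: `positive` above 1, `purifying` below, `neutral` at exactly
1, `undetermined` otherwise.

Per-codon site counts and the full 64×64 pathway table are computed once
per session and cached; the test suite checks both against an independent
brute-force oracle that enumerates neighbours and permutations literally
(all 61 codons and all 61×61 sense pairs, tolerance 1e−12).

Model-based estimators (Goldman–Yang, YN00) and
transition/transversion-weighted counting are intentionally out of scope:
the counting estimator is the method this workflow standardises on.

## The synthetic testbed and what it shows

`simulate_cds` draws uniform random sense codons after an initial ATG.
`evolve_pair` gives each descendant lineage Poisson(divergence × length/2)
proposed point mutations at uniform random sites and alternative bases —
the same mutational null the counting estimator assumes. Proposals creating
a stop are rejected; synonymous proposals are always accepted and
nonsynonymous ones with probability ω (inverted for ω > 1). This is a
deliberate simplification relative to a continuous-time codon model: it is
dependency-free, exactly analysable, and sufficient for validating the
estimation chain. Divergence is split equally between the lineages, the
neutral default when branch asymmetry is unknown.

One structural property deserves record. Of the 549 single-nucleotide
changes available from the 61 sense codons, 23 (≈4.2%) create a stop. The
estimator counts these as nonsynonymous *opportunity* (sites), but coding
sequence can never *realize* them, so Ka computed against the true
alignment is depressed by ≈5%. Measured at 300 codons, divergence 0.2, 200
replicates per level: threading the true (identity) alignment gives mean
ratios 0.0995 / 0.4722 / 0.9585 at ω = 0.1 / 0.5 / 1.0 — the deficit is
visible at the upper levels. Through the package's standard chain (global
protein alignment, then threading), slight local realignment noise inflates
Ka marginally and offsets the deficit: means 0.0987 / 0.5036 / 0.9845,
each within two standard errors of ω. This is a known property of
counting estimators with the stop-as-nonsynonymous convention, not a bug;
both measurements are reproduced by the acceptance checks and this is the
basis on which the ω-recovery validation uses the standard chain.

What the generators do *not* emulate: indels (alignments of simulated pairs
are gap-free by construction, so threading fidelity under gaps is exercised
separately with designed cases), pyrosequencing flowgram error structure
(homopolymer miscalls are represented only through the planted-SNP truth
flags), assembly artefacts, and correlated evolution among genes. Passing
tests therefore validate the estimation machinery, not the upstream
assembly.

## SNP tiers

A pileup column (per-position A/C/G/T counts over an assembly contig)
yields a call only if: the second-most-frequent base is the single minor
allele considered, and the third-most-frequent base does not exceed the
noise ceiling `max(1, 1% of depth)` (columns above it are rejected as
multi-allelic — the workflow targets single-nucleotide differences; the
ceiling is configurable); depth and minor-allele frequency *strictly*
exceed the tier thresholds; the site has at least 50 bp of contig sequence
on each side (counted from the contig ends); and the maximal mononucleotide
run of the reference containing the site is at most 2 bp — the homopolymer
rule targeting the dominant 454-style error mode. Default tiers are
low (depth > 8, MAF > 15%), medium (> 12, > 20%) and high (> 15, > 25%).
The source material states the high-tier depth cutoff three ways (> 12,
> 15, > 16 in different places); the procedural-methods value (> 15) is the
default and all six thresholds are configurable. With ordered thresholds
the tiers nest: every high call is a medium call is a low call, and within
each tier transitions (A↔G, C↔T) plus transversions equal the call count.
MAF uses the full column depth; whether the original workflow divided by
mapper difference counts instead is not determinable, and full depth is the
reproducible choice.

## Rank test and the decoupling model

`mann_whitney` reports `W`, the first-sample U statistic — the number of
`(x, y)` pairs won by the first sample, ties counted one half — matching
the convention in which a rank-sum test's statistic is reported for the
first group. With no ties and $n_1 n_2 \le 400$ the two-sided p is exact
(doubled smaller tail of the exact U distribution); otherwise a normal
approximation with tie-corrected variance and continuity correction is
used, with p = 1 when the variance degenerates (all values tied).

The decoupling model is ordinary least squares of log(Ka/Ks) on
log(overall expression), alignment length, sequence length, number of
tissues with expression, log(sex bias), log(morph bias), and the product of
the two logged biases as the interaction, plus an intercept — eight
parameters, so residual df = n − 8. Two transform profiles exist because
descriptions of such models commonly disagree on whether the length
covariates are logged: the default `"methods"` profile logs only the ratio,
the biases and overall expression; `"log_lengths"` additionally logs both
lengths. The default is the profile consistent with length-effect
magnitudes of order 10⁻³ per bp (logging a length covariate while keeping
an estimate of that order would imply a negligible t, contradicting the
strong length effects such models report). Ratio-zero rows cannot be
logged; they are excluded and counted by default, with an optional floor
mode substituting half the smallest positive ratio. Non-positive values
under any log are likewise excluded and counted. Exact collinearity is
refused with the offending terms named. Quadratic bias terms are not
fitted: they are reported not to improve such models, and are out of scope.

Per-term partial r² is $t^2/(t^2 + \mathrm{df})$, algebraically identical
to the drop-one-term comparison $(SSE_{reduced} - SSE_{full}) /
SSE_{reduced}$; the suite verifies the identity against refits to 1e−10.

The expression-table generator draws log-normal biases and overall
expression (log-scale SD 1, overall expression centred at e³ arbitrary
array units), tissue counts uniform on 1–11, sequence lengths uniform on
150–3000 bp with alignment lengths uniform up to the sequence length —
documented defaults, all overridable, standing in for empirical covariate
distributions that are only available by download. When `noise_sd` is not
given it is calibrated from the realized linear predictor so the fitted
model's expected adjusted r² equals a target (defaults 0.105 and 0.150 for
the two preset effect-size sets, the explanatory power typical of such
models); coefficient presets at n = 761 and n = 249 carry the two printed
morph-bias effect sizes (0.230 and 0.384) used for recovery checks.

## Orchestration and determinism

`run_config` validates a flat key=value configuration (unknown keys
rejected, referenced paths must exist, thresholds positive); the
INI-style file form is echoed verbatim into the run manifest for
provenance. Stage runners write TSV reports, per-pair aligned codon FASTA,
a minimal VCF v4.2 for SNP calls, and a `manifest.json` whose counts
reconcile (pairs in = kept + discarded by reason). Invalid inputs signal
condition class `kakspipe_config_error`, structurally valid runs with
nothing to report signal `kakspipe_empty_result`; the shell wrapper maps
these to exit codes 2 and 3. Reruns under the same configuration and seed
are byte-identical. Generators take explicit seeds and restore the caller's
RNG state.

## Problem sizes used in validation

The suite validates at sizes chosen to keep a full run in a few minutes on
one CPU while leaving estimates well-powered: alignment scores against an
exhaustive DP oracle on sequences up to length 6 over a reduced alphabet;
the full 61 and 61×61 NG86 count tables against literal enumeration;
ω recovery with 200 replicate pairs of 300 codons per level; RBH recovery
over 20 seeded sets of four 60-codon pairs (≥95% recovery, zero false
pairs observed); rank-test exactness by full enumeration for all
$n_1, n_2 \le 7$; GLM coefficient recovery at n = 761 and n = 249 with CI
coverage checked over 100 simulations; SNP truth recovery on planted
deterministic pileups. Known limitations: the search is a desk-scale
stand-in, not indexed for thousands-of-contigs databases; only pairwise
alignment is provided; indel-containing SNPs and genotype likelihoods are
out of scope; and the ~5% stop-convention deficit of the counting estimator
at high ω (documented above) applies to any use of the true-alignment
route.
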