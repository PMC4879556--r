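---
title: "Discriminative co-expression networks with promoter motif and GO analysis: methods"
author: "discoex authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{discoex methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoex)
```

# The problem

Large public expression compendia mix thousands of hybridizations from
unrelated tissues, genotypes and treatments. A co-expression network built
over such a mixture dilutes condition-specific co-regulation. The
workflow implemented here sharpens the compendium *before* the network is
built: arrays are kept only if a positive gene list — genes with validated
roles in the process of interest (here, root hair differentiation in
*Arabidopsis* under phosphate starvation) — behaves extremely on them.
A Pearson-thresholded co-expression network over a candidate
(process-responsive) gene set is then computed on the selected arrays
only, its connected components become gene clusters, and two orthogonal
filters annotate the clusters: de-novo promoter motif discovery plus
comparison to known transcription-factor binding sites, and GO-term
over-representation.

# Stage by stage

## Normalization

Expression matrices are quantile-normalized (`quantileNormalize()`, via
`limma::normalizeQuantiles` with tie-averaging) on the log2 scale. The
downstream steps are rank-based (extreme-quantile membership) or
correlation-based, so what matters is that array distributions are
comparable; quantile normalization is the standard choice for single-dye
array compendia. Missing or non-numeric rows are dropped at ingestion,
never imputed, because imputation would bias both ranks and correlations.

## Discriminative array selection

For an array with $n$ genes, the pooled extremes are the $k$ highest and
$k$ lowest values with $k = \lfloor q\,n \rfloor$ (default $q = 0.25$:
the 25% highest or lowest signals). An array's score is the fraction of
positive-list genes (restricted to genes present in the matrix) that land
in the pooled extremes, and the array is selected iff score $> f$
(default $f = 0.70$, strict, reading "more than 70%" literally).
Boundary ties are resolved by ranking on (value, gene id): the low tail
prefers lexicographically smaller ids, the high tail larger ones, which
makes selection reproducible across platforms.

Because the pooled extremes cover a fraction $2q$ of each array, a null
array gives each list gene a $2q$ chance of being "extreme"; with
$q = 0.25$ the null score is centred on $0.5$ and the false-positive
probability of an array is the upper tail of a hypergeometric
distribution. With a 20-gene list this is
$P(X \ge 15) \approx 0.016$ per array — about 1.4 spurious selections per
100-array compendium — whereas a 56-gene list (the scale used in the
original root-hair study) pushes it to $\sim 10^{-3}$. Desk-scale
benchmarks of the selection step therefore achieve perfect sensitivity
but not a literal specificity of 1; the acceptance suite reports the
honest number.

A second, subtler property showed up in testing: selection is biased
toward arrays in which co-expression-module latent factors are *weak*,
because strong module excursions crowd the extreme quantiles and push
list genes out of them. The effect is negligible at 200 genes but visible
at 80, which is why the shipped test fixtures use the default scale.

## Co-expression network and clusters

Edges connect candidate-gene pairs with sample Pearson correlation
$r \ge r_0$ over the selected arrays (default $r_0 = 0.90$, signed and
inclusive: strong *negative* correlation does not create an edge).
Zero-variance genes are excluded and recorded. Clusters are the connected
components with at least `minClusterSize` members (default 5 — the
original analysis reported only its "five larger clusters", implying a
size cutoff), labelled C0, C1, … by decreasing size with ties broken by
the smallest member id; smaller components form an explicit remainder, so
clusters plus remainder always partition the node set. Connected
components are the minimal clustering assumption consistent with a
thresholded graph; no soft-threshold (WGCNA-style) machinery is implied.

## Promoters

Core promoters are the up-to-1000-bp window ending immediately before the
annotated gene start (gene-level 5' end; no TSS refinement), truncated
where any other gene body intrudes — strand-agnostic, because a promoter
should not run through a neighbouring transcription unit regardless of
its orientation — and dropped below 50 bp. Minus-strand promoters are
reverse-complemented so every promoter reads 5'→3' toward its gene.
Internally all coordinates are 0-based half-open; GFF3 1-based inclusive
coordinates are converted at the boundary. Repeat-masked (lowercase)
genome positions are kept in the sequence for coordinate bookkeeping but
flagged: they never host motif sites, never seed the motif search and
never match a consensus scan.

## Markov background

The null model for promoter sequence is an order-$k$ Markov chain
(default $k = 3$), trained by counting (context → base) transitions on
both strands with pseudocount $\alpha$ (default 0.01; $\alpha = 0$ gives
pure ML frequencies but can produce $-\infty$ log-probabilities on
held-out sequence, so a small positive default is safer). Orders
$0 \dots k$ are all stored so the first $k$ positions of a sequence are
scored with the matching lower-order chain. In practice such backgrounds
should be estimated from a large genome-wide upstream-sequence pool, not
from the handful of promoters being searched: a 20-carrier motif in 30
input promoters measurably inflates its own 3-mer context counts
(palindromic cores doubly so under both-strand counting) and partially
absorbs the signal. The synthetic promoter generator therefore returns
its generating chain as the ready-made background, playing the role of a
pre-calculated genome-wide model.

## ZOOPS motif discovery

The finder implements the zero-or-one-occurrence-per-sequence mixture:
for sequence $s$ with eligible windows $O_s$ (both strands; masked or
erased positions excluded),

$$P(s) \;=\; (1-\lambda)\,P_{bg}(s) \;+\;
  \frac{\lambda}{|O_s|} \sum_{(j,\sigma) \in O_s} P_{bg}(s)\,
  \frac{P(\text{window}_{j,\sigma} \mid \theta)}{P_{bg}(\text{window}_{j,\sigma})},$$

with $\theta$ the $w \times 4$ position probability matrix and $\lambda$
the per-sequence occurrence prior (initialized at $1/\sqrt{\#\text{seqs}}$,
re-estimated each M-step). EM maximizes the penalized likelihood with a
Dirichlet pseudocount of 0.01 per base; the recorded objective trace is
the penalized one, which the EM guarantee keeps non-decreasing
(tolerance $10^{-9}$ in the tests). Convergence is
$|\Delta \text{objective}| < 10^{-6}$ or 200 iterations.

Starting points: every distinct promoter substring of the current width
is enumerated (deterministically — no subsampling) and scored by a
closed-form estimate of its converged objective: assume the motif
sharpens to 0.9 per column and occurs exactly where the word occurs, so
$\hat\lambda$ = carrier fraction and the score adds the usual mixture
gain over carriers and the $\log(1-\hat\lambda)$ penalty over
non-carriers. The top `nRefine` (default 5) words per width run to EM
convergence. A cheaper stochastic variant (subsampled seeds scored by a
single E-pass) was tried first and discarded: it systematically ranked
single ultra-rare background words above genuinely recurrent planted
words. After convergence the winner undergoes phase-shift refinement
(slide $\theta$ one column left/right, re-run EM, keep improvements),
countering the well-known phase indeterminacy of window EM.

Sites are assigned one per sequence when the posterior occurrence
probability exceeds 0.5; accepted sites are erased (masked) before the
next of up to `nMotifs` (default 10) motifs is sought, and discovery
stops early when no candidate beats the background. Widths 6–12 are
searched by default; note that the raw log-likelihood-ratio objective
grows with width, so when widths compete the widest informative motif
tends to win — the benchmark fixes $w = 8$ to keep truth comparisons
crisp.

## Motif annotation

Discovered motifs supported by fewer than 4 distinct genes (ZOOPS site
list, one site max per gene — discovery-time support) are discarded.
Retained motifs are compared to a known-TFBS library (minimal MEME motif
format) Tomtom-style: both orientations, all offsets with at least 4
aligned columns, alignment score = the **sum** of per-column Pearson
correlations between probability columns. The sum, not the mean, is used
deliberately: with a mean, a coincidental 4-column overlap against a
column-shuffled target can tie a full-width self-match, which breaks the
self-match sanity property; summing makes longer faithful overlaps
dominate, as in Tomtom's own summed column scores. Significance is an
empirical p-value against `nShuffles` (≥ 100, default 200) column-order
shuffles of the target, $p = (1 + \#\{\text{shuffled} \ge
\text{observed}\})/(1 + n)$, seeded and reproducible. No analytic
column-score distribution is attempted. Candidates are emitted ranked;
the manual curation step of the original analysis is out of scope.

IUPAC consensus scanning (`scanConsensus()`) finds exact degenerate
matches on the forward strand and, for the reverse strand, matches of the
reverse-complemented pattern reported with strand `-`. The no-overlap
rule ("noov") is greedy left-to-right per strand: after a match at
$[i, i+w)$ the next accepted match starts at $i + w$. A useful sanity
relation, asserted in the tests: scanning rc(pattern) on rc(sequence)
mirrors positions and preserves strand labels, while scanning the pattern
itself on rc(sequence) returns the same matches strand-swapped.

## GO enrichment

Per cluster, every term with at least one universe gene and at least one
cluster gene is tested with the right-sided hypergeometric test
($P(X \ge k)$ via `phyper`), and the Holm (Bonferroni step-down)
correction is applied across the tested terms of that cluster
(`p.adjust(method = "holm")`). The universe is explicit — all genes
carrying at least one annotation — rather than tool-internal; GO-graph
ancestor propagation is not performed (flat annotation is the testable
minimum, and the annotation format carries whatever propagation the user
has applied upstream). Holm controls the family-wise error rate, which
the null benchmark confirms empirically (≤ 5% of null clusters show any
adjusted p < 0.05, checked against a 7% ceiling over 100 simulations).

# The synthetic generators

`simulateExpression()` emulates the compendium at desk scale: 200 genes ×
100 arrays, i.i.d. N(0, 1) background on a normalized log-like scale,
three single-latent-factor modules of 20/15/10 genes at within-module
correlation 0.95, a 20-gene positive list, and 10 discriminative arrays
in which every list gene is shifted by ±4 SD (sign fixed per gene). The
single-factor model is the simplest generative mechanism with a tunable
within-module Pearson correlation; the shift is applied on the
normalized scale because selection runs after normalization.

`simulatePromoters()` draws 30 sequences of 500 bp from a random order-3
Markov chain whose conditionals are Dirichlet(8) draws — mild
compositional bias, as in real upstream regions, rather than a
pathologically spiky chain — and plants one exact instance of an 8-bp
consensus (default CACGTGGC, a CRE reported for the auxin/chromatin
cluster of the motivating study) at a uniform offset in each of 20
carriers, resolving degenerate positions uniformly per instance.

`simulateGoAnnotation()` builds 50 decoy terms of uniform size 10–40 over
a 500-gene universe and, where requested, planted terms containing 90% of
a module plus uniform fill.

What the generators do *not* emulate: probe-level artifacts, batch
effects, correlated (non-i.i.d.) backgrounds between modules, overlapping
or nested GO terms (a real DAG), TSS uncertainty, and promoters with
shared regulatory grammar beyond a single planted word. Passing the
benchmarks therefore demonstrates correctness of the machinery under the
stated statistical model, not performance on real compendia.

# Orchestration and reproducibility

`runPipeline()` composes the stages from one validated configuration
(`pipelineConfig()` / `readPipelineConfig()` for YAML); each study
parameter is a named, defaulted field, so the shipped defaults *are* the
study settings (0.25, 0.70, 0.90, 1000/50 bp, 10 motifs of width 6–12,
order-3 background, ≥ 4-gene support). All randomness flows from one
master seed through fixed per-stage derivations, outputs carry no
timestamps, and numeric tables are written at full precision with
17-significant-digit formatting, so a rerun with the same configuration
is byte-identical — asserted file-by-file in the test suite. Each stage's
output is an ordinary TSV/GraphML/MEME/JSON file that reloads through the
package's own readers.

Problem sizes used by the shipped checks: 20-seed sweeps for selection
and module recovery at the 200 × 100 default scale; 20 random instances
(≤ 50 genes) against the brute-force network oracle; the full
hypergeometric grid N ≤ 30; 1000 random vectors (Holm) and 1000 random
sequences (scanning); 20-seed motif recovery at 30 × 500 bp with width
fixed to the planted 8; 100 null simulations for the enrichment
type-I check; and a double pipeline run on the default fixture with 2
motifs at width 8 for the determinism check.

# Known limitations

* Connected components are a deliberately minimal clustering rule; dense
  thresholded graphs can chain distinct modules through single edges.
* The LLR objective is not width-normalized, so mixed-width searches
  favour wide motifs; an information-content-per-column criterion would
  be a natural extension.
* The Tomtom-style empirical p-value is coarse (resolution
  $1/(1+n_{\text{shuffles}})$) and column shuffling preserves column
  composition only, not inter-column dependence.
* Gene support for discovered motifs counts ZOOPS sites, capping support
  at one site per gene; re-scanning promoters with the final PWM would
  count multiple sites and can differ near the ≥ 4-gene threshold.
* The selection stage's false-positive rate is a property of the list
  size and $q$, not of the implementation; small positive lists cannot
  reach literal specificity 1 on null compendia.
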