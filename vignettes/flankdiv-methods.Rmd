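---
title: "flankdiv: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{flankdiv: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flankdiv)
```

## The idea

Mobile genetic elements (MGEs) are defined, algorithmically as much as
mechanistically, by their bounding sequences: a transposon terminus is a
constant sequence that sits next to a *different* flanking sequence at every
insertion site.  Diversity-generating mechanisms such as CRISPR arrays show
the same signature on both sides of the repeat, and cargo-gene hotspots
inside integrative and conjugative elements show it at the hotspot
boundaries.  flankdiv turns this observation into a reference-free
statistical scan: stream the raw reads, and for every k-mer (**anchor**)
ask whether the k-mers immediately upstream and downstream of it
(**targets**) are more diverse than background biological variation (point
mutations) and technical noise (sequencing error) can explain.

No reference genome, assembler, or annotation participates in the
detection; annotation enters only as an optional post-hoc classification of
the output.

## Streaming model

Reads are processed sequentially with a stride-1 sliding window.  For an
anchor starting at position $p$ (0-based) in a read, the downstream target
occupies $[p+k+g,\, p+2k+g)$ and the upstream target $[p-k-g,\, p-g)$; each
is recorded only when it fits inside the read.  Defaults are $k = 27$ and
gap $g = 0$: 27 balances memory against sequence specificity, and with
150 bp reads every anchor away from the read edges contributes a pair in
each direction.  Reads are used exactly as written: there is **no
reverse-complement canonicalisation**, because a 5' and a 3' terminus are
genuinely different anchors and collapsing strands would mix their flank
distributions.  Windows containing an ambiguous base (`N`) are skipped in
either role, and quality strings are ignored.  Paired-end data are simply
two FASTQ files contributing to one sample, jointly capped (default
2.5 million records per sample, trading power against runtime).

## Clustering targets on the fly

Each anchor keeps two independent target dictionaries (upstream,
downstream); independence matters because MGE termini are one-sided while
repeats are two-sided.  A new target is compared against the existing
cluster keys *in insertion order* and recruited to the **first** key whose
Jaccard similarity over 7-mer sets exceeds 0.2 (strict `>`):

$$\mathrm{JS}(\mathcal X_1, \mathcal X_2) =
  \frac{|\mathcal X_1 \cap \mathcal X_2|}{|\mathcal X_1 \cup \mathcal X_2|},$$

where $\mathcal X_i$ is the *set* of the 21 overlapping 7-mers of target
$i$ (duplicates collapsed).  On recruitment the cluster's key is replaced
by the new target with probability 0.5, so the key random-walks across the
cluster's members instead of being pinned to whichever arrived first.
Otherwise a new cluster is opened.  First-match scanning is a deterministic
O(C) rule; since any key above the threshold certifies the target is
"nothing new", which matching cluster absorbs it has no effect on the test
statistic $C_N$, only on key bookkeeping.

The 0.2 threshold is a compromise: low enough that genuinely diverse
flanks keep opening clusters, high enough that single-nucleotide variants
and sequencing errors of one flank (JS about 0.5 for one substitution,
about 0.9 for a 1 bp shift) are absorbed rather than inflating the
dictionaries.  The test below calibrates its null *from the data at the
chosen threshold*, so validity does not depend on this choice — only power
and memory do.

## Admission control and retention

Testing requires at least $N_{\min} = 25$ targets per direction, and
collection stops at $N_{\max} = 75$ — enough resolution for the tail test
while letting the stream skip saturated anchors entirely (an anchor closed
in both directions costs one hash lookup).  Two probability rules keep the
dictionary from filling with hopeless anchors:

* **Admission.**  With $L$ total records and $p_{\min} = N_{\min}/L$, an
  anchor first seen after $l$ records has had $l$ chances to produce a
  target; once $(1-p_{\min})^l < 0.01$, any newly appearing anchor is too
  late to plausibly reach $N_{\min}$, and no new anchors are admitted.
  Existing anchors keep accumulating.
* **Retention.**  After admission closes, every $10^5$ records each
  anchor's end-of-file target count is projected as
  $\mathrm{Binomial}(L, x/l)$ (x targets seen in l records), evaluated with
  the normal approximation (continuity-corrected at the $N_{\min} - 0.5$
  boundary) for speed; at the operating point
  ($L \sim 10^6$, $x/l \sim 10^{-5}$) it agrees with the exact survival
  function to well under 0.05.  Anchors whose probability of reaching
  $N_{\min}$ is below 0.5 are evicted.  Eviction uses the **max over the
  two directions**: an anchor viable in either direction may still be a
  one-sided terminus, and keeping it costs little.  An anchor that already
  holds $N_{\min}$ targets in some direction is never evicted.

The sweep schedule (every $10^5$ records, only after admission has closed)
is a cost choice: per-read evaluation would dominate runtime for no
statistical benefit.

## The hyper-variability test

Let $X_n \in \{0,1\}$ indicate that the $n$-th target opened a new cluster,
and $C_N = \sum_n X_n$.  Under the null (no hyper-variability), the $X_n$
are modelled as independent Bernoulli$(p_n)$ with rank-specific
probabilities, so $C_N \sim \mathrm{PoissonBinomial}(p_1,\dots,p_N)$.  The
$p_n$ are estimated by pooling all trajectories in the store:

$$\hat p_n = \frac{\sum_m x_{m,n}}{\sum_m \mathbf 1\{N_m \ge n\}}.$$

This works because the overwhelming majority of anchors are nowhere near a
hyper-variable region; the few that are only make the test conservative.
Three pooling decisions, made here because the estimator leaves them open:

* Upstream and downstream trajectories are **pooled**: the cluster-forming
  process is direction-symmetric, and pooling doubles the calibration
  sample.
* Trajectories shorter than $N_{\min}$ still contribute to the ranks they
  reach (the indicator in the denominator handles ragged lengths); they are
  never *tested*.
* Only anchors surviving to the end of the stream contribute (evicted
  anchors are gone, by construction of the streaming pass).

The p-value is the upper tail $P[C_N \ge c]$ of the Poisson-Binomial,
computed exactly by discrete-Fourier inversion of its characteristic
function with the $(N{+}1)$-th root of unity $R = e^{2\pi i/(N+1)}$:

$$P[C_N = j] = \frac{1}{N+1} \sum_{l=0}^{N} R^{-lj}
  \prod_{n=1}^{N}\bigl(1 + (R^l - 1)\hat p_n\bigr),$$

implemented as one FFT over the $N+1$ evaluation points.  For $N > 30$ the
product is evaluated as a sum of complex logarithms; each factor has
modulus at most 1 (it is a convex combination of $1$ and $R^l$), so the
direct product cannot overflow and the two paths agree to machine
precision — the log path simply guards very long products against
underflow.  The real part is taken, per-mass values are clamped at 0 and
tails at $[0,1]$, which also makes the tail monotone in $c$ by
construction.  The suite verifies the inversion against direct DP
convolution to $10^{-9}$ absolute and against the closed-form binomial
survival function when the $\hat p_n$ are constant.

**Effect size.**  $\alpha = \log_2\!\bigl(C_N / E[C_N \mid N]\bigr)$ with
$E[C_N \mid N] = \sum_{n \le N} \hat p_n$ — the mean of the
Poisson-Binomial null, the only expectation consistent with the test's own
model.  $\alpha$ is coverage-relative, so it ranks a highly diverse CRISPR
array above a weakly mobilised element at the same $N$.

**Multiple testing.**  Tests are performed per anchor × direction and $m$
counts both directions.  The correction is a memory-efficient
Benjamini-Hochberg: only $m$ and the p-values $\le 0.1$ are kept; retained
p-values are ranked ascending and adjusted as $q^{(i)} = p^{(i)} m / i$,
and anchors with $q < 0.1$ are reported.  The implementation adds the
standard step-up monotone enforcement
$q^{(i)} \leftarrow \min_{j \ge i} p^{(j)} m / j$ (capped at 1) because the
raw ratios can invert order when p-values are nearly tied; when no
enforcement is needed the two coincide, and the raw behaviour remains
available via `monotone = FALSE`.  Overlapping k-mers make neighbouring
p-values positively dependent, a regime in which BH still controls FDR.

## Post-processing

* **Anchor deduplication.**  Significant anchors (any direction) are
  clustered by Levenshtein edit distance with every point a core point
  (`eps = 2`, `min_samples = 1`) — exactly the connected components of the
  $\le 2$-edit graph, computed here via `utils::adist` and igraph
  components, with transitive chaining and no noise points.
* **Representatives.**  Per cluster and direction, the member with maximal
  $\alpha$ among members tested in that direction; exact ties break
  lexicographically so runs are reproducible.
* **CRISPR candidates.**  A cluster is flagged when it is significant in
  both directions, $\tfrac12(\alpha_u + \alpha_d) \ge 3.5$ for its
  representatives (inclusive boundary), and a representative occurred more
  than once within a single read — the tandem-array signature.  "A
  representative" means either of the two; the filter is a screen, and
  requiring both would silently drop clusters whose up/down representatives
  differ.
* **Annotation.**  Supplied 12-column tabular alignments are classified by
  the anchor's best e-value.  The bands are annotated $e \le 0.01$,
  questionable $0.01 < e < 0.25$, unannotated $e \ge 0.25$ (or no hit);
  both boundaries are assigned to the more confident side below and the
  less confident side above, resolving the overlap a verbal specification
  of three bands leaves open.  Running the aligner and curating databases
  is the user's concern.
* **Covariate regression.**  Across samples,
  $C \sim \mathrm{Binomial}(N, p(\mathbf x))$ with
  $p(\mathbf x) = (1 + e^{-\boldsymbol\beta^\top \mathbf x})^{-1}$, fitted
  by `stats::glm`.  Separation is reported as non-convergence when any
  fitted log-odds exceeds $\pm 15$ (the fitted probability is then within
  $3\times10^{-7}$ of 0 or 1, which finite binomial data cannot support at
  a finite MLE); coefficients are still returned with a warning.
* **Across-sample target clustering.**  Greedy: the highest-total-count
  unassigned target seeds a cluster and recruits everything with
  $\mathrm{JS} > 0.2$; repeat until empty.  Count ties break
  lexicographically.
* **Assembly seeds.**  Clusters significant in exactly one direction — the
  MGE-terminus signature — are written as FASTA for external seed-based
  assembly; bidirectional (repeat-like) clusters are excluded.

## The planted-MGE simulator

The simulator is the package's benchmark substrate and stands in for real
datasets.  Its generative model is deliberately transparent, with every
parameter in `sim_config()`:

* a uniform-random ancestor genome (default 100 kb) and element (1.5 kb);
* **ancestral scenario**: `copy_number` copies inserted at well-separated
  uniform loci in the ancestor, then each of `n_genomes` descendants
  diverges at the MIR;
* **active scenario**: one ancestral copy, each descendant diverges at the
  MIR and then receives `activity` further pristine copies at loci drawn
  independently per genome;
* MIR events are 9:1 substitutions:indels with geometric(0.5) indel lengths
  (mean 2), a generic bacterial-divergence caricature;
* fixed-length reads (150 bp) at the configured depth, start positions
  uniform, strand flipped with probability 0.5 (reverse complement), and
  uniform substitution errors (0.1%) — the strand mixing deliberately
  stress-tests the no-canonicalisation design.

Insertion points keep $2k$ bp of separation from each other and from
existing junctions so each copy's flanks are genuinely independent
sequence; coordinates are tracked through indels so truth stays exact.

**Truth labels.**  The positive set contains, for every element copy in
every (post-mutation) genome, the k-mer occupying the element's **terminal
k bases** at each junction, plus reverse complements (reads come from both
strands and plus- and minus-strand anchors are distinct k-mers).  This is
the minimal, signal-carrying definition: k-mers *straddling* a junction are
copy-specific (they almost never recur, hence are never tested), and
k-mers deeper inside the element have outward targets that share most of
their sequence across insertion sites, which the 0.2 recruitment threshold
deliberately absorbs.  A looser window-overlap labelling
(`positive = "proximal"`) is available for sensitivity analysis.
Detection is scored as rank-based ROC AUC (Mann-Whitney with mid-ranks)
over all tested anchors, scored by $-\log_{10} q$ (dropped q-values score
as $q = 1$) or by $\alpha$.

**What the simulator does not emulate** — and therefore what passing
benchmarks do not certify on real data: quality-dependent and
context-dependent error profiles, paired-end fragment structure, GC and
coverage bias, metagenomic abundance mixtures, repeat families beyond the
single planted element, and target-site duplications.  The benchmark
demonstrates the statistical machinery recovers planted termini under
honest divergence and strand mixing; real-sample performance rests on the
calibrated-null design, not on these simulations.

## Problem sizes and numerical choices

The test suite runs the benchmark once at full scale — active scenario,
100 kb genome, 1.5 kb element, `activity = 20`, 10 genomes at 30X
(about 260k reads, about 200k tested anchor-directions) — where the AUC
criterion is $\ge 0.99$; unit and property tests use reduced scales
(8–20 kb genomes, 5–30X) chosen to keep the default suite in a couple of
minutes while leaving every rule observable.  Null calibration is checked
with 5000 simulated trajectories at $N = 75$ (empirical
$P[p \le 0.05] \in [0.03, 0.07]$, the slack reflecting the discreteness of
$C_N$), and FDR control with an all-null run of i.i.d. random 27-mer
targets.

Numerical conventions, in one place: recruitment and greedy clustering use
strict `>` at JS = 0.2 (a JS of exactly 0.2 opens a new cluster); the
CRISPR effect-size boundary 3.5 is inclusive; q-values are capped at 1;
tails are clamped to $[0,1]$; all similarity values are exact small-set
ratios so threshold comparisons are not at the mercy of accumulated
floating error; every tie that could make output order ambiguous
(representatives, greedy seeds, cluster ids, result rows) breaks
lexicographically; and one seeded RNG drives a whole run in stream order,
so a seed plus an input yields byte-identical outputs.

## Limitations

Anchors are exact k-mers: a terminus mutated inside the anchor window is a
different anchor and must reach $N_{\min}$ on its own (edit-distance
clustering of the *output* mitigates, but does not remove, this).  The
independence assumption across $X_n$ ignores the mild dependence induced
by key replacement and by overlapping reads; the empirical null absorbs
most of this in calibration.  Single-sample design: cross-sample inference
happens only through the merge utilities and the covariate regression.
Memory is linear in surviving anchors; extreme libraries may need a lower
`max_records` or `Nmax`.
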