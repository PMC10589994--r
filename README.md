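# flankdiv

Reference-free detection of k-mer anchors with statistically hyper-diverse
flanking sequence in raw sequencing reads — the signature of mobile genetic
element (MGE) termini, CRISPR direct repeats, and cargo-gene hotspots.

## Who this is for

Microbial genomicists and metagenomics researchers who want to find
transposon/IS termini, CRISPR repeats, or unannotated hyper-variable loci
**without** a reference genome, an assembler, or annotation heuristics —
including organisms and communities for which none of those exist.  The
input is a FASTQ sample; the output is a ranked, FDR-controlled table of
anchor k-mers with effect sizes, plus deduplicated representative anchors,
CRISPR-repeat candidates, and assembly seeds.

## The statistic

For every 27-mer anchor the stream records the 27-mer targets immediately
upstream and downstream of each occurrence, clustering targets on the fly:
a target joins the first cluster whose key exceeds Jaccard similarity 0.2
over 7-mer sets, otherwise it opens a new cluster.  With `X_n` indicating
that the `n`-th target opened a cluster, the null model is
`X_n ~ Bernoulli(p_n)` independently, so the cluster count is
Poisson-Binomial:

    C_N ~ PoissBin(p_1, ..., p_N),      p_n estimated by pooling all anchors:
    p_hat_n = sum_m x_{m,n} / sum_m 1{N_m >= n}

The p-value is the exact upper tail `P[C_N >= c]`, computed by
roots-of-unity inversion of the characteristic function; p-values are
corrected with a memory-efficient Benjamini–Hochberg procedure (keep `m`
and the p-values below 0.1 only; `q_i = p_i * m / i`), and each
anchor/direction gets an effect size `alpha = log2(C_N / E[C_N | N])`.
Anchors with `q < 0.1` are deduplicated by edit-distance clustering
(`eps = 2`), and per-direction representative anchors maximising `alpha`
are reported.  CRISPR-repeat candidates are clusters with bidirectional
significance, `0.5 * (alpha_u + alpha_d) >= 3.5`, and an anchor seen more
than once within a read.

See `vignettes/flankdiv-methods.Rmd` for the full model, the admission /
retention rules that keep the stream tractable, and every design decision.

## Worked example

Simulate an active element (one ancestral copy, eight fresh insertions per
genome across three genomes at 25X), run the pipeline, and score recovery
of the planted termini:

```r
library(flankdiv)

cfg <- sim_config(genome_len = 2e4, element_len = 800, activity = 8,
                  n_genomes = 3, coverage = 25, seed = 11)
sim <- simulate_active(cfg, out_dir = "sim")
run <- flankdiv_run(sim$fastq, seed = 12)
print(run)
#> flankdiv run: 13599 reads; 33327 tests; 691 retained (p <= 0.1 );
#>   71 significant (q < 0.1 ) in 4 anchor clusters; 0 CRISPR candidate cluster(s)

res <- run$results
head(res[order(res$q_value), c("anchor","direction","N","C_N","q_value","alpha")], 3)
#>                           anchor direction  N C_N      q_value    alpha
#> 1276 AAGCTTGAGCTCGAACGCGCGTTATGG        up 75  15 3.029248e-12 3.738493
#> 1794 AATGACTACCTACCGCAACCCTATTGG        up 75  15 3.029248e-12 3.738493
#> 2584 ACCACCGACCATAACGCGCGTTCGAGC      down 75  14 3.029248e-12 3.638957

ev <- evaluate_auc(run$results, sim$truth)
#> AUC = 0.9988 over 20956 anchors (4 true terminus k-mers)
```

Reading the output: the top anchor collected `N = 75` targets whose
upstream flanks formed `C_N = 15` clusters where the background null
expects ~1.1 (`alpha = 3.7`, i.e. 2^3.7 ≈ 13-fold more diversity than
expected), at `q ~ 3e-12`.  It is in fact the planted element's terminal
27-mer (`sim$truth$kmers`), and the ROC AUC of the q-value ranking over
all ~21k tested anchors is 0.999.  On a real sample the same call is
simply `flankdiv_run("sample.fastq", output_prefix = "out", seed = 1)`,
which writes `out.results.tsv`, `out.clusters.tsv`, `out.seeds.fasta`,
`out.log` and `out.config`.  A command-line wrapper with `run`,
`simulate`, `evaluate` and `merge` subcommands lives in
`inst/cli/flankdiv.R`.

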