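# igkselect

Disentangling **generation** from **selection** in immunoglobulin kappa
light-chain (IGK) repertoires.

The kappa chain's CDR3 is formed by a V–J junction with no D segment, which
makes it the cleanest place to study how the naive B-cell repertoire is
shaped: out-of-frame (OF) rearrangements never code for a receptor and so
sample the raw VJ-recombination process, while in-frame productive (IF)
rearrangements have additionally passed selection. Comparing the two
ensembles quantifies selection.

`igkselect` is for computational immunologists who want that comparison as
a tested, reproducible pipeline:

* **Generation model** — a probabilistic recombination model
  `P(V,J) P(delV|V) P(delJ|J) P(ins)` with a first-order Markov model of
  inserted nucleotides, fitted to OF reads by EM over hidden recombination
  scenarios (`fit_generation_model()`), with an exact correction for the
  out-of-frame ascertainment of the sample. Per-sequence generation
  probabilities (Pgen) by exhaustive enumeration (`pgen_brute()`) or a
  forward dynamic program (`pgen_forward()`).
* **Selection model** — factorized selection factors
  `Q = q(V,J) · q_L · Π_i q_{i;L}(a_i) / z`, the fold change between
  post- and pre-selection feature probabilities, fitted by sequential
  iterative proportional fitting against a Monte-Carlo pre-selection
  ensemble (`fit_selection_model()`), with codon-level factors,
  length-averaged heatmap tables and `E_pre[Q] = 1` normalization.
* **Clone detection** — deterministic pipeline: ungapped terminal V/J
  assignment, grouping by clone-invariant keys, neighbor-joining trees,
  partition at a 4-mutation cutoff, one ancestor per clone
  (`detect_clones()`).
* **Statistics** — CDR3 length and molecular-mass contrasts
  (`sd(IF)/sd(OF) − 1`), F/Welch-t tests, Spearman correlation of log
  generation probability against log selection factor, per-amino-acid
  Wilcoxon signed-rank tests, codon-versus-amino-acid variance
  decomposition (`stats_report()`, `pq_spearman()`, `wilcoxon_by_aa()`,
  `codon_aa_variance()`).
* **Simulator** — fully annotated synthetic repertoires (gene-choice bias,
  deletion profiles, biased N insertions, frame classification,
  acceptance–rejection selection by Q, clonal families with point
  mutations) so every stage is testable without any external data
  (`simulate_pool()`, `simulate_clonal_families()`).

A packaged toy germline (8 V, 4 J, conserved-anchor annotations in the
FASTA headers) and a reference parameter set define the simulated study
conditions. See the vignette
(`vignettes/kappa-repertoire-selection.Rmd`) for the models, conventions
and limitations.

## Worked example

```r
library(igkselect)

g  <- load_germline(system.file("extdata", "toy_germline.fasta",
                                package = "igkselect"))
p  <- toy_generation_params(g)

## unselected (out-of-frame) pool -> generation model
of  <- simulate_pool(5000, p, g, frame = "out_of_frame", seed = 1)
gen <- fit_generation_model(of, g, d_max = 6, i_max = 10)
gen
#> VJ-recombination generation model
#>   genes: 8 V x 4 J; d_max = 6, i_max = 10
#>   fitted on 5000 reads (0 excluded), 38 EM iterations, converged
#>   logLik: -52934.795

## selected (productive) pool with glycine favoured, proline disfavoured
ifp <- simulate_pool(5000, p, g, frame = "productive",
                     selection = aa_factor_selection(c(G = 2, P = 0.5)),
                     seed = 2)
pre <- sample_pre_repertoire(gen, n = 25000, seed = 3)
sel <- fit_selection_model(ifp, pre, min_count = 20)
summary(sel)
#> Factorized CDR3 selection model
#>   granularity: amino_acid; L_max = 19; z = 0.9695
#>   defined factors: 24 (V,J), 6 lengths, 156 position cells
#>   fit: 26 sweeps, max marginal gap 9.88e-04 (converged); n_if = 5000, n_pre = 25000
#> Mean log selection factor by amino acid (over positions):
#>      G      W      N      E      H      A      I      L      V      D      S 
#>  0.805  0.149  0.131  0.108  0.063  0.034  0.029  0.027  0.015  0.006 -0.005 
#>      F      T      R      C      Q      K      P 
#> -0.006 -0.025 -0.030 -0.087 -0.422 -0.482 -0.903
```

The fitted mean log factors recover the simulated truth: glycine at the
top (truth `log 2 ≈ 0.69`), proline at the bottom (truth
`log 0.5 ≈ −0.69`), the rest scattered near zero. At this small demo size
a few rare, A-rich amino acids (Q, K) pick up sizeable negative values:
their factors rest on a handful of low-count cells, and the Markov
structure of the inserted nucleotides correlates neighbouring junction
codons, so selection on proline leaks slightly into amino acids that
co-occur with it. The standing recovery experiments at 20x this
size (see below) recover the per-position factors with Pearson r above
0.95 against truth.

`predict(gen, reads)` evaluates Pgen for new sequences, `sequence_q(features, sel)` evaluates selection factors,
`plot(sel)` draws the position-by-amino-acid heatmap, and
`detect_clones(reads, g, cutoff = 4)` returns the clone table with one
flagged ancestor per clone. `run_pipeline()` executes the whole workflow
from a YAML config and writes a digest manifest.

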