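---
title: "Simulating and scoring a known-phylogeny evolution experiment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and scoring a known-phylogeny evolution experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phi6kp)
```

## The system being modelled

Bacteriophage phi6 is a tri-segmented RNA virus (segments L, M and S of
6374, 4063 and 2948 bp) cultured by serial passage on bacterial lawns: an
inoculum of N plaque-forming units is plated, each founding particle grows
into a plaque of roughly $b^g = 100^5 = 10^{10}$ pfu over about five
generations of burst replication, the plaques are pooled into a lysate, and
a fresh inoculum founds the next day's passage.  Every serial transfer is
therefore a population bottleneck of size N followed by explosive regrowth.

A *known-phylogeny* experiment turns this protocol into a test bed for
phylogenetics.  A founding lineage is repeatedly bifurcated into demes that
evolve under different host regimes — the original host *Pseudomonas
phaseolicola* (PP), the novel host *P. pseudoalcaligenes* ERA, or daily
alternation — and different bottleneck schedules (constant large N, daily
single-plaque N = 1 transfers, or N ramped across 10–10^4).  One clone is
isolated and fully sequenced at every node and tip.  Because the branching
history is imposed and every intermediate genome is sampled, the true tree,
the true ancestral sequences and the complete substitution history are all
known, and the output of any reconstruction method can be scored against
them exactly.

The default design shipped with the package (`default_design()`) has 16
tips, 15 internal nodes and 1 ancestor (32 sequenced clones), five
bifurcation levels lasting 50, 50, 50, 100 and 100 generations (at 5
generations/day), 350 generations from root to tip and 2750 generations
summed over all branches.  The branch-to-regime assignment is chosen so the
per-regime generation totals are 500 (PP at large N), 450 (ERA at large N),
200 for each of the three N = 1 treatments, and 600 for each of the
increasing- and decreasing-N treatments.  The design file is ordinary TSV
and is the editable ground truth: any other bifurcating layout can be
supplied through `read_design()`.

## The forward simulator

`simulate_experiment()` runs every branch through a per-day transfer cycle
(`run_transfer()`):

1. **Bottleneck.** N founder particles are drawn multinomially from the
   pooled lysate.  Particle proportions already carry the previous day's
   within-plaque selection, so for N = 1 this is exactly the single
   fitness-weighted draw in which drift dominates but within-plaque
   selection is retained.
2. **Plaque growth.** Every founder grows through $g$ generations of burst
   replication.  Genotype counts multiply by $b\,(1+s_{\text{host}})$ per
   generation, so a selection coefficient acts per generation of
   within-plaque growth.  Populations are genotype→count tables, never
   individual particles; after pooling, the total is normalised to exactly
   $N b^g$.
3. **Mutation** enters by two routes at different resolutions:
   * *Focal (pleiotropy) sites* get full within-plaque treatment: at every
     generation each class emits a Poisson-distributed number of particles
     that switch allele at the focal site (specific substitution rate
     $\mu/3$), and those particles found classes that are then amplified or
     purged by the remaining generations of growth.  This is what makes
     focal-allele dynamics depend on bottleneck size, and it reproduces
     Luria–Delbrück jackpot skew in the standing variation.
   * *The rest of the genome* is neutral or unconditionally deleterious
     within a single plaque, so its mutations are attached to the
     replication ancestry of each sampled founder: under the
     stamping-machine replication model a sampled genome has exactly $g$
     replication events in its within-plaque ancestry and carries
     Poisson($\mu L g$) new mutations, with positions uniform over sites.
     The geometric replication mode draws the per-genome event count
     uniformly on $1..(2g-1)$ — the same mean $g$, but larger variance,
     capturing the variance contrast between the two replication modes
     without simulating $10^{10}$ genomes.

At the end of each branch a single particle is sampled as the sequenced
clone, and both daughter branches are founded from it — mirroring the
protocol, in which each bifurcation is founded from one isolated plaque.
Recorded per-branch events are the substitutions between the parent clone
and the child clone, so a lost allele appears as a reversion substitution,
exactly as clone-to-predecessor comparisons report it.

### Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `mu` | 2e-6 /base/replication | spontaneous mutation rate |
| `u_deleterious` | 0.067 /generation | genomic deleterious rate (aggregated load model) |
| `burst` | 100 | particles per infected cell per generation |
| `gens_per_plaque` | 5 | generations per plaque (so $100^5 = 10^{10}$ pfu) |
| `frac_deleterious` | 0.6 | fraction of background mutations that are deleterious |
| `s_deleterious` | 0.05 | per-generation cost of a deleterious background mutation |
| `pleiotropy` | F176L analogue | host-antagonistic locus (below) |

Generations per day is 5, consistent with 50 generations per 10-day passage
and with the $100^5$ plaque size; the alternation regime starts on PP.  The
deleterious-load figure 0.067 is applied **per bottleneck event** in the
aggregated model (`simulate_bottleneck_load()`), matching the arithmetic
$0.067 \times 20 \approx 1.3$ by which one fixed mutation is expected per
20 days of single-plaque bottlenecking; a per-generation interpretation
would simply scale the event rate by 5 and can be supplied explicitly.

### The antagonistic-pleiotropy calibration

The default pleiotropy table contains one locus: the analogue of the P12
F176L substitution on segment S (first base of codon 176; T→C), beneficial
on ERA and deleterious on PP.  No selection coefficients are published for
this allele, so the package calibrates them to the *qualitative* outcome of
the follow-up reversion experiment: populations founded fixed for the
derived allele and passaged on PP for 20 days show the reverted allele
dominant at bottlenecks of $10^3$ and $10^4$ but below detection at 10 and
100.  Under the plaque model above, the standing revertant frequency in a
day's pool is dominated by rare early-generation jackpot mutations (its
median is far below its mean), and the chance of the bottleneck catching a
revertant founder scales as $N \times$ frequency.  Calibration runs over a
grid of coefficients (50 replicates per bottleneck size) showed that
$s_{PP} = -0.8$, $s_{ERA} = +0.8$ per generation reproduces the observed
pattern with wide margins (fixation fraction 0.84 at $10^3$, 1.00 at
$10^4$, 0.18 at 100, 0.00 at 10), while weak coefficients (±0.1) cannot
drive a sweep within 20 days at any allowed N.  These values are a
synthetic calibration, not measurements; `simulate_reversion_assay()`
re-runs the assay for any coefficients.

### What the generator does and does not emulate

The simulator reproduces the experiment's population process — bottleneck
schedules, within-plaque selection, stamping-machine mutation supply,
single-clone sampling — and its molecular bookkeeping (tri-segment genome,
no indels, DNA alphabet matching cDNA sequencing).  It does not model
co-infection and segment reassortment (a tiny minority subpopulation under
the plating conditions), host coevolution (passages use naïve hosts),
spatial plaque structure, transition/transversion bias, or a continuous
distribution of beneficial effects; background fitness effects are a
two-point distribution (neutral or a fixed cost).  Tests that pass on
simulated data therefore certify the analysis machinery and the stated
population process, not any claim about unmodelled features of the real
data.

## Molecular-evolution statistics

`diff_genomes()` calls substitutions between clone pairs and classifies
each through the standard genetic code: a change is nonsynonymous if it
alters the protein of *any* overlapping CDS (the first affected gene, in
annotation order, is reported — a conservative, deterministic rule).
Coding labels follow the `K144R` convention with 1-based codon indices;
noncoding changes are labelled `n.c. <pos> <segment>`.  Ka/Ks tallies per
treatment regime are raw substitution counts (the form in which small
experimental datasets are tabulated), not per-site-normalised rates; a
normalised variant is available but off by default.  The uniformity test is
a Pearson goodness-of-fit of per-segment counts against expectation
proportional to full segment lengths, and regime contrasts use the standard
two-sided Fisher exact rule (sum of hypergeometric probabilities not
exceeding the observed table's).  `detect_homoplasy()` reports reversions
(a descendant branch restoring the state its lineage carried before an
ancestral branch's forward mutation) and parallel events (identical
substitutions on branches neither of which is ancestral to the other; if
some carriers are ancestrally related the reported set is the antichain of
most-derived carriers).

Exact phi6 CDS coordinates are not bundled: the shipped annotation honours
the real gene-to-segment assignments (P3 on M; P8, P9, P5, P12 on S;
polymerase-complex genes on L) but its coordinates are synthetic, and the
file is named accordingly.  Analyses of real sequence data should supply
their own annotation TSV.

## Tree inference

Maximum parsimony is exact: `fitch_score()` is the bitwise Fitch dynamic
programme over compressed site patterns, and `branch_and_bound_mp()`
searches all unrooted binary topologies with taxon addition ordered by
divergence, an initial upper bound from the neighbor-joining tree, and an
admissible per-pattern lower bound (any complete tree spends at least
(#states − 1) changes per site over *all* taxa, placed or not).  That floor
is what keeps exact 16-taxon search fast even on weak data, where the naive
partial-tree bound explores essentially the whole tree space.  All tying
optima are returned in a canonical order (children sorted by smallest
contained tip label); with no parsimony-informative sites every topology
ties, so the search is skipped and a canonical topology is returned with an
`uninformative` flag.  On pathologically weak data the number of true
co-optima can explode combinatorially; collection stops at `max_optimal`
(default 20000) with a `truncated` flag while the score stays exact.

Bootstrap support resamples site patterns (a multinomial on pattern
weights, equivalent to resampling columns), re-runs the search, and counts
a clade only if it appears in the strict consensus of the replicate's
optima — a conservative, deterministic tie rule; the point estimate is the
strict consensus of the original optima.  Neighbor joining (`ape::nj`
behind `neighbor_joining()`) serves as the distance-based comparison method
and recovers additive matrices exactly; negative branch-length estimates
are clamped to zero with a warning.

`ancestral_states()` reconstructs internal sequences either by unit-cost
parsimony with full most-parsimonious-reconstruction state sets (ambiguity
kept as IUPAC codes; computed by forward/backward Sankoff passes, which is
exact where two-pass Fitch set rules are not) or by marginal likelihood
under a Jukes–Cantor model mixed with an invariant-site class.  The
invariant proportion defaults to 0.97, the value appropriate to datasets in
which almost all sites never vary; edges without branch lengths default to
0.01 substitutions/site, and posterior ties break deterministically in
A,C,G,T order.  Posteriors at every node sum to one to within $10^{-12}$.

## Accuracy scoring

`clade_errors()` compares canonical bipartition sets: false positives are
clades of the inferred tree absent from the truth, false negatives the
reverse, and Robinson–Foulds distance is their sum; multifurcations in the
inferred tree can only create false negatives (unresolved is missing, never
wrong).  `ancestral_accuracy()` maps nodes between trees by clade content
(never by label), scores sequences site by site, counts ambiguous inferred
states as incorrect while flagging them separately, and reports unmappable
nodes rather than dropping them.

Two regimes bracket the method's behaviour, and both are exercised by the
test suite.  With ample mutation supply (a validation scenario using the
same 16-tip design shape at 5× the mutation rate with a neutral
background), every internal branch carries several unique markers and
exact parsimony recovers the true tree with no clade errors.  At the
experiment's own mutation rate, tips differ from the ancestor by only a
handful of substitutions (means near 5–6, within the observed 4–13 range),
several internal branches carry no substitution at all, and reconstruction
shows false negatives in most runs — the same failure mode the real
experiment attributed to the small number of polymorphic sites.  An exact
reversion that erases a mutation from all sampled descendants leaves the
intermediate ancestral state unrecoverable by any method; the accuracy
report localises exactly that (node, site) pair.

## Fitness statistics

Fitness is $W = R_1/R_0$, the relative change in the test-to-competitor
ratio across one assay culture; analyses are on $\ln W$, with $W = 0$
(inability to infect the assay host) flagged as undefined and excluded from
tests.  `one_sample_t()` accepts either raw replicates or printed
(mean, sd, n) summaries — the parenthetical values in the bundled clone
table are standard deviations, which is decisive: recomputing the
ancestor's one-sample t from its summary gives 11.77 against a printed
11.71, whereas treating them as standard errors would give 4.81.  The
two-sample test defaults to pooled-variance Student's t (df = 10 for
6 vs 6), with Welch available; all tests are two-sided, and significance
is judged against Bonferroni-corrected thresholds (0.05/31, 0.05/17, 0.025
for predecessor pairs).  `lnw_trend()` is ordinary least squares of
$\ln W$ on generations with the standard slope t-test.  The published
regression slopes themselves depend on per-clone generation times not
recoverable from the printed record, so they are computed but not asserted.

## Numerical and reproducibility choices

* All randomness flows from a single integer seed; stage seeds are derived
  deterministically (`derive_seed`) so disabling one pipeline stage does
  not shift another's draws.  Identical inputs and seed give byte-identical
  FASTA/Newick/TSV artifacts and an identical run manifest.
* Genotype classes are append-only within a day (duplicates are equivalent
  under multinomial sampling); classes below $10^{-12}$ relative frequency
  are pruned at day end to bound table growth.
* Coordinates are 1-based and inclusive; positions are per-segment, with
  concatenation (fixed L, M, S order) only at alignment export.
* Problem sizes used by the shipped tests: five full-design runs at the
  default rate plus two high-supply validation runs for the end-to-end
  properties; 50 replicates per bottleneck size for the reversion assay;
  $10^4$–$10^6$ replicate lineages for the bottleneck-load checks;
  exhaustive-search cross-checks at up to 7 taxa, where enumeration
  (945 topologies) is still comfortable.

## Known limitations

Single-locus pleiotropy by default (the table accepts any number of rows,
but loci are treated independently — no epistasis); no reassortment or
co-infection; equal substitution rates among bases; the sequenced-fraction
mask of real data (93.2% of the genome) is not applied by default; exact MP
search is intended for ≤ 16 taxa and, on data with almost no signal,
reports truncated tie sets rather than attempting to enumerate millions of
co-optima.
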