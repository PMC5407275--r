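---
title: "Methods: COI barcode identification and mislabeling audits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: COI barcode identification and mislabeling audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`barcodeaudit` identifies seafood samples from cytochrome oxidase I (COI)
barcode sequences and audits their menu listings. A single query passes
through up to four identification methods — database-style percent identity
against a local reference panel, placement in a maximum-likelihood (ML)
phylogeny, Bayes-factor topology tests, and a diagnostic nucleotide
character key — and the calls are combined into one final identification
that is judged against acceptability rules for the menu phrase. This
vignette explains each model and procedure, its assumptions, the tunable
parameters, and the numerical choices the implementation makes.

## Sequence handling and numt screening

COI is a protein-coding mitochondrial gene, so all alignment is codon-aware:
sequences are translated (NCBI tables 2 and 5, the vertebrate and
invertebrate mitochondrial codes), the amino-acid sequences are aligned, and
gaps are back-translated as whole codons. The aligner is a deterministic
center-star scheme: every sequence is globally aligned (affine gaps, default
BLOSUM62, gap open 10, extend 0.5) to the longest sequence, and insertions
are merged by maximum length. Guide order is descending length with ties
broken by record id, so output is reproducible bit-for-bit. For gapless or
near-gapless barcode amplicons — the intended use — this center-star scheme
is equivalent to any sensible progressive order; it is not meant for deeply
indel-rich data.

The reading frame of each sequence is the frame whose translation has the
fewest stop codons (ties to the smallest offset). A sequence with early
stops in every frame is numt-suspect (a nuclear pseudogene copy) and is
excluded from alignment with a warning. Leading frame-offset bases and
trailing partial codons are kept as gap-padded edge columns so that
de-gapping any aligned row always reproduces the input sequence exactly; the
codon-position labels (1/2/3) extend across these pads on the same cycle.

The numt screen flags, per row, (i) internal in-frame stop codons and (ii)
internal gap runs whose length is not a multiple of three. Two deliberate
exemptions: a *terminal* stop codon is tolerated (it can arise from frame
bookkeeping at a ragged amplicon end, not from pseudogenization), and
*terminal* gap runs are ignored because they are overhangs of unequal-length
sequences, not indels. All reported coordinates are 1-based inclusive
alignment columns; internal storage is a character matrix with the same
1-based indexing.

## Percent-identity identification

Identity between two aligned rows is `100 * matches / overlap`, where
overlap counts columns in which both rows have a non-gap base and an
IUPAC-ambiguous position matches iff the two base sets intersect (`N`
matches anything). This is symmetric, transparent, and reproduces the
2-decimal granularity of database hit tables; whether public databases
treat overhangs identically is not knowable, so the definition is
documented rather than claimed equivalent. Candidates are all taxa whose
best hit lies within a reporting band (default 1.0 percentage point) of the
global best; the decision is species-level only when a single species
remains in the band, genus-level when all banded candidates are congeneric,
and absent when the best hit falls below a floor (default 90%). The band
default reproduces the multi-species listings seen in low-divergence
groups (several tuna species tie at ~100%) without a per-query cutoff;
ranking ties break lexicographically by reference id.

## Likelihood model

All phylogenetic computation uses GTR-family substitution models (JC69,
K80, HKY85, GTR; bases ordered A, C, G, T; exchangeabilities ordered AC,
AG, AT, CG, CT, GT with GT fixed at 1) with the rate matrix scaled to one
expected substitution per unit branch length. Among-site rate variation is
the discrete-Gamma approximation: four equiprobable categories whose rates
sit at the quantile midpoints of a mean-one Gamma(shape α) distribution and
are renormalized to average exactly 1. Quantile midpoints (the "median"
discretization) are used rather than category means; the two agree as the
category count grows and the choice is applied consistently in simulation
and inference. Transition probabilities come from the eigendecomposition of
the symmetrized reversible rate matrix, which is cached per model.

Site likelihoods are computed by Felsenstein pruning on the unrooted tree
with site-pattern compression per partition; gaps and `N` are missing data
(partial likelihood 1 for every state), so an all-gap column contributes
exactly zero log-likelihood. Partitioned analyses (unpartitioned, or by
codon position — the biologically motivated subsets for a protein-coding
gene) share branch lengths, with per-subset rate multipliers constrained to
a size-weighted mean of 1.

## Optimization and model selection

Parameters are optimized by coordinate ascent: Brent line searches on each
branch length (bounds 1e-8 to 10 substitutions/site) alternate with
Nelder-Mead over the model parameters in unconstrained space (log rates,
log-ratio frequencies, log Gamma shape clamped to [0.05, 50], log subset
multipliers), until a round improves the log-likelihood by less than 1e-6
or 200 rounds elapse; non-convergence is flagged, not raised. Model and
partition selection minimizes BIC = k·ln(n) − 2·lnL over the grid
{unpartitioned, codon positions} × {JC69, K80, HKY85, GTR} × {±Γ}, with n
the number of alignment columns and k counting branch lengths (2n−3),
per-subset model parameters (0/1/4/8 by family, +1 for Γ) and the free
subset multipliers. Counting branch lengths in k follows standard
partition-selection practice; since every candidate shares the same tree it
shifts all scores equally within a scheme and only matters between schemes,
where the extra multiplier parameters are also counted.

## ML search, bootstrap and placement

Tree searches start from a neighbor-joining tree built on ML pairwise
distances (each pair's two-sequence likelihood maximized over the
separating path) plus optional random topologies generated by seeded
sequential addition, and hill-climb by nearest-neighbor interchange (NNI),
re-optimizing branch lengths as they go; the best local optimum over starts
wins. NNI-only rearrangement is a deliberate desk-scale choice — barcode
panels are small and multiple starts mitigate local optima; subtree
pruning-regrafting is a natural extension point. All tie-breaks (equal-lnL
moves, split orderings) use lexicographic keys so results are reproducible.

Bootstrap support resamples columns with replacement within each partition
subset, re-searches each replicate from its own NJ tree with a fast NNI
variant (only internal edges re-optimized when scoring neighbors), and
reports the percentage of replicates containing each bipartition of the ML
tree; with R replicates every support is a multiple of 100/R. A degenerate
alignment (single repeated pattern) yields whatever topology the
deterministic tie-breaking produces in every replicate, so supports are
then an artifact of the tie-break — flagged here rather than hidden.
Posterior probabilities for the same bipartitions can be annotated from any
sample of trees (e.g. the MCMC below). Query placement reports the smallest
clade containing the query whose other members share one species label,
with that clade's bootstrap/posterior pair printed as integers ("98/100");
the posterior is reported ×100 to mirror the integer convention of the
packaged observation tables.

## Bayesian topology tests

Monophyly of a taxon set on an unrooted tree is equivalent to the existence
of the corresponding bipartition. Hypotheses are encoded as constraints
(monophyletic / not monophyletic) and compared by Bayes factors computed
from stepping-stone estimates of each hypothesis's marginal likelihood.

The MCMC samples (topology, branch lengths, model parameters) under priors:
topology uniform over the constraint-satisfying set, branch lengths iid
exponential with mean 0.1, flat Dirichlet on exchangeabilities and base
frequencies, Gamma shape uniform on (0.05, 50). These mirror common
Bayesian-phylogenetics defaults and are settings, not claims; all are
visible in code. Moves are NNI (uniform over internal edges and swap
directions), a branch-length multiplier, a one-component simplex scaling
with the exact Jacobian as Hastings correction, and a shape multiplier.
Constraints are enforced by proposal rejection: the NNI kernel is
symmetric, the target density is zero off the satisfying set, so rejecting
violating proposals is valid Metropolis-Hastings; the constrained space
remains NNI-connected for monophyly-type constraints at these problem
sizes, and the prior-only sampler is checked against enumeration in tests.
Optional Metropolis coupling runs incrementally heated chains (temperature
step 0.1, swap proposals every 10 generations) and samples the cold chain.

Convergence is monitored by the average standard deviation of split
frequencies across independent runs (splits under 10% everywhere excluded;
< 0.01 indicates topological convergence) and per-parameter effective
sample sizes from the autocorrelation sum truncated at the first
non-positive lag.

Stepping-stone estimation bridges posterior and prior through powers β at
Beta(0.3, 1) quantiles — the standard generalized ladder, concentrating
steps near the prior. With 1 = b₀ > … > b_K = 0, each ratio is estimated
from samples at the *lower* power via a log-sum-exp-stabilized mean of
L^(Δβ), and the marginal log-likelihood is the telescoping sum (the prior
is proper, so the β = 0 normalizer is 1). Two burn-in rules apply: the
initial β = 1 step is discarded entirely, and the leading 25% of each
step's samples are dropped because the chain arrives from the previous,
more concentrated power and needs to re-equilibrate — without this the
estimate inherits a systematic upward bias at desk-scale step lengths. The
estimator is validated in tests against closed-form marginals (conjugate
normal), a constant-likelihood identity that holds exactly at any K, and
exhaustive enumeration of the 15 five-taxon topologies. Desk-scale defaults
(K = 10, thousands of generations per step, 3–4 runs) replace the
published-scale 50 × 200,000 × 4 design, which remains available through
the configuration; the Monte Carlo error is the standard error of the
per-run estimates.

The reported statistic is the log Bayes factor — the difference of marginal
log-likelihoods — with |log BF| > 5 read as strong support, matching the
arithmetic of the hypothesis tables this package ships; only
arithmetically consistent comparisons (those expressible as differences of
the tabulated marginals) are reproduced.

## Character key and adjudication

The diagnostic key stores species-specific nucleotide states at 14 fixed
1-based barcode positions (262–535); the packaged key carries the three
distinct published tuna profiles (*Thunnus albacares*, *T. alalunga*,
*T. obesus* — the last often printed with a "T. obsesus" misspelling,
corrected here), and user keys in the same TSV schema can carry the full
eight species. The coordinate frame of the key is its own alignment;
mapping a query uses an explicit frame offset (default 0), an assumption
made explicit and overridable because published keys rarely state their
coordinate anchor. Matching is minimum-Hamming with `N`
never counting as a mismatch, so truncated queries drift toward ambiguity
rather than misidentification; an exact identification requires zero
mismatches and no tie.

The consensus over methods uses the precedence: exact character-key match,
then Bayes-supported grouping, then supported ML placement (default
bootstrap ≥ 70), then identity top hit. Barcoding studies typically
combine their methods narratively; this explicit ordering is this
package's own design, chosen so
that the methods able to separate low-divergence congeners outrank raw
identity, and it is configurable, with disagreements recorded in the
verdict. A listing's rule gives its acceptable species (genus wildcards
expand, e.g. any *Thunnus* may be sold as "tuna"); a genus-level final call
is acceptable only if every member species is. The audit table recomputes
its counts and the whole-percent mislabeling rate on every call — nothing
stores a verdict.

## Synthetic data and what the tests show

The simulator draws birth-death trees (default pure-birth), rescales them
to a target mean root-to-tip divergence (default 0.2 substitutions/site, a
family-level panel; ~0.01 mimics the near-zero divergence of tunas), and
evolves codon-structured sequences with per-position models (third
positions 5× faster by default, Gamma-distributed site rates at third
positions) under the same transition machinery the inference uses. Codons
that would place an in-frame stop in any tip sequence are redrawn — a mild,
documented departure from the pure substitution process that keeps
simulated data valid coding sequence. Branch lengths are floored at 0.03
substitutions/site: birth-death draws can contain effectively-zero internal
branches, and the recovery properties this package validates presuppose
panels whose species are actually distinguishable at barcode lengths
(divergent panels, inter-species divergence ≳ 0.05). Scenario generation
plants a known truth — reference panels (two copies per species), queries
as shallow descendants (within-species divergence 0.004), listings whose
rules exclude the truth for intended mislabels — and the end-to-end
pipeline must recover it.

What passing tests do show: the pruning likelihood agrees with brute-force
enumeration to 1e-8; the samplers are distributionally correct on
enumerable spaces; the estimators recover known parameters at stated
problem sizes (e.g. topology recovery on 8 taxa × ~1000 sites, where the
occasional miss is verified to be estimation variance — the search's tree
scores at least as well as the truth — rather than search failure). What
they do not show: robustness to misidentified reference sequences,
heterogeneous sequence quality, real indels, numts that pass the screen, or
database coverage gaps — the properties of real panels that no simulator
certifies. Problem sizes in the tests (alignments of 300–2000 sites, 3–10
taxa, 10–20 scenario replicates) were chosen as the smallest at which the
statistical properties under test are expected to hold with comfortable
margins.

## Worked example

```{r, eval = FALSE}
library(barcodeaudit)

# the packaged restaurant audit, recomputed end to end
rep <- dc_audit()
rep$table
rep$percent_mislabeled

# a simulated scenario with known truth
spec <- simulation_spec(6, divergence = 0.3, length_codons = 120, seed = 1)
sc <- make_scenario(6, data.frame(true_species = paste0("sp", 1:6),
                                  mislabel = c(rep(FALSE, 4), TRUE, TRUE)),
                    spec)
res <- run_scenario_audit(sc)
res$report
```

## Known limitations

The aligner is center-star, adequate for barcode amplicons but not for
indel-rich loci. NNI-only search can stop at local optima on larger or
less-divergent panels (use more starts). The MCMC recomputes the full
likelihood per proposal (no partial-likelihood reuse), which bounds
practical problem sizes to barcode scale. Percent identity is one specific,
documented definition and need not match proprietary database scores beyond
the high-identity regime. The packaged key covers three tuna profiles only;
genus-level wildcards in menu rules treat regulatory acceptability as a
purely taxonomic statement.
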