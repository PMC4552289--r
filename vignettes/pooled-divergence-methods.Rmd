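---
title: "Methods: divergence and selection from pooled transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence and selection from pooled transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

poolsel reconstructs, as a tested pipeline, the analysis chain used to
detect divergent selection on chemosensory genes between two sibling
species sequenced as read pools. This vignette is the package's own
account of the models, the defaults, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The data model

Each gene is an orthologous pair of equal-length, in-frame coding
sequences, one per species. Each species was sequenced as a single pool
of 40 haploid males, so the observable per site is a vector of base
counts (A, C, G, T) whose proportions estimate population allele
frequencies. There is no read-level haplotype information; every rule
below operates on counts.

## Site classification

Four rules, each surfaced as a configurable threshold with the study's
value as default:

* **Presence** (`presence_floor = 5`, `presence_frac = 0.05`): a base is
  present at a site if supported by at least `max(5, 0.05 × depth)`
  reads. The source phrasing ("a minimum of five reads, or five percent
  of all reads when higher than five") is read as the *stricter-of-two*
  rule; at depth ≤ 100 the five-read floor binds, above that the 5%
  fraction does.
* **Fixed** (`fixed_major_freq = 0.95`): a site is fixed when in at
  least one species a base reaches ≥ 95% of reads and that base is not
  present (by the rule above) in the other species. The literal source
  wording is unidirectional; we record which direction(s) satisfied the
  rule and a `require_bidirectional` switch provides the stricter
  reading. With the defaults the two readings rarely differ: a 95%
  majority base of one pool that is present in the other pool usually
  implies the other pool's majority base is present in the first pool
  too.
* **Polymorphic**: not fixed, and two or more bases present in at least
  one species.
* **Depth floors**: genes need `min_mean_cov = 10` mean per-base
  coverage in *both* species (gene-level, as in the source); sites below
  `min_site_depth = 10` reads in either species are *unclassifiable* —
  a per-site floor is needed for the five-read presence rule to be
  meaningful, and 10 is the smallest depth at which the 95% majority
  rule can fail by a single read.

Ties for the major allele are broken in the fixed base order
A < C < G < T and flagged. Coordinates are 1-based along the ORF.

**Effect annotation.** Each fixed or polymorphic site is labelled
synonymous or non-synonymous by swapping the two alleles inside the
codon while holding the other codon positions at the within-species
major-allele consensus. When several variable sites share a codon each
is evaluated independently this way — matching per-site accounting
rather than joint codon haplotypes, which pooled data cannot resolve.

**Fixed-difference alignments.** The dN/dS input pair carries the
species-specific major allele at fixed sites only; polymorphic and
unclassifiable sites carry the species-A major in both sequences, i.e.
polymorphisms are discarded before divergence estimation (they inflate
dN/dS between recently diverged species). Consensus positions below the
per-site depth floor fall back to the reference base so one or two
error reads cannot fabricate a consensus change. Rarely, a fixed
difference and a neighbouring polymorphism combine into a premature stop
codon in this consensus pair; such orthologs are excluded from the
dN/dS stage, mirroring the upstream filter that discarded ortholog
candidates with premature stops.

## Pairwise dN/dS

**Model.** The Goldman–Yang codon substitution model over the 61 sense
codons: `q_ij = 0` for multi-nucleotide changes, otherwise
`π_j · κ^[transition] · ω^[non-synonymous]`, scaled so the expected
substitution rate at equilibrium is 1, so `t` is measured in expected
substitutions per codon. Codon frequencies default to F3×4 (per-position
nucleotide frequencies of the pair, floored at 1e-8 and renormalized);
an `equal` mode is used in simulation tests.

**Likelihood.** For a sequence pair the ancestor integrates out under
reversibility: `lnL = Σ_sites log(π_i P_ij(t))`. `P(t) = exp(Qt)` is
computed by eigendecomposition of the symmetrized generator
`S = D^{1/2} Q D^{-1/2}` (real spectrum guaranteed by reversibility);
agreement with an independent dense matrix exponential is part of the
test suite.

**Optimization.** `(κ, ω)` are maximized by bounded quasi-Newton
(L-BFGS-B) on log-parameters from three fixed starting points, with `t`
*profiled out*: for each `(κ, ω)` one eigendecomposition is reused by a
golden-section search over `t`. Bounds are `t ∈ [1e-6, 50]`,
`κ ∈ [0.01, 100]`, `ω ∈ [1e-4, 99]`; convergence tolerance ~1e-8 in
lnL. Pairs with zero differences are degenerate: `t` is reported at its
lower bound, dN = dS = 0, and the LRT is Δ = 0, p = 1.

**dN and dS** are derived from the fitted matrix: with ρ_N the
non-synonymous flux fraction of the scaled generator,
`dN = t·ρ_N(ω̂) / (3·ρ_N(ω=1))` and symmetrically for dS — i.e.
substitutions per non-synonymous (synonymous) site with sites measured
by neutral mutational opportunity at the fitted κ.

**LRT.** Δ = 2(lnL_free − lnL_{ω=1}) referred to χ² with 1 df. With the
handful of fixed differences typical of young species pairs the test has
low power; results from pairs with fewer than 3 fixed substitutions are
flagged low-support in the report table, and ω is printed as ∞ when no
synonymous difference was observed (dS = 0) while the ML value is kept
internally at its bound.

**NG86 check.** The Nei–Gojobori counting estimator provides the second
route: per-codon synonymous site fractions, pathway-averaged difference
counts, Jukes–Cantor correction. Conventions: mutations creating stop
codons count as non-synonymous opportunities (site denominators stay 3
per position); substitution pathways passing through a stop are excluded
from averaging unless all are blocked. The correction is undefined when
a difference proportion reaches 3/4 — on very short fragments a single
synonymous difference can exceed the synonymous site count, and the
package raises an error rather than reporting an extrapolated distance.

## Gene-set statistics

All four tests are implemented from first principles and cross-checked
against the standard statistics environment in the test suite:

* **Fisher's exact 2×2**, two-sided by the minimum-likelihood
  convention (sum of hypergeometric point probabilities ≤ the observed
  table's) — required to reproduce the published p-values, which came
  from that convention. Degenerate margins give p = 1.
* **Mann–Whitney U** with midranks, tie correction and continuity
  correction under the normal approximation (group sizes in this design
  are far beyond exact-enumeration range).
* **Goodness-of-fit χ²** on an observed in/out split against an
  expected fraction, two cells, no continuity correction, df = 1 —
  verified against the published 9.38 and 2.91 values.
* **Pearson correlation** with the t transform, n − 2 df, two-sided.

The standard contingency set: (1) fixed vs polymorphic sites ×
gene set; (2) non-synonymous vs synonymous fixed sites × gene set;
(3) ω > 1 vs ω ≤ 1 genes × gene set; (4) receptor vs non-receptor
among ω > 1 genes; plus Mann–Whitney on per-gene dN and dS between
sets. No multiple-testing correction is applied (none was applied in the
source analysis); reports note this. For the ω > 1 enrichment the
package builds the statistically proper complement tables; the
acceptance report additionally reproduces the published p-value from the
table layout the original authors evidently used (set totals rather than
complements in the second column).

## Topology consensus and domain mapping

A residue is consensus-TM when ≥ `min_support = 2` of the (≥ 3)
predictors place it in a TM interval; maximal runs become TM1..TMn from
the N-terminus. The source voted per substitution; per-residue voting
generalizes this and yields the same in/out-TM call at every
substitution position (the vote at a position is the same quantity
either way). Loops are labelled positionally — IN before TM1
(intracellular N-terminus, the 7-TM insect OR orientation), then
alternating EL/IL, EC after the last TM. Ligand-binding-domain transfer
projects reference S1/S2 intervals through a global protein alignment
(BLOSUM62, affine gaps); reference positions aligned to gaps contract
the interval; identity < 15% sets a warning flag. The pooled enrichment
test uses the *unweighted mean* of per-protein LBD coverage fractions as
the expected fraction — matching the "mean proportion" construction —
and delegates to the two-cell χ².

## ORF extraction and orthology

ORFs are ATG-to-stop (stop included) over all six frames; "all possible
ORFs" is ambiguous in the source, so a `stop_to_stop` flag provides the
permissive variant. Candidates containing N are excluded rather than
ambiguity-expanded. Family length floors follow the source: 300 nt for
OBP/CSP, 900 nt for receptors. Orthology is reciprocal best hit with
*identical length* and column-wise *nucleotide* identity ≥ 0.95 (whether
the source's 95% was nucleotide or protein identity is unstated;
nucleotide is the stricter and simpler choice on equal-length pairs);
best-hit ties break to the lexicographically smallest id and are
flagged. Completeness = % of reference residues covered by the union of
candidate segments; contiguity = % covered by the single longest segment
(the source's exact definitions follow its annotation tooling and are
not spelled out; these interval definitions are the documented choice).
The iterative discovery loop (search → ORF extraction → validation →
query augmentation) terminates because the query set grows monotonically
and is bounded; a 20-iteration cap guards pathological backends. The
built-in backend is a translated local alignment scorer so discovery
runs offline; e-value-based external tools plug in via `search_fn`.

## The synthetic world

The generator's defaults state the emulated conditions; they are not
tuning knobs:

* pools of **40 haploid males** per species; **depth 50×** negative
  binomial with dispersion (size) 10, independent across sites — the
  simplest overdispersed stand-in for RNA-seq coverage (var = μ + μ²/10,
  roughly sixfold Poisson variance at 50×);
* per-base **error 0.3%**, uniform over the three alternative bases, no
  indels (the consensus ORF pairs in this design are equal-length and
  indel-free). The source does not report per-base error or depth
  distributions; 50× / 0.3% are documented fixture choices;
* fixed substitution rates defaulting to the chemosensory-set means
  (dN 0.0035, dS 0.0039 per site, applied as Poisson counts with mean
  rate × length); the NC preset uses 0.0005/0.0043;
* at most one segregating allele per species per site; minor allele
  frequency uniform on [0.1, 0.5] — below 0.1 a variant in a 40-haploid
  pool is carried by fewer than 4 haplotypes and is undetectable by the
  presence rule at 50×, so lower frequencies would only dilute truth
  labels — realized on `round(f × 40)` haplotypes;
* substitutions never create stops (resampling with a 100-retry bound);
  start and stop codons are never mutated;
* 7-TM truth topologies with 21-residue helices and proportionally
  spaced loops; predictor variants jitter boundaries by integer
  Gaussian noise, clamped to stay ordered and disjoint;
* pipeline-default gene lengths are receptor-like, 300–400 codons (the
  source's receptor ORF floor is 900 nt, and a 7-TM topology needs
  ~190+ residues);
* all randomness flows from a single integer seed; identical configs
  give byte-identical outputs.

What a green test does *not* establish: the generator has no mapping
bias, no position-correlated coverage, no indel or splice-isoform
structure, and its polymorphisms are single-allele per site. Sensitivity
and FDR measured on it bound performance under the stated model only.

The planted-enrichment acceptance check gives receptor genes a 5× higher
fixed non-synonymous rate and asks whether the full pipeline's ω > 1
enrichment test recovers the signal across seeds; the 10 + 30 gene
split is a desk-scale stand-in chosen once (enough NC genes for a
stable contingency margin at ~15 s per replicate).

## Known limitations

* Pairwise dN/dS has low power at divergences of a few substitutions
  per gene; the low-support flag, not the p-value, is the honest signal
  at n < 3 fixed differences.
* κ is weakly identified on nearly invariant pairs and can sit at a
  bound; `t` and ω are insensitive to it there.
* The NG86 Jukes–Cantor correction errors rather than extrapolating on
  saturated short fragments.
* The fixed-site rule inherits the pooled design's blindness to
  haplotype phase; multi-allele sites within one species are collapsed
  to major/minor.
* The iterative discovery backend is a scoring stand-in, not a
  calibrated e-value search; thresholds are raw alignment scores.
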