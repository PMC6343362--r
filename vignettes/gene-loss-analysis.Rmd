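---
title: "Detecting, screening and dating gene loss on phylogenies"
author: "pseudogeneKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, screening and dating gene loss on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudogeneKit)
```

# The problem

When the phenotype a gene serves disappears — teeth in baleen whales and
pangolins, enamel in armadillos and aardvarks — purifying selection on the
gene relaxes and the coding sequence starts to decay: frameshift indels,
premature stop codons, splice-site mutations and eventually whole-exon
losses accumulate, and the nonsynonymous/synonymous rate ratio
$\omega = dN/dS$ drifts from its constrained value toward the neutral
expectation of 1. `pseudogeneKit` implements the full analysis chain around
this process: lesion detection and classification, parsimony mapping of
shared lesions, a percent-intact screen for convergent losses with a
phylogenetic association test, branch-category $\omega$ estimation under a
codon substitution model, and closed-form dating of the inactivation event
on *transitional* branches. A matching simulator makes every stage testable
against known ground truth.

# Lesion scanning

`scanTaxon()` compares one query sequence against a reference taxon whose
reading frame is verified intact (ATG start, no internal stop, length
divisible by 3, and agreement with the `GeneStructure`). Calls are:

* **Frameshift indels.** Each maximal gap run in the query-vs-reference
  comparison whose length is not a multiple of 3 is one event: a deletion
  when the query has the gap, an insertion when the reference does.
  Adjacent runs of different type are *not* merged — each run is one indel
  event, since no merging rule is defensible without re-alignment.
* **Premature stops.** By default, stops are evaluated in the *reference*
  reading frame (the convention of lesion tables that report "stop relative
  to the original reading frame"); a query-frame mode additionally reports
  stops created downstream of frameshifts, verified in tests against direct
  re-translation of the degapped query. A mutated terminal stop is
  classified as a premature-stop record with subtype `"terminal"` and does
  not truncate the %intact statistic.
* **Start codon.** A pure non-ATG initiator codon is a
  `start_codon_mutation`.
* **Splice sites.** Donor/acceptor dinucleotides are supplied per taxon
  (the alignment holds only coding sequence). Any donor ≠ GT or acceptor ≠
  AG is a lesion, with one exception: GC donors are a known minor
  functional splice class and produce a warning rather than a record.
  `findAlternativeSpliceSite()` searches a window (default 30 nt, chosen so
  that a canonical site 75 nt away — the distance at which we still want an
  inactivating call — stays outside it) for a canonical dinucleotide whose
  use changes the exon length by a multiple of 3; the nearest
  frame-preserving site wins, preferring the shorter exon on a distance
  tie. Rescued sites should be reset to canonical before scanning.
* **Exon-level losses.** An exon that is entirely gaps is an
  `exon_deletion`; an exon that is entirely missing data (N) is classified
  by a user-supplied evidence tag as `exon_no_blast` (assembly gap) or
  `exon_no_reads` (no sequencing reads) — the scanner never infers which,
  because that distinction lives in the upstream evidence, not in the
  alignment.

Compound events spanning an exon/intron boundary are recorded as a single
record (one biological event), with the secondary consequence noted in the
subtype field.

# Parsimony mapping and lesion counting

`mapLesionsDeltran()` optimises each lesion's presence/absence as a binary
character by minimum-cost (Sankoff) parsimony with the root constrained to
*absence*: genes start intact, so a lesion present in scattered tips must be
explained by gains below the root, never by a primordially broken gene.
Where the reconstruction is ambiguous, changes are delayed toward the tips
(deltran): a child keeps its parent's state whenever that choice is on a
minimum-cost path. Monophyletic presence sets therefore map to the clade's
stem branch, and paraphyletic sets resolve into independent gains on the
smallest covering clades. Tests verify the reconstruction cost against
exhaustive enumeration (root fixed at absence) on trees of up to 8 leaves.

`countLesions()` implements the shared+own counting rule used in per-taxon
totals: a taxon's count is the number of records attributed to it plus all
records attributed to any clade on its root-to-tip path.

# The percent-intact screen

`computePctIntact()` defines
$\%intact = 100 \cdot \frac{\text{intact codons}}{\text{reference codons}}$,
where a codon is non-intact iff (a) it lies in a deleted exon or (b) it lies
at or downstream of the first frameshift or premature stop in reading
order. Missing-data exons (NBR/NRM) leave both numerator and denominator.
The original forward-genomics formula this emulates is not printed in the
sources available to us; the rule above is this package's documented
definition, chosen to be monotone in lesion position and exactly 0/100 at
the extremes. Splice and start-codon records deliberately do not enter the
statistic (their phenotypic effect depends on rescue), which is worth
remembering when comparing numbers across tools.

`classifyGene()` applies the screen's thresholds: inactivated below 80%,
intact at or above 90%, ambiguous between. `screenConvergentLosses()` keeps
genes inactivated in at least 2 focal species and intact in at least 90% of
background species (the fraction compared as a real number, no ceiling),
ranked by focal losses (descending), then background non-intact species
(ascending), then gene id. Whether the ≥2 rule counts species or lineages
is a design choice; the package counts species, with lineage grouping left
to the caller's species lists.

`pglsFit()` supplies the phylogeny-corrected association P-value:
generalized least squares with Brownian covariance $V_{ij}$ = shared
root-to-tip path length, slope $(X^TV^{-1}X)^{-1}X^TV^{-1}y$, two-sided $t$
test on $n-2$ degrees of freedom. On a star tree with equal branch lengths
this reduces exactly to ordinary least squares; under the null (Brownian
response, unrelated predictor) the P-values are uniform, which the test
suite checks with a Kolmogorov–Smirnov test over 1000 replicates.

# The codon model

`fitBranchModel()` implements the GY94 branch model. The instantaneous rate
from sense codon $i$ to $j$ is 0 unless they differ at one position, and
otherwise $\pi_j$, $\kappa\pi_j$, $\omega\pi_j$ or $\omega\kappa\pi_j$ for
synonymous transversions/transitions and nonsynonymous
transversions/transitions. Stop codons are excluded from the state space
(61 states, universal code). Codon frequencies come from
`buildCodonFrequencies()`: CF1 pools nucleotide frequencies across codon
positions (F1x4-style), CF2 keeps them position-specific (F3x4-style); stop
mass is removed and the 61 sense frequencies renormalised.

Every branch carries the $\omega$ of its category; a single global $\kappa$
is shared (matching how branch models are usually run). The rate matrix is
scaled so the *first* category (conventionally the background) has mean
rate 1 — branch lengths are expected substitutions per codon under the
background regime. The log-likelihood is computed by Felsenstein pruning
with transition matrices from an eigendecomposition of the
$\pi$-symmetrised (reversible) rate matrix; N and gaps are missing data,
other IUPAC codes expand to their compatible codon states, and an observed
stop codon in the data (possible only before preprocessing) is treated as
missing. `preprocessAlignment()` applies the conventional cleanup before
fitting: frameshift-insertion columns are deleted for all taxa, in-frame
insertion columns carried by at most 2 taxa ("unique to one or a few
taxa"; configurable) are deleted, and premature stop codons are recoded as
NNN in the affected taxon.

**Optimisation.** $\kappa$, the free category $\omega$s and all branch
lengths are jointly optimised on log scale with L-BFGS-B (relative
convergence tolerance ~2e-9 on the likelihood); the default is 3 starts —
the first from neutral-ish values with branch lengths warm-started from the
input tree, later starts randomising $\kappa$ and $\omega$ — although these
likelihood surfaces are unimodal in practice and a single start reaches the
same optimum on all our simulated problems. Per-category expected counts
are reported as $N dN = \rho_N \sum_b t_b L$ and $S dS = \rho_S \sum_b t_b
L$, with $\rho_N, \rho_S$ the equilibrium nonsynonymous/synonymous flux of
the scaled rate matrix and $L$ the codon count. A category whose $S dS$ is
(numerically) zero has an unidentifiable ratio and reports an `NA`
sentinel, with the raw counts always available — the analogue of the
"999" convention in some program outputs. This scaling is this package's
own documented convention; bit-compatibility with other implementations'
printed $N dN$/$S dS$ is not claimed. `lrtFixedOmega()` compares nested
fits differing by one fixed ratio against $\chi^2_1$.

# Dating inactivation on transitional branches

A transitional branch runs from age $t_b$ (older) to $t_e$ (younger; 0 for
terminal branches). If the gene was inactivated at age $t_i$, the
branch-wide ratio is a mixture of the functional ratio $\omega_f$ (for
duration $t_b - t_i$) and the pseudogenic ratio $\omega_p$ (for
$t_i - t_e$). With one synonymous rate the weights are durations, giving

$$t_i = t_e + (t_b - t_e)\,\frac{\omega_t - \omega_f}{\omega_p - \omega_f};$$

with two synonymous rates the pseudogenic segment's weight scales by
$r = s_p/s_f$ and

$$t_i = t_e + (t_b - t_e)\,\frac{\omega_t - \omega_f}
{(\omega_t - \omega_f) + r\,(\omega_p - \omega_t)},$$

which reduces to the one-rate form at $r = 1$ and is non-increasing in $r$.
Estimates are always clamped to $[t_e, t_b]$: $\omega_t \ge \omega_p$ dates
the event to the branch origin and $\omega_t \le \omega_f$ to the branch
end, with the clamp flagged. $\omega_p \le \omega_f$ leaves no interior
solution and is an error. `gridEstimate()` runs the 2×2×2 grid of
frequency model × $\omega_p$ treatment × rate model and averages over all
valid cells, clamped ones included (a clamped date is still the best
estimate under that model combination).

The two-rate equations need $r$, which published tables rarely print. Two
helpers address this: `synRateRatio()` computes $r$ from per-category
synonymous counts and summed branch durations when those are available,
and `fitRateRatio()` finds the single $r$ that best reconciles a set of
two-rate dates with their one-rate counterparts by least squares. Applying
the latter to the published dating table this package's tests reproduce
yields $r \approx 1.43$, under which every printed two-rate cell is matched
to ~0.01 Ma — a *derived* reconciliation, not a value any source states.
Similarly, where a table prints dates but not the branch ages behind them,
the tests back-solve $t_b$ and $t_e$ from two printed one-rate cells and
then reproduce the remaining six cells and the grid means, which keeps
those checks non-circular.

# The simulator

`simulateCodonAlignment()` draws a root sequence from $\pi$ and evolves it
along the tree with exact matrix-exponential transition probabilities per
codon — no approximate discretisation — under each branch's $\omega$
regime. On a switch branch the segment older than the switch age $t_i$
uses $\omega_f$ and the younger segment $\omega_p$, composing the two
transition matrices; this requires node ages, so switch simulations demand
an ultrametric (ages-mode) tree plus a clock `rate` converting Ma to
expected substitutions per codon. Because stop codons are excluded from
the state space, simulated functional sequences can never contain internal
stops, making injected stops unambiguous ground truth. One seed feeds a
single RNG stream in documented order (root first, then branches in
preorder), so runs are bit-reproducible.

`injectLesions()` mutates an alignment according to directives covering
every scanned lesion class and returns truth records in final alignment
coordinates (insertions are applied right-to-left with coordinate
shifting). `generateScreenMatrix()` plants convergent losses in a
gene × species %intact matrix: lost cells draw uniformly from [0, 75),
retained cells $100 - |N(0, \sigma)|$ truncated to [0, 100], with sporadic
focal (default 0.05) and background (default 0.02) losses and retained-cell
noise $\sigma = 3$ percentage points — values chosen to represent a clean
forward-genomics input where assembly noise rarely pushes a retained gene
below the 90% threshold.

What the generator deliberately does *not* emulate: stochastic indel
evolution (lesions are injected, not evolved), rate heterogeneity across
sites, alignment error, and paralog contamination. Passing round-trip and
recovery tests therefore demonstrates internal correctness of the
statistics, not robustness to dirty real-world alignments.

# Numerical choices and problem sizes

* Transition matrices by eigendecomposition of the symmetrised reversible
  generator; negative entries from roundoff are clipped at 0.
* Likelihood optimisation bounds: $\omega \in [10^{-4}, 50]$,
  $\kappa \in [0.05, 100]$, branch lengths $[10^{-7}, 20]$, all log-scale.
* Dating clamps use closed-form comparisons, no tolerance; forward
  consistency of unclamped estimates is property-tested to $10^{-10}$.
* The pruning likelihood is validated against brute-force summation over
  all ancestral states (with an independent matrix exponential) on 3-taxon,
  5-codon problems to $10^{-8}$, and against the pulley principle (root
  placement invariance) to the same tolerance.
* Parameter-recovery experiments run at 8 taxa × 2000 codons (ω recovery to
  ±0.05 for the background category, ±0.1 for the neutral category over
  seeded replicates) — sizes at which sampling error on ω̂ is a few
  hundredths, large enough to make the checks meaningful and small enough
  to run routinely.
* The counting-based dN/dS cross-check (`countingDnDs`) weights mutational
  opportunities by κ in its site counts; the classic equal-weight counting
  estimator is downward-biased (≈0.89 at κ = 2) even on neutral data, so
  the neutrality invariant is tested with the simulation's κ.

# Known limitations

* The scanner assumes a codon-aware alignment and an intact reference; it
  does not re-align, and paralogous or allelic sequence mixtures will
  produce records that need manual curation.
* No trained splice-strength model is included: splice calls are
  dinucleotide-based, plus the frame-preserving rescue search.
* The codon model is rate-homogeneous across sites (no gamma mixture) and
  shares one κ across branches, matching how branch-model dN/dS analyses
  are typically configured for single genes.
* Dating inherits the mixture model's assumptions: a single instantaneous
  switch from $\omega_f$ to $\omega_p$ on the branch, and externally
  supplied divergence times.
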