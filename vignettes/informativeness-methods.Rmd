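---
title: "Methods: phylogenetic informativeness profiling in phylopi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic informativeness profiling in phylopi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopi)
```

`phylopi` predicts the utility of candidate loci for resolving divergences at
particular depths in time, given alignments over taxa whose relationships are
reasonably known and an ultrametric tree for those taxa. This vignette is the
package's own account of the model, the estimation machinery, the conventions
and numerical choices behind it, and what the simulation-based validation
does and does not establish.

## The informativeness of a site

A site evolving at rate $\lambda$ (substitutions per site per unit of tree
time) contributes informativeness

$$\rho(t;\lambda) = 16\,\lambda^2\, t\, e^{-4\lambda t}$$

toward resolving a divergence at historical time $t$. The time axis runs from
the present at the tips ($t = 0$) toward the root — a convention stated
explicitly because Newick files carry no direction; all epochs, grids, and
figures in the package use it. The shape captures two opposing forces: a site
too slow for an epoch has probably not changed on the short internal branch
subtending the divergence (the $\lambda^2 t$ factor), while a site too fast
will have changed again afterwards and overwritten the evidence (the
$e^{-4\lambda t}$ factor). Consequences the package tests directly:

* $\rho(0;\lambda) = 0$ and $\rho(t;0) = 0$;
* for fixed $\lambda > 0$ the curve is unimodal with its peak at
  $t = 1/(4\lambda)$ and height $4\lambda/e$;
* $\int_0^\infty \rho(t;\lambda)\,dt = 1$: each rated site carries one unit
  of informativeness, distributed over time according to its rate.

Integration over an epoch $[t_1, t_2]$ uses the closed form
$(1+4\lambda t_1)e^{-4\lambda t_1} - (1+4\lambda t_2)e^{-4\lambda t_2}$,
summed over a locus's rated sites. Epoch integrals are always computed from
this closed form, never by integrating the tabulated curve, so rankings are
exact and independent of the display grid (the grid — 1,000 evenly spaced
points on $[0, \mathrm{depth}]$ by default — exists only for tables and
plots).

Two normalisations are reported everywhere: *net* (the plain sum over rated
sites, signal of the locus as a whole) and *per site* (net divided by the
number of rated sites). Per site is the default ranking basis: it compares
loci as sequencing investments per base and is less dominated by locus
length. The per-site denominator is the number of sites with estimated rates,
not the raw alignment length — faulty sites carry no signal estimate, and
counting them would deflate loci with more missing data;
`per_site_denominator = "length"` restores length-based normalisation.
Amino-acid loci use the same functional form applied to their estimated
rates; the four-state-derived constant affects all loci of an analysis
equally and so cannot change a ranking within an alphabet.

## Per-site rate estimation

Rates are estimated per column by maximum likelihood on the fixed tree. The
likelihood of a column is the standard pruning recursion with every branch
length multiplied by the site rate; for a reversible generator $Q$
(normalised so one unit of time at rate 1 yields one expected substitution,
$-\sum_i \pi_i Q_{ii} = 1$) transition matrices come from the spectral
decomposition of the symmetrised generator, so the whole locus is evaluated
in one vectorised pass per rate. Partial likelihoods are rescaled per column
at every step to avoid underflow on larger trees. Under reversibility the
likelihood is root-invariant; the supplied root is used as-is. Zero-length
branches contribute exact identity transitions. IUPAC ambiguity codes expand
to state sets; `-`, `?`, and `N` (DNA) or `X`/`*` (protein) are fully
missing and contribute a vector of ones.

The default model is deliberately assumption-light: JC69 for DNA, the
20-state equal-rates Poisson model for proteins. Richer models are opt-in:
K80/HKY85/GTR parameters can be supplied, or fitted once globally with
`fit_model()`, which maximises the summed log-likelihood of all variable
columns at a shared rate of 1 with empirical base frequencies. Fitting a
model per site would be hopeless (a single column carries far too little
information); fitting globally and then profiling per-site rates is the
compromise the package adopts.

The per-site optimisation is a bracketed scalar search on
$[0, \lambda_{\max}]$: a 33-point quadratically spaced grid locates the
bracket, then a golden-section refinement (relative tolerance $10^{-6}$,
evaluated for all unresolved columns simultaneously) polishes it. The default
box $\lambda_{\max} = 20/\mathrm{depth}$ allows twenty expected substitutions
over the tree height — far beyond saturation, where the informativeness
contribution is numerically nil — while keeping the optimiser bracketed.
Each site receives a status from the package's own taxonomy:

* `OK` — interior maximum found;
* `INVARIANT_ZERO` — all non-missing states identical; the likelihood is
  maximised at $\lambda = 0$, assigned without optimisation;
* `CLAMPED_MAX` — the maximum sits on the upper bound (e.g. a two-taxon
  mismatch, whose likelihood increases monotonically in $\lambda$); the rate
  is reported as $\lambda_{\max}$ and flagged;
* `FAULTY` — fewer than two non-missing states, or a degenerate likelihood;
  the rate is missing (`NA` in memory, the literal `NA` in rate files),
  never silently zero. Faulty sites are excluded from profiles and counted
  per locus.

Identical columns are estimated once and reused; results are identical with
caching on or off because the cached value *is* the per-column computation.
Because the likelihood depends on rate and branch lengths only through their
product, rescaling the tree by $c$ rescales every estimate by $1/c$ and
leaves every ranking invariant — an end-to-end property the test suite
checks at machine precision.

## Input conventions

* **Alignments**: FASTA, Phylip (sequential and interleaved; strict 10-column
  or relaxed whitespace-delimited names) and NEXUS, for DNA or protein. The
  format is sniffed from the first non-blank line unless stated. Alphabet
  detection calls a matrix DNA when at least 80% of its non-gap characters
  are in `{A,C,G,T,U,N}`; `U` maps to `T` on input.
* **Partitions**: NEXUS `charset` statements, including ranges `a-b` and the
  codon-position step syntax `a-b\3`, become named partitions and can be
  profiled as pseudo-loci. Overlapping charsets warn but are honoured. All
  site coordinates in files and reports are 1-based inclusive, matching the
  NEXUS convention.
* **Trees**: Newick or a NEXUS TREES block with translate table; the first
  tree is used (with a warning if there are several). Ultrametricity is
  enforced with a relative tolerance of $10^{-4}$ of the depth — chronograms
  from rate-smoothing software carry rounding noise, so exact equality would
  reject legitimate input; the tolerance is user-adjustable. A basal
  trifurcation is accepted as a root.
* **Taxon reconciliation**: tips present in the tree but absent from a locus
  are pruned from a working copy (with a warning) — the forgiving,
  information-preserving choice; alignment taxa absent from the tree are a
  hard error, since their columns cannot be placed.
* **Branch-length units**: no automatic depth normalisation. Trees in
  arbitrary molecular-evolutionary units work unchanged — rates and epochs
  are then in the same arbitrary unit, and rankings are unit-invariant by
  the rescaling property. `--normalize-depth` rescales depth to 1 so epochs
  can be given as fractions of tree height.
* **Rate files**: the canonical TSV (`locus`, `site`, `rate`, `model`;
  faulty sites as `NA`; loci contiguous; LF endings) is this package's own
  format for the direct-supply path. Rates are written with 17 significant
  digits so a write/read round trip is bitwise exact.

## Rankings

`rank_loci()` sorts loci by the epoch integral on the chosen basis
(per-site by default, `basis = "net"` available — both are always reported).
Exact ties receive competition ranks ("1, 1, 3"), are flagged, and are
ordered by locus label for reproducibility. Epochs must lie within
$[0, \mathrm{depth}]$; multi-epoch reports rank each epoch independently and
add a combined wide table.

## Rendering

The figure places the chronogram above the profiles with a single linear
time transform shared by both panels, so a divergence on the tree sits
exactly above the informativeness available to resolve it. The SVG is
written directly as text: coordinates are formatted to fixed precision and
node order is deterministic (ladderised by clade size, ties alphabetical),
so the same input renders to the same bytes — convenient for version control
and for regression tests that parse the XML. The present is drawn at the
left and the root at the right (`flip_time` mirrors it); the default palette
is a colourblind-safe 8-colour cycle with per-locus hex overrides; only
generic font family names are used so the file ports cleanly into vector
editors. `autoplot()` methods provide ggplot2 equivalents for interactive
work.

## The simulator and what validation shows

`simulate_locus()` evolves independent sites down the tree under the exact
transition probabilities of the chosen model: root states from the
stationary distribution, per-site rates constant, gamma-distributed, or
explicit. Random chronograms are pure-birth (Yule) topologies rescaled to a
requested depth. All randomness flows through R's Mersenne-Twister generator
with explicit seeds, so fixtures are bit-reproducible. The simulator shares
no code with the estimator's likelihood beyond the model object itself, and
its output is checked against closed-form expectations (two-lineage
divergence probability, stationary state frequencies) rather than against
the estimator.

The validation suite simulates data at sizes chosen to exercise the
estimator meaningfully on one CPU — a 16-taxon depth-1 chronogram with 2,000
gamma-rate sites for rank-order recovery, 1,000 constant-rate sites for
calibration, 100 kilobase-scale loci for the end-to-end pipeline — and the
acceptance script reruns the same computations from a caller-supplied seed.

Two caveats delimit what passing simulations demonstrate. First, simulated
data are clean: correctly aligned, indel-free, stationary, with no
among-branch rate variation and a correctly specified model. Real loci
violate all of these to some degree, so recovery statistics here are an
upper bound on field performance. Second, a *single site* is very little
data: the per-site MLE has a discrete sampling distribution whose atoms
(invariant site, one substitution on this or that branch, ...) can be far
apart on small trees. Rank-order recovery across sites is therefore the
meaningful accuracy measure, and it is strong (Spearman correlation ≈ 0.85-0.9
under the conditions above). Location statistics of the estimate
distribution, such as the median of 1,000 per-site estimates at a shared
true rate, inherit the atom structure: on some tree draws the truth falls
between two atoms and the sample median sits 15-20% away regardless of how
much data is simulated. This is a property of per-site maximum likelihood on
few taxa, not of the implementation — the likelihood itself is verified
against brute-force enumeration to $10^{-10}$ and against an independent
implementation (phangorn) to $10^{-10}$, and the optimiser against Brent's
method. Users who need stabilised per-site rates on small trees should
consider pooled estimators (e.g. gamma-posterior means), a documented
extension point that the per-site-independent design deliberately leaves
out.

## Known limitations

* Informativeness predicts signal; it does not model homoplasy (convergence
  and parallelism), so integrals over epochs much deeper than a profile's
  peak are optimistic and should be read cautiously.
* No codon models, no among-branch rate variation, no empirical protein
  exchangeability matrices, no indel information.
* Per-site independent ML is noisy site-by-site (see above); profiles and
  rankings, which aggregate hundreds of sites, are the intended use.
* NEXUS/Newick writing is out of scope; outputs are the rate TSV, profile
  and ranking CSVs, and SVG figures.
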