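---
title: "Detecting non-neutral species modules from co-occurrence data"
author: "cooccurModules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting non-neutral species modules from co-occurrence data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooccurModules)
```

## The scientific question

Spatially implicit neutral theory assumes that all individuals, whatever
their species, are ecologically equivalent: they may respond to the local
environment, but all in the same way. Under this assumption the only
species-level difference that can reach a local community connected to a
common regional pool is the species' regional relative abundance
$\pi_j$. A direct consequence is *rank consistency*: for any two species,

$$\pi_1 \le \pi_2 \;\Longrightarrow\; p_1(i) \le p_2(i)
\quad\text{for every sampling unit } i,$$

where $p_j(i)$ is the presence probability of species $j$ in unit $i$. The
ordering of presence probabilities cannot flip between units. A flip —
species 1 more frequent than species 2 under one set of conditions, less
frequent under another — requires their fitness ratio to change along the
conditions, which is exactly a non-neutral interaction.

`cooccurModules` turns this prediction into a pairwise statistical test
along an ecological gradient, assembles the non-rejected pairs into a
network, reads the network's modules as groups of species with non-neutral
interactions *between* groups, and interprets module composition with
species traits. Only rejections carry information: neutrality can never
produce a rank inconsistency, but many non-neutral regimes (species
sorting, mass effects) can still produce rank-consistent pairs, so
membership in a common module must not be read as positive evidence of
neutrality.

## The pairwise test

For a pair of species the informative units are the *discordant* ones,
where exactly one member of the pair is present; units with both or neither
species carry no information about their relative standing. Discordant
units are split into two subsets $A^*$ and $B^*$ along the gradient, and
the test works from the bivariate count statistic $(N_{1A^*}, N_{1B^*})$:
how often the present species is species 1 in each subset.

Under the null, the conditional probability $q(i)$ that the present species
is species 1 lies on the same side of $\tfrac12$ in every unit (a composite
null: all $q(i) \le \tfrac12$, or all $\ge \tfrac12$). Each one-sided
configuration is bounded by worst-case binomial tails at $q = \tfrac12$:

$$p_1 = \max\{P(\mathrm{Bin}(n_A, \tfrac12) \ge n_{1A}),\;
              P(\mathrm{Bin}(n_B, \tfrac12) \le n_{1B})\},$$

$p_2$ symmetrically for the reverse configuration, and
$p = \min(1,\, 2\min(p_1, p_2))$ Bonferroni-combines the two directions.
The construction is distribution-free and conservative by design; the test
suite verifies its level by exact enumeration of the full bivariate outcome
space over a grid of the composite null. Conservativeness costs power —
that is the deliberate trade, robustness first.

Degenerate inputs are resolved towards non-rejection: a pair with no
discordant unit in one of the subsets is untestable and receives $p = 1$,
and species present in fewer than `minOccurrences = 5` units are removed
before testing, since so few occurrences can never push the two binomial
tails below the usual levels.

### Where to split the gradient

A rank inconsistency between two species reveals itself around the gradient
value where their fitness ratio crosses one, and that value depends on the
pair: with three equally spaced niche optima, the crossing for an
adjacent pair sits near an outer quartile of the gradient, not at the
median. A single median split averages over units on both sides of such a
crossing inside one subset and loses essentially all power against it — at
typical survey sizes the middle of three planted groups is then
undetectable in principle, not merely at reduced power.

The default in `pairwiseRankTest()` is therefore a *fixed scan*: the same
three candidate splits, at the gradient quartiles (0.25, 0.5, 0.75), are
applied to every pair, and each pair's p-value is the Bonferroni-corrected
minimum over the splits. The union bound preserves validity exactly; using
one global set of splits for all pairs keeps the edges of the network
comparable, which per-pair split selection would not. A binary gradient
(e.g. presence/absence of an allelopathic shrub) has its single natural
split and no correction. Quartiles rather than a finer grid keep the
correction factor at 3: finer scans buy little extra power for pairs of
evenly spread niche optima and pay the full correction for all pairs.
`splitByGradient()` exposes the plain single-split (binary level or median)
partition for users who want the narrower test.

## From p-values to modules

`buildConsistencyGraph()` connects pairs with $p \ge \alpha$
(default $\alpha = 0.05$, no multiple-testing correction across pairs — the
graph definition thresholds raw p-values). `detectModules()` runs Leiden
community detection with the modularity objective at resolution 1 on the
unweighted graph; these are the conventional defaults, and on the
near-complete graphs that neutral data produce they return a single
community. Isolated vertices come out as singletons.

Two conventions follow from the reading "one single large module means no
structure": `countEffectiveModules()` counts only modules with at least two
species, and the virtual-experiment trees below discriminate only those
counted modules.

Leiden is stochastic, so real-data workflows aggregate many runs.
`consensusCores()` (default 500 runs, seeded reproducibly from one base
seed via `spawnSeeds()`) computes the pairwise co-assignment frequency
matrix and defines *robust cores* as the connected components (size
$\ge 2$) of the graph whose edges are pairs co-assigned in **every** run —
the strictest reading of "occur in the same modules across replicates",
chosen so that cores are themselves reproducible objects. Species in no
core are reported as unassigned rather than forced into a module.

## Interpreting modules with traits

`fitModuleTree()` fits a CART tree (Gini impurity, via `rpart`) predicting
module membership from species traits, grows it fully (complexity penalty
0) and prunes with the one-standard-error rule on the 10-fold
cross-validated cost-complexity path. Two departures from `rpart`'s
defaults matter and are deliberate:

* **`minsplit = 5`.** The observations here are species, and surveys
  commonly retain only 10–30 of them. A node-size floor of 20 — calibrated
  for datasets orders of magnitude larger — would forbid any split in such
  data regardless of how cleanly a trait separates the modules. Overfitting
  is controlled where it belongs, in the pruning.
* **Significance is a cross-validated drop, not "kept a split".** A fully
  grown path offers many candidate subtrees, and the minimum of that many
  noisy CV estimates undercuts the root error by chance alone often enough
  that "the 1-SE tree retains a split" misfires on unstructured labels
  roughly 40% of the time. The package instead requires the drop to clear
  the joint noise: significant iff
  $x_{err}(\text{root}) - SE(\text{root}) >
   \min_k x_{err}(k) + 2\,SE(\arg\min)$.
  Under random labels this keeps false significance below 10% while clean
  trait structure in as few as a dozen species is always detected (both
  properties are asserted in the test suite). A significant tree always
  retains at least one split after 1-SE pruning; the converse does not
  hold.

Species with missing trait values are dropped per tree with a recorded
count; categorical traits use CART's native subset splits.

## The environmental-filtering simulator

The virtual laboratory is a spatially implicit metacommunity in which
species $j$ has trait $t_j$, unit $i$ has optimal trait $t_{opt}(i)$, and
fitness $w_{ij} = \exp(-(t_j - t_{opt}(i))^2)$ tilts per-capita birth,
death and immigration rates with intensities $\Omega_b, \Omega_d,
\Omega_m$. At stationarity the composition of a unit with $a$ individuals
is drawn in three steps:

1. propose local relative abundances $g \sim
   \mathrm{Dirichlet}(I_i\, w_{ij}^{\Omega_m} \pi_j)$;
2. accept with probability
   $\left(\sum_j g_j w_{ij}^{\Omega_b+\Omega_d} /
   \max_l w_{il}^{\Omega_b+\Omega_d}\right)^{a}$, repeating until
   acceptance;
3. tilt, $\tilde g_j \propto g_j w_{ij}^{\Omega_b+\Omega_d}$, and draw the
   $a$ individuals from $\mathrm{Multinomial}(a, \tilde g)$.

With $\Omega_b = \Omega_d = 0$ or constant traits the acceptance is 1 and
the draw is exactly Dirichlet-multinomial — the neutral prediction. The
suite checks this reduction against the closed-form Dirichlet-multinomial
pmf, and checks the non-neutral sampler against an independent quadrature
oracle at $J = 2$. The density-dependence functions that regulate total
community size in the underlying jump process cancel at stationarity and
are therefore documented but never evaluated; the dynamic, time-stepping
process itself is out of scope.

Numerical choices: fitness powers are computed in log space (large
$\Omega (t - t_{opt})^2$ would underflow naively); Dirichlet parameters are
floored at $10^{-12}$ to avoid degenerate gamma draws; all-zero gamma
vectors (possible at very small shape parameters) are redrawn; proposals
are drawn in geometrically growing batches (16 up to 1024) for speed. The
rejection budget is `maxProposals = 1e5` per unit, and exhausting it raises
an error naming the unit and the estimated acceptance rate — a loud failure
is preferred to a silently biased sample. Budget exhaustion does occur in
a small fraction of extreme parameter combinations (very uneven pools,
$\theta = 0.04$, under strong selection, where a regional pool dominated by
a badly adapted species makes the stationary composition a rare event under
the proposal); the experiment harness records such datasets as failed
rather than dropping them silently, and summary rates exclude them from
their denominators.

## The virtual experiment

`designGrid()` crosses $n \in \{50, 100, 200\}$ sampling units,
pool evenness $\theta \in \{0.04, 0.2, 1\}$ (symmetric Dirichlet parameter
of the regional pool; higher is more even), $F \in \{1, 2, 3\}$ functional
groups (trait values 0.5; 0.25/0.75; 0/0.5/1, each species assigned a
group uniformly at random) and selection intensity
$\Omega \in \{0, 2.77, 11.98\}$ applied to birth and immigration
($\Omega_b = \Omega_m = \Omega$, $\Omega_d = 0$), with 30 replicates per
cell by default — 2430 datasets at full scale. The two non-zero
intensities are calibrated so that a species adapted to the middle of the
gradient loses 50% ($\Omega = 2.77$) or 95% ($\Omega = 11.98$) of its
per-capita rates at a gradient end: $1 - e^{-0.25\,\Omega}$.

Remaining per-dataset inputs: unit optima $t_{opt}(i) \sim U(0,1)$ (these
are the gradient used for testing), $J = 100$ pool species, unit sizes from
a negative binomial with mean 100 and CV 0.25 (dispersion
$r = \mu^2/(\sigma^2 - \mu) = 10000/525$; zero draws redrawn, since a unit
needs at least one individual for presence data to mean anything), and
immigration from a Gamma with mean 5 and CV 0.25 (shape $1/CV^2 = 16$,
scale $5/16$). The distributions are stated by their mean and CV only;
these are the standard parameter conversions. Each dataset gets its own
child seed from a documented spawning rule, so any single dataset is
reproducible in isolation and records are independent of execution order.
The virtual experiment uses a single Leiden run per dataset; consensus
cores are a real-data tool, where the cost of 500 runs is paid once rather
than thousands of times.

The package's own reduced-scale runs — the acceptance script and the
heaviest test blocks — use this grid with 5 replicates per cell (405
datasets), a size chosen so a full sweep completes in minutes on one core
while every cell still contributes several replicates to the rates.

## What the simulator does and does not emulate

It emulates: limited dispersal from a common pool, demographic
stochasticity at stationarity, uneven regional abundance, variable unit
sizes and immigration, and environmental filtering on a single trait along
a single gradient. It does **not** emulate spatial autocorrelation between
nearby units (units are exchangeable given their optima), hierarchical
sampling designs (quadrats within sites), multiple interacting gradients,
temporal dynamics, or direct pairwise species interactions. Passing the
virtual experiment therefore shows that the pipeline detects
filtering-driven departures from neutrality at realistic survey sizes with
a controlled false-positive rate — it does not certify behaviour under
spatially structured or multi-gradient noise, where the independence
assumptions behind the binomial bounds may be optimistic.

## Known limitations

* The test is deliberately conservative; its power against subtle rank
  inconsistencies is limited, and more than two modules demand large,
  species-rich datasets.
* The quartile-scan correction factor is paid by every pair, including
  those a median split would serve best.
* Modularity at resolution 1 inherits the resolution limit of modularity
  optimization; very small genuine modules attached to a large one may not
  be resolved.
* The 100%-co-assignment core rule is strict: with many replicate runs a
  single discordant run removes a species from a core, so core sizes should
  be read as lower bounds on stable module membership.
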