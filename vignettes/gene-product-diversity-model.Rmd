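---
title: "Modeling the evolution of gene product diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the evolution of gene product diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdevo)
```

Many genes express several product isoforms through modification processes
such as A-to-I RNA editing (editing-type: an optional conversion of a
functional unmodified isoform $I_0$ into a modified isoform $I_1$) or
splicing (splicing-type: an obligatory processing step that yields either a
functional isoform $I_1$ or a mis-processed isoform $I_2$). gpdevo implements
a quantitative framework for asking when such diversity is adaptive and when
it is simply what mutation, drift, and imperfect selection leave behind.

## Isoform kinetics

Isoform abundances follow mass-action kinetics: $I_0$ is produced at rate
$\alpha$, converted at per-molecule rates $\beta$, and isoform $I_i$ decays
at rate $\gamma_i$. For the two-isoform system,

$$P_0 = \frac{\alpha}{\beta + \gamma_0}, \qquad
  P_1 = \frac{\alpha\beta}{\gamma_1(\beta + \gamma_0)}, \qquad
  f = \frac{P_1}{P_0 + P_1} = \frac{\beta}{\beta + \gamma_1},$$

where $f$ is the *modification level*. `equilibrium_branching()`,
`equilibrium_chain()`, `equilibrium_multisite()` and `equilibrium_general()`
extend this to one-step branching topologies, multi-step chains, molecules
with $n$ equivalent modifiable sites ($\beta_{i \to i+1} = (n-i)\beta$), and
arbitrary conversion matrices; `equilibrium_alt_transcription()` covers
diversity decided at transcription. All equilibria are computed by direct
linear solve rather than ODE integration — the systems are small and linear,
so the solve is exact; forward integration (deSolve) is kept as an
independent oracle in the test suite. Degenerate systems (an isoform with
inflow but no outflow) are detected by an exact reciprocal-condition check
with threshold $10^{-12}$ and rejected with an explicit error.

Two conventions worth noting. First, the general conversion-matrix solver
implements the full mass balance, including conversion inflow back into
$I_0$; this is what makes the flux identity $\alpha = \sum_i \gamma_i P_i$
hold identically for every topology, and it reduces to the simpler
branching/chain forms whenever no isoform converts back. Second,
`modification_level()` with an all-zero denominator returns 0 with a warning
rather than erroring, so that genotypes with no modification activity at all
remain representable.

## Genetic architecture

The conversion rate is controlled by a *trans*-factor and $l$ *cis*-loci.
Each cis-locus carries an effector or a null allele; with equal additive
effects the genotypic value $v$ is the effector count, $\hat v = v/l$, and

$$\beta = Q\,(C\hat v + \epsilon),$$

where $Q$ aggregates the enzyme's expression and catalytic efficiency, $C$
captures whole-molecule features (e.g. RNA secondary structure) that scale
the cis effect, and $\epsilon$ is nonspecific, genotype-independent activity.
For splicing-type events the same loci control both outcomes with inversely
correlated effects: $\beta_1 = Q(C\hat v + \epsilon)$ and
$\beta_2 = Q(C(1-\hat v) + \epsilon)$, so $\beta_1 + \beta_2 = Q(C+2\epsilon)$
regardless of genotype. `l = 0` is allowed and maps to $\hat v = 0$: the rate
is purely nonspecific, which avoids $0/0$ and matches the meaning of
$\epsilon$. Unequal per-locus effects are deliberately out of scope; the
genotypic-value representation would accommodate them but nothing downstream
implements them.

## Selection and fixation

A functional isoform is under Gaussian stabilizing selection on its log
abundance, $\omega = \exp(-(\ln P - \ln \tilde P)^2 / 2\sigma^2)$; a toxic
isoform contributes $\omega = \exp(-\lambda P)$; components multiply. The
deviation in the stabilizing form is *squared*: the unsquared variant is not
maximized at the optimum and contradicts the meaning of stabilizing
selection, but it is preserved behind `exponent = "linear"` for sensitivity
checks. For deleterious editing the optimum of the unmodified isoform
defaults to $\tilde P_0 = \alpha/\gamma_0$, its abundance in the absence of
modification; for splicing the optimum of $P_1$ defaults to the abundance
reached by the fully committed genotype ($v = l$). A genotype that produces
none of the stabilized isoform (possible for splicing with $\epsilon = 0$ at
$v = 0$) has fitness 0 — effectively lethal — and the chain builder floors
such values at $10^{-300}$ so that selection coefficients into them are $-1$
and out of them effectively infinite, without forming $0/0$.

Fixation probabilities use Kimura's diploid formula
$u(s) = (1 - e^{-2s})/(1 - e^{-4N_e s})$. It is evaluated as a ratio of
`expm1` terms, which is accurate to machine precision for arbitrarily small
$|s|$ (no series switch-over is needed); the exactly-neutral case returns
$1/(2N_e)$, and strongly deleterious cases ($-4N_e s > 700$, where the direct
ratio would overflow) are computed in log space and underflow cleanly to 0.

## Origin–fixation dynamics of the cis-genotypic value

When $2N_e(\mu_{01} + \mu_{10}) \ll 1$ the population is essentially
monomorphic and evolution proceeds one substitution at a time, so $v$ follows
a Markov chain on $\{0, \dots, l\}$ with per-time-step transition
probabilities

$$\Pr(v \to v+1) = 2(l-v)N_e\mu_{01}\,u(s_{v \to v+1}), \qquad
  \Pr(v \to v-1) = 2vN_e\mu_{10}\,u(s_{v \to v-1}),$$

built by `build_transition_matrix()`. The validity condition is enforced
operationally: a warning at $2N_e\mu \ge 0.01$ and an error at $\ge 0.1$.
`evolve_distribution()` computes $\mathbf v_0 T^t$ by binary exponentiation
(27 squarings for $t = 10^8$), renormalizing whenever round-off moves the
total mass by more than $10^{-12}$. Under a flat fitness profile the chain's
stationary law is $\mathrm{Binomial}(l, \mu_{01}/(\mu_{01}+\mu_{10}))$ —
a closed-form oracle the tests verify both by eigen-decomposition and by
propagation in a converged regime ($t \gg 1/(\mu_{01}+\mu_{10})$; note that
at the default $\mu = 2\times10^{-9}$ the relaxation time is $5\times10^8$
steps, so a $10^8$-step run deliberately probes *long-term evolution*, not
the stationary limit).

The headline statistic of `scaling_experiment()` is the modification level
evaluated at the expected genotypic value, $f(\mathrm E[v])$; because $f$ is
nonlinear in $v$ the expectation of the level itself,
$\mathrm E[f] = \sum_v p(v) f(v)$, is reported alongside, and both appear in
all output tables. Editing-type runs start from $v = 0$ and are
parameterized by the optimal expression level via
$\alpha = \tilde P_0 \gamma_0$; splicing-type runs start from $v = l$ and
take $\alpha$ directly (there $\gamma_0 = 0$, reflecting co-transcriptional
processing, so $\tilde P_0$ is undefined).

## Cis–trans coevolution

`simulate_lineage()` couples the cis chains of `n_genes` genes to a shared
trans-factor under opposing selection: each modification is deleterious
(favoring low $Q$), but $Q$ is under stabilizing selection around
$\tilde Q$ through an independent essential function. Trans mutations arrive
as an origin–fixation point process: $m \sim
\mathrm{Poisson}(2N_eU_QL)$ mutations (redrawn if $m > L$) at distinct
uniform time steps; each perturbs $\ln Q$ by $\mathrm{Normal}(0, S_Q)$.
At an event one genotypic value per gene is sampled from its current
distribution and used for *both* the mutant and ancestral fitness (a paired
evaluation), so the selection coefficient isolates the $Q$ change; fixation
uses the same Kimura formula as cis substitutions.
A fixed mutation updates $Q$ and rebuilds every gene's transition matrix.

Two design choices are worth recording. After an event the full cis
distribution of each gene is retained — the sampled genotype serves only
that event's fitness evaluation; the alternative reading (collapse each
gene's distribution to its sampled value) is available as
`collapse_on_sample = TRUE`. And the simulation starts at $Q_0 = \tilde Q$
with intermediate genotypic values ($v_0 = \lfloor l/2 \rfloor$, the value
with the largest genotypic space), representing a newly evolved, unoptimized
modification activity.

Because all genes in this design share one architecture and (without
collapsing) provably identical distributions at all times, the compiled core
tracks a single shared distribution and samples per-gene genotypes only at
events; propagation over an interval of $\Delta t$ steps costs
$O(\log \Delta t)$ vector–matrix products against cached binary powers of
$T$. This makes a full $10^8$-step lineage at $N_e = 10^5$ run in about a
second.

The summary statistics are `qbar()`, the among-lineage mean of the final
$Q$, and `sharing_statistic()`, the among-gene median of the fraction of
lineages in which the modified isoform persists above an abundance
threshold (default $P_1 > 0.005$). With an even gene count the median is the
lower-middle order statistic — deterministic, and it stays on the lattice of
attainable lineage fractions. The characteristic result is a non-monotone
$\bar Q(N_e)$: at small $N_e$ nothing is optimized and the starting state
persists; at intermediate $N_e$ selection lowers $Q$ globally because
individual cis-loci cannot be purged against mutational pressure; at large
$N_e$ cis-substitutions optimize each gene locally and $Q$ returns to its
optimum. The minimum sits near $N_e = 10^4$ under weak trans selection
($\sigma_Q = 20$) and at or below $10^3$ under strong ($\sigma_Q = 2$).

## Simulation along a species tree

`simulate_tree_panel()` evolves a panel of editing-type sites along a rooted
tree with branch lengths in time steps (one step per year in the coleoid
preset). The trans-factor is held constant ($Q = 1$), modeling strong
pleiotropic stabilization. Per-site parameters are drawn by
`sample_site_panel()`: $\ln\alpha \sim \mathrm{Normal}(0,1)$,
$l \sim \mathrm{Uniform}\{0,\dots,10\}$, and
$C \sim \mathrm{Exponential}(\text{mean } 0.1)$ — a moderate mean, well above
$\epsilon = 10^{-4}$ yet low enough that even a fully committed genotype
stays below a ~10% editing level, which is what produces the strongly
right-skewed editing-level distributions seen in coleoid editomes. Half the
sites are selectively neutral (flat fitness over $v$ — the minimal reading
of "neutral"), half deleterious (stabilizing-plus-toxicity fitness with
$\tilde P_0 = \alpha/\gamma_0$).

The root genotype is drawn uniformly from the $2^l$ allele configurations,
i.e. $v \sim \mathrm{Binomial}(l, 1/2)$; along each branch the distribution
starts as a point mass at the parent value, evolves for the branch length,
and a child value is sampled (zero-length branches therefore copy the parent
state surely). Tip genotypes become editing levels
$f = \beta/(\beta+\gamma_1)$, all strictly positive because $\epsilon > 0$
(a $10^{-300}$ floor guards the log transform against pathological
$\epsilon = 0$ configurations). Species distances are Euclidean in
log-editing space, and `neighbor_joining()` (a validated wrapper around
`ape::nj`, the standard implementation for trait distances) reconstructs the
tree; `topology_check()` scores whether the two octopuses form one clade of
the unrooted tree and whether they are closer to each other than the squid
is to the cuttlefish.

The shipped coleoid preset places the octopus–bimac split at 5 My; the
deeper depths (squid–cuttlefish 120 My, root 270 My) are synthetic midpoints
of commonly cited ranges and the file is named accordingly — supply your own
newick tree where precise dates matter. $N_e$ and $\mu$ for this simulation
are free configuration (defaults $N_e = 10^4$, $\mu_{01} = \mu_{10} =
10^{-9}$, matching the global total of $2\times10^{-9}$) and are recorded in
run metadata.

## What the generator does and does not emulate

The synthetic panels reproduce the *distributional* features relevant to the
model — log-normal expression, few cis-loci, a skewed whole-molecule scale,
a neutral/deleterious mixture — but not sequence-level reality: no sequence
motifs, no shared cis-loci between sites, no trans-factor retargeting (guide
RNAs, PPR-style specificity changes), no within-population polymorphism, and
no stochastic finite-molecule kinetics. Passing tests therefore demonstrate
internal consistency of the evolutionary model and its qualitative agreement
with observed editing-level distributions, not a fit to any empirical
editome. One empirical nuance we observed: at the preset $N_e$, deleterious
sites are lower and pile up more heavily below 1% editing than neutral
sites, but their moment skewness is not larger — "more skewed" reproduces in
the concentration-near-zero sense, not in the third-moment sense.

## Numerical and scale choices

Tolerances: equilibria are exact linear solves checked to $10^{-10}$ against
the general solver and $10^{-6}$ against ODE integration; transition-matrix
rows sum to 1 within $10^{-12}$; binary exponentiation matches naive
powering to $10^{-12}$ (as maximum absolute deviation — entries span many
orders of magnitude). The test suite and the shipped experiments use reduced
replication chosen to keep full runs in the minutes range on one CPU: 10
lineages per grid cell for coevolution curves (50 in the reference design;
`n_lineages` restores it), panels of a few hundred to a few thousand sites
for tree simulations (20,000 in the reference design), and 3 seeds with
majority voting for the stochastic minima of $\bar Q(N_e)$. All randomness
flows from a single top-level seed through `substream_seed()`, so
re-ordering or parallelizing replicates cannot change results.

## A worked example

```{r example, eval = FALSE}
# Steady state of a splicing-type gene fully committed to the functional
# isoform (gamma0 = 0, co-transcriptional processing; Q = 100):
arch <- cis_architecture(10, C = 1, epsilon = 0, mode = "splicing")
st <- equilibrium_branching(1, conversion_rate(arch, 10, Q = 100),
                            gammas = c(0, 1, 20))
st$abundances / sum(st$abundances)   # ~1% remains unspliced precursor

# Long-run mean editing level across population sizes:
scaling_experiment(Ne = c(1e2, 1e3, 1e4), l = 5, P0_opt = exp(1), t = 1e8)

# One coevolving lineage:
simulate_lineage(lineage_config(Ne = 1e4, l = 5, sigma_Q = 20), seed = 1)
```
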