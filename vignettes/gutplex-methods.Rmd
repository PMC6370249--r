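---
title: "Methods: coupled social-metabolic dynamics of dietary behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled social-metabolic dynamics of dietary behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutplex)
```

## The model

`gutplex` simulates a population of $N$ individuals whose dietary behavior
(cooperate = eat and share healthy meals, defect = opportunistic high-energy
eating) evolves on a social multiplex network while being coupled, in both
directions, to a constraint-based model of each individual's gut microbial
community.

### Social layer: an iterated snowdrift game on a multiplex

Each of $M$ layers is an independently grown preferential-attachment
(scale-free) graph over the same node set; a node is additionally coupled to
its replica on every other layer with weight $w$ in the supra-adjacency
matrix $\mathcal{A}$. Payoffs follow the snowdrift matrix with benefit $b$
and cost $c$ ($b > c > 0$): mutual cooperation pays $b - c/2$, cooperating
against a defector $b - c$, defecting against a cooperator $b$, and mutual
defection $0$. The snowdrift game is a coexistence game: its well-mixed
replicator dynamics admit the stable mixed equilibrium
$\rho^\ast = 1 - c/(2b - c)$, which is the quantitative anchor we test the
Monte Carlo engine against.

One Monte Carlo sweep performs $N$ elementary steps. In each: a random
player $i$ accrues its payoff $P_i$ against all its neighbors on a random
layer $\alpha$; a random neighbor $j$ of $i$ on a second layer $\beta$
accrues $P_j$ there; then $i$ adopts $S_j$ with the Fermi probability

$$W(S_j \to S_i) \;=\; \eta_i\,\psi_i\,
  \frac{1}{1 + \exp\!\big[(P_i - P_j)/(\theta_{ij}\,\delta_{ij}\,K)\big]},$$

where $K$ is the selection intensity and the two similarities
$\theta_{ij}$ (gut) and $\delta_{ij}$ (homophily) rescale the effective
selection temperature: similar pairs imitate each other more readily.

The cross-layer estimator $\eta_i$ uses communicability — the matrix
exponential $e^{\mathcal{A}}$, a walk-count damped by $1/k!$ — to measure
how strongly the other layer echoes $i$'s current strategy:
$\eta_i = 1 - (\eta^{\max} - \eta^{\min})\, m_{\rm same}/m_{\rm all}$,
where the masses sum the communicability entries from $i$ on $\alpha$ to
the nodes of $\beta$ with (numerator) and without (denominator) the
restriction to $i$'s strategy. A node whose strategy saturates the other
layer is pinned ($\eta = \eta^{\min} = 0.1$); one echoed nowhere is free
($\eta = 1$). We exclude $i$'s own replica from both sums: it trivially
shares $i$'s strategy, and including it would make complete disagreement —
one of the estimator's two boundary states — unreachable.

The psychological estimator $\psi_i$ counts micro-affirmations (MA: the
opponent cooperated) and micro-inequities (MI: the opponent defected)
accumulated over the epoch. With $r = \sum MI / (\sum MA + \sum MI)$,
$\psi_i = 1 - (\psi^{\max} - \psi^{\min})(1 - r)$: an all-affirmation
experience pins the node to its strategy ($\psi = 0.1$), an all-inequity
experience maximizes its urge to switch ($\psi = 1$). The ratio-of-sums
form is the only reading of the counter ratio that keeps $\psi$ inside its
declared range for all counter values. A node with no interactions yet is
treated as satisfied ($\psi = \psi^{\min}$), matching the all-zero
initialization.

### Gut layer: lexicographic community FBA

The community model holds $S$ species sharing an extracellular compartment
with exchange metabolites grouped into sugar, fiber, fat and protein
classes. A diet (carbohydrate/fat/protein percentages summing to 100, plus
a sugar share of carbohydrate) becomes uptake bounds: with fractions
$f_C, f_F, f_P$ and basal rates $B$,

$$C_u = 2 f_C B \cdot \{s, 1-s\}, \qquad F_u = 2 f_F B, \qquad P_u = 2 f_P B,$$

where $s$ is the sugar fraction ($0.5$ by default, $0.9436$ for the
Western preset, so at the default split each carbohydrate metabolite
receives $f_C B$ and fats/proteins carry the compensating factor 2).
Uptake is a negative exchange flux, so exchange lower bounds are set to
$-A_u$. Basal rates default to 1 for every class — a deliberately neutral
choice; survey-derived per-metabolite values can be supplied instead, and
carbon-number scaling is represented only through these rates.

Growth is computed by lexicographic flux balance analysis over the ordered
per-species biomass objectives $c_1, \dots, c_S$ (commensals and probiotics
ahead of pathogens and host in the motivating 12-species ordering): level
$k$ maximizes $c_k \cdot v$ subject to steady state $\Lambda v = 0$, flux
bounds, a minimal growth floor of $0.01$ on every biomass reaction, and all
earlier optima held within a slack of $10^{-6}$. The slack
(equality-with-tolerance rather than a hard fix) is kinder to the solver
and gives the monotone property that relaxing it never lowers later
optima. Alternate optima at the final level are resolved deterministically
by the solver's fixed pivoting rules; the returned flux vector is
well-defined but not unique in the mathematical sense, which is the usual
caveat of FBA flux values.

The linear programs are solved by the package's own dense two-phase
simplex (Dantzig pricing with a Bland fallback for anti-cycling,
deterministic tie-breaks by lowest index). Tests cross-check every
lexicographic optimum against an independent vertex-enumeration oracle on
small models.

### The toy community generator

`generate_toy_community()` draws a small always-solvable community in the
structural image of a genome-scale gut reconstruction: per species, uptake
reactions for all four nutrient classes, an ATP-synthase-like reaction, a
reversible amino-acid interconversion (so that any macronutrient mix can
feed growth), an ATP-maintenance sink and a biomass reaction draining
carbon, amino and ATP pools in randomized proportions; subsystem labels
come from a fixed vocabulary. Feasibility under the 50/30/20 reference
diet (every species' biomass at least 0.01) is verified at generation time
by an actual lexicographic solve. What the generator does *not* emulate:
realistic stoichiometry and pathway structure, gene—protein—reaction
rules, per-metabolite diversity within a nutrient class (one exchange
metabolite per class), or cross-feeding chains. Passing tests therefore
demonstrate the correctness of the machinery on community-structured
models, not biological predictions about real gut communities.

### Feedback loop

After each epoch of $N_r$ sweeps, every node's happiness index
$\gamma_i \in [0,1]$ is its fraction of cooperative rounds. Nodes with
$\gamma_i \ge \gamma_{th}$ take the positive branch: their MA counter is
amplified, $MA \leftarrow MA(1 + \epsilon_i)$ with the gut bias
$\epsilon_i = \sum MA / N_r$; the others amplify MI analogously with
$\epsilon_i = \sum MI / N_r$. The amplified counters are carried into the
next epoch's $\psi$, and $\epsilon$ may exceed 1 — it is a per-round rate,
not a probability. Each node's diet is then re-drawn: every macronutrient
percentage moves within $\pm(1-\gamma_i)\cdot 10$ percentage points
(integer draws; carbohydrate and fat drawn, protein set to the remainder
and accepted iff inside its own limits, with enumeration of the feasible
integer pairs as a fallback and a widen-by-one retry in the impossible
case). A fully happy node keeps its diet exactly. The new diets are
re-solved (profiles are memoized per distinct diet — the solve is a pure
function of the diet), the gut similarity
$\theta_{ij} = \max(\text{floor},\, 1 - d_{ij}/d_{\max})$ is recomputed
from Euclidean distances between flux profiles, and the population is
re-clustered by Ward's minimum-variance linkage.

The text motivating this design states both that $\gamma$ derives from
cooperation counts and that biomass/ATP-synthase fluxes recalculate
$\gamma$; the two readings cannot be reconciled, so the package exposes
`gamma_mode`: `"behavioral"` (default; counts only) and `"blended"`
(average of the behavioral value and the node's min–max-normalized
biomass + ATP-synthase flux sum).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `b`, `c` | 1, 0.8 | snowdrift benefit/cost; gives $\rho^\ast = 1/3$, a defector-majority mixed equilibrium |
| `K` | 0.1 | selection intensity (Fermi temperature scale) |
| `eta_min`, `psi_min` | 0.1 | estimator floors; keep the dynamics off frozen states |
| `delta_floor`, `theta_floor` | 0.05 | similarity floors; keep the Fermi denominator positive |
| `coupling_weight` | 1 | inter-layer replica coupling in the supra-adjacency |
| `attachment` | 2 | preferential-attachment edges per node (the topology is only specified as scale-free; 2 gives mean degree near 4) |
| `gamma_th` | 0.5 | happiness threshold; an unbiased midpoint, no value is prescribed by the motivating text |
| `n_rounds_per_epoch` | 100 | sweeps per epoch; long enough for the baseline to settle at the scales used here |
| `n_feedback_rounds` | 4 | feedback rounds after the baseline epoch |
| `sugar_fraction` | 0.5 | carbohydrate sugar share outside the Western preset (0.9436) |
| `min_biomass` | 0.01 | minimal growth floor on biomass reactions |
| `fba_tolerance` | $10^{-6}$ | inter-level slack of the lexicographic solve |

Diet presets: Western (50/35/15 with the 94.36/5.64 sugar/fiber split),
high-fat 20/60/20, high-carbohydrate 70/15/15, high-protein 20/20/60. The
Western macronutrient split and the other three compositions are package
choices representative of each dietary pattern; only the Western
sugar/fiber split is prescribed. Four nodes start on the presets; the
rest draw uniformly from the integer simplex.

## Design choices in the open corners

**Homophily coupling and its normalization.** The coupling is a similarity
$\delta_{ij} = \max(\text{floor},\, 1 - |h_i - h_j|/s)$ with $s$ defaulting
to the largest pairwise attribute difference, so the most dissimilar pair
sits exactly at the floor. This relative normalization has a consequence
worth stating plainly: for normally distributed attributes it is
*scale-invariant* — the distribution of $\delta$ is identical whether the
attribute spread $\sigma$ is 1 or 8, because the ratio of pairwise
differences to their maximum does not depend on $\sigma$. Any contrast
between narrow- and wide-spread homophily regimes therefore requires a
fixed normalization; `delta_matrix(scale =)` provides it, and the
package's homophily experiment uses a fixed reference scale of 5
(approximately the maximal spread of the $\sigma = 1$ regime, so narrow
populations sit near full coupling while wide ones floor out).

**Layer pair per elementary step.** $\alpha$ is drawn uniformly (redrawn
if the player is isolated there); $\beta$ is drawn uniformly among the
*other* layers, falling back to $\alpha$ only in the single-layer case.
Payoffs are recomputed freshly per elementary step (memory-1 play);
accumulation across rounds lives in the MA/MI counters and the
cooperation history.

**Communicability.** Defined as the exponential of the supra-adjacency
with uniform inter-layer coupling (default 1), the standard multiplex
communicability construction; the motivating text references it without
writing the formula.

**Clustering.** Ward linkage on raw (unstandardized) flux distances — all
fluxes share units; a z-score option exists but is off by default.
Cluster labels are a reporting device (default cut at 0.7 of the maximum
merge height); the dynamics couple to the gut layer only through
$\theta$, never through the labels.

## Problem sizes and what the experiments show

The package's own reference experiments (in the test suite) run at desk
scale, chosen as the sizes a laptop solves in minutes: the well-mixed
equilibrium check uses a 50-node complete graph over 150 sweeps and 10
seeds; the feedback experiment uses 50 nodes, 2 layers, a 3-species
community, 100 sweeps per epoch and 4 feedback rounds over 10 seeds; the
homophily contrast uses 50 nodes and 25 seeds per regime. The full
defaults (100 nodes, 12 species) run in a few minutes per trajectory and
are exercised end-to-end at reduced size in the unit tests.

Two properties of the dynamics at these scales deserve honesty. First,
they are strongly *bistable*: individual trajectories tend toward either
a high-cooperation state or extinction of cooperation (an absorbing state
of imitation dynamics), so all population-level claims are seed-averaged.
Second, the feedback loop amplifies whatever strategy a happy node
currently holds — MA amplification freezes strategies rather than
promoting cooperation directly — so a cooperation rise after feedback is
expected only when the positive branch dominates a cooperative
population, and trajectories are matched qualitatively, never
numerically.

## Known limitations

* The community model is a structural toy; no claim about real gut
  communities or the pathway rankings of genome-scale models follows from
  it. The SBML path exists precisely so that real reconstructions can be
  substituted.
* The LP solver is a dense tableau simplex: appropriate for hundreds of
  reactions, not for genome-scale models with tens of thousands.
* Network topology is static; only strategies, diets, counters and
  clusters evolve.
* Correlation analyses are exploratory (no multiple-testing correction is
  applied, and none is claimed).
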