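---
title: "Simulating invasion and colonization resistance in chemically mediated microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating invasion and colonization resistance in chemically mediated microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`invasim` simulates communities of microbes whose only interactions run
through diffusible chemical mediators that members release into, and take up
from, a well-mixed environment. Its purpose is the *in silico* invasion
assay: assemble a stable resident community from a random species pool,
introduce a newcomer, and ask whether the community resists, absorbs, or is
damaged by the invasion. This vignette documents the model, every tunable
parameter with its units and default, the design choices that were genuinely
open, the numerical scheme, and what the synthetic setting does and does not
say about real communities.

## The mediator-explicit model

The state is a vector of cell densities $S_j$ (cells/ml), mediator
concentrations $C_i$ (fmole/ml), and optionally a single limiting resource
$R$ (fmole/ml). In the basic model,

$$\frac{dC_i}{dt} = \sum_j \Big[\beta_{ij} - \alpha_{ij}\,
  \frac{C_i}{C_i + K_{ij}}\Big]\, S_j,
\qquad
\frac{dS_j}{dt} = \Big[r_{j0} + \sum_i r_{ji}\,
  \frac{C_i}{C_i + K_{ji}}\Big]\, S_j.$$

Every species grows exponentially at its basal net rate $r_{j0}$, modulated
additively by the mediators: a positive influence amplitude $r_{ji}$ is
facilitation, a negative one inhibition, each saturating with half-max
concentration $K_{ji}$. Mediators are produced at constant per-cell rates
$\beta_{ij}$ and consumed by saturating per-cell uptake $\alpha_{ij}$; the
same $K$ governs uptake and growth influence. There is no abiotic decay:
mediators leave the system only through consumption and dilution.

The resource variant multiplies each species' whole growth-rate bracket by a
Monod factor $R/(R + K_{R,j})$ and consumes the resource in proportion to
the realized growth rate with per-cell rate $\alpha_{R,j}$. The resource is
never produced; it is supplied in fresh medium and replenished at every
dilution. We follow the growth-rate-proportional consumption form literally,
which means a species with a (transiently) negative realized growth rate
contributes a small positive term to $dR/dt$; in practice growth-arrested
species contribute almost nothing because the bracket is near zero, and $R$
is clamped at zero like every other state variable.

### Growth–dilution cycles

Communities live in serial batch culture. Growth starts from a total density
of $10^4$ cells/ml; when the total reaches $10^7$ cells/ml the culture is
diluted back to $10^4$ (a $\sim$1000-fold dilution), carrying species and
mediators down by the same factor and resetting the resource. In the
resource variant a cycle also ends after 80 hours, so that turnover
continues even when the resource cannot support 1000-fold growth. After each
dilution, any species below the extinction threshold of 0.1 cells/ml is
removed permanently.

A *generation* is one doubling of total community density, accrued per
growth interval as $\log_2(\text{end}/\text{start})$; this makes the sum of
per-interval contributions equal the log of the cumulative fold growth
exactly, and makes 200 generations come out to $\sim$20 cycles of 1000-fold
growth in the basic model, or however many capped cycles the resource level
allows. Both assembly and the post-introduction assay run for 200
generations. Runs stop at the generation target, which can fall mid-cycle.

### Units

Concentrations are held internally in fmole/ml; 1 nM = 1000 fmole/ml, so the
mediator saturation range of 50–150 nM becomes $5\times10^4$–$1.5\times10^5$
fmole/ml. This closes the dimensions of the production term (fmole
cell$^{-1}$ hr$^{-1}$ times cells/ml). Two nominal parameter listings
conflict with the distributional definitions used throughout: a tabulated
average saturation of $10^4\,\mu$M and a resource half-max of 1 mM. We treat
the distribution statements as authoritative. For the resource half-max, a
literal 1 mM ($10^9$ fmole/ml) would pin the Monod factor below $10^{-3}$ at
the default resource supply $R_0 = 10^6$ fmole/ml — nothing could grow
within an 80-hour cycle and the 200-generation assay would be unreachable.
We therefore default $K_{R,j}$ to a uniform draw on $5\times10^5$–$1.5\times
10^6$ fmole/ml, comparable to $R_0$, so that growth is genuinely
resource-limited and the resource is depleted within a growth round; the
range is a configuration field for users who prefer another convention.

## The random ensemble

`generator_config()` holds the ensemble parameters:

| parameter | meaning | default |
|---|---|---|
| `n_species` | species pool size | 20 |
| `n_mediators` | number of mediators | 10 |
| `r0_range` | basal growth rate (hr$^{-1}$) | 0.08–0.12 |
| `influence_range` | influence amplitude $|r_{ji}|$ (hr$^{-1}$) | 0–0.2 |
| `beta_range` | production (fmole cell$^{-1}$ hr$^{-1}$) | 0.05–0.15 |
| `alpha_range` | consumption (fmole cell$^{-1}$ hr$^{-1}$) | 0.25–0.75 |
| `K_range_nM` | saturation concentration (nM) | 50–150 |
| `q_p` | producer connectivity | 0.3 |
| `q_c` | influence connectivity | 0.3 |
| `f_fac` | facilitative fraction, resident–resident | 0.5 |
| `f_fac_inv` | facilitative fraction, resident→invader | 0.5 (0.1 in the standard assay) |

Each (mediator, species) production link exists independently with
probability `q_p`, each (species, mediator) influence link with `q_c`, and
rates are drawn uniformly on existing links; influence signs are positive
with probability `f_fac`. Only these two connectivities exist in the
ensemble definition, so the consumption topology is a design choice: **a
species consumes exactly the mediators that influence it**, with $\alpha$
drawn independently of the influence amplitude. This reflects uptake-coupled
sensing — a chemical affects the cells that import it — and keeps
production and influence as the two independently tunable link types.
Because rates are stored separately, invader production, consumption and
influence can still be ablated independently.

The invader is drawn over the *same* mediator set with the same
connectivities (separately overridable), influence signs positive with
probability `f_fac_inv`, and a basal rate drawn from the resident
distribution then multiplied by `r0_ratio` — so the default ratio 1.5 gives
"on average a 50% basal-rate advantage" while preserving resident-scale
variability. Invader saturation constants are redrawn from the same range.
`ablate_invader()` zeroes any combination of the three channels without
touching link bookkeeping, giving the eight keep/remove combinations.

All draws are seed-controlled. Experiments derive one child seed per
replicate from the root seed with a counter-based modular hash
(`child_seed()`), so any replicate can be regenerated in isolation, and a
matched-seed mode reuses identical replicate seeds across grid points for
paired contrasts.

## Numerical integration

The equations are integrated with forward Euler, the scheme under which the
model family is defined in batch-culture studies. The step is set from the
shortest *achievable* doubling time: $dt = \ln 2 / \mu_{max} / 10$, where
$\mu_{max}$ is the largest basal rate plus the sum of that species' positive
influence amplitudes — a conservative bound, since saturating influences
rarely realize fully. State variables are clamped at zero after each step.
Clamping concentrates on mediators whose consumption capacity exceeds their
production: their true dynamics hover at a small positive quasi-equilibrium
that explicit Euler repeatedly undershoots. On default parameters one to two
percent of steps clamp some variable; the clamp counter is returned with
every run so users can audit it.

Accuracy is first-order, and over a full 1000-fold growth cycle the global
relative error is approximately $\mu \ln(1000)\, dt / 2$ — about 1% at the
default step, shrinking linearly with $dt$. The test suite checks this
convergence against closed forms (interaction-free growth follows the
discrete compound-growth law exactly) and against an adaptive multistep
reference integrator on small instances; outcome classifications, which is
what the assay consumes, are insensitive to halving the step. Euler steps
overshoot the dilution threshold by up to one step's growth; the dilution
factor and the generation bookkeeping use the actual overshot total, which
keeps generation accounting exact.

Two guards handle degenerate runs: in the basic model a cycle lasting more
than ten times the slowest interaction-free cycle duration flags the run as
stalled (the community cannot reach the threshold — effectively a
collapse), and a hard cap bounds total cycles and steps.

## Assembly, stability, and why stability is enforced

Assembly follows the enrichment procedure: inoculate all pool species in
equal proportions at $10^4$ cells/ml into fresh medium (mediators start at
zero), run 200 generations of growth–dilution cycles, and harvest the
species above the extinction threshold. With default parameters the
assembled communities hold a handful of coexisting members (mean richness
around 3.5 out of 20; the acceptance script recomputes this).

Surviving 200 generations is not the same as being settled.
`check_stability()` re-inoculates a harvested community and continues it;
a community is called stable if no member is lost and no member's
pre-dilution relative abundance drifts by more than 1% (absolute) over the
final three cycles. A substantial minority of 200-generation survivors fail
this check — slow competitive exclusions with growth-rate gaps of order
$10^{-3}$ hr$^{-1}$ need thousands of hours to resolve, and the failure rate
*rises* with the facilitative fraction among residents, because facilitation
sustains near-neutral members longer.

This matters for the assay taxonomy: if residents keep dropping out on
their own, an invasion assay misreads that endogenous attrition as
invader-caused damage ("disruption"), and at high `f_fac` the bias is strong
enough to mask the strengthening of colonization resistance by resident
facilitation. Since the assay is defined against *stable* resident
communities, `run_invasion_chain()` and `sweep_invasion()` therefore
regenerate pools until the assembled community passes the stability check
(50 extra generations, 1% drift) by default. The unfiltered procedure —
stability operationalized as bare 200-generation survival — remains
available via `require_stable = FALSE`, and the number of regenerated pools
is reported with every sweep. Collapsed pools (no survivors) are likewise
regenerated from fresh child seeds and counted.

## The invasion assay

`introduce()` re-inoculates the residents into fresh medium at $10^4$
cells/ml in their harvest proportions, carries the harvest mediators over
diluted by the re-inoculation factor, and adds the invader at
`propagule_fraction` times the resident inoculum (0.3% in the standard
assay; the propagule grid spans $10^{-4}$ to 0.99 in 20 log-spaced points).
Introduction happens at a transfer, mirroring how cells are added to a
culture at passage. A propagule below the extinction threshold (under
$10^{-5}$ of the inoculum) is flagged sub-detectable.

After 200 further generations, `classify_outcome()` applies the 2×2
taxonomy: did the invader persist, and did every pre-invasion resident
persist?

|  | residents all persist | some resident lost |
|---|---|---|
| **invader extinct** | resistance | disruption |
| **invader persists** | augmentation | displacement |

Persistence defaults to the only numeric criterion the model defines:
final density above the extinction threshold, applied to invader and
residents alike. A stricter fraction-based rule for the invader (final
relative abundance at least its introduced relative abundance) is available
via `persistence = "fraction"`; it reclassifies slow-declining invaders
that have not yet crossed the extinction threshold at 200 generations. The
headline trends are the same under both rules.

## Experiments and statistics

`sweep_invasion()` runs the battery: propagule size, invader growth-rate
ratio, `f_fac_inv`, `f_fac`, the eight ablation combinations, invader
connectivities, invader rate magnitudes, and resource supply ($10^5$–$10^7$
fmole/ml under the resource model). Each grid point tallies the four
outcomes over `n_instances` independent replicate chains
(network → enrichment → invader → assay), each from its own derived child
seed, with exact Clopper–Pearson intervals (`clopper_pearson()`, Beta
quantile form, 80% by default) on every frequency. Grid resolutions for the
growth-ratio and facilitation sweeps are not dictated by the ensemble
definition; the defaults (0.5–2.5 in steps of 0.25, and 0.1–0.9 in steps of
0.1) cover the ranges those contrasts are reported over.

Monotone-trend claims are tested, not eyeballed: with matched seeds the
contrast between two grid points is paired per replicate, and a one-sided
exact binomial test on the discordant pairs (McNemar-style) decides the
direction at the 5% level. The test suite exercises the battery at
$N_s = 200$ replicates per condition — desk scale chosen so the whole suite
runs in well under a minute of simulation per contrast — while the
production default is $N_s = 1000$ and the ablation battery is typically run
at $N_s = 10^4$.

Reproduced at desk scale: outcome frequencies are insensitive to propagule
size below about 1% and resistance erodes only for near-total propagules;
facilitation of the invader converts resistance into displacement;
facilitation among residents strengthens resistance (with the stability
filter; without it the trend drowns in endogenous attrition, see above); a
larger basal-rate advantage shifts outcomes to displacement; and removing
invader production suppresses augmentation in favour of displacement.
Two-compartment reasoning suggests a stronger version of the last trend:
without facilitation in either direction, stable coexistence should be
impossible, so production ablation under mostly-inhibitory influence might
be expected to eliminate augmentation entirely. It does not here:
augmentation drops by about forty percent, not to zero. The residue is
dominated by invaders that happen to have no *active* mediator influence
(probability $\sim(1-q_c \cdot a)^{10}$ with only a fraction $a$ of the 10
mediators actively produced in a small assembled community) and a
basal-rate gap too small to resolve extinction or displacement within 200
generations — stragglers that any persistence cutoff classifies as
coexisting. The acceptance suite includes the stringent elimination check
and reports the measured value against it.

## What the synthetic setting does not capture

Everything here is well-mixed batch culture with deterministic dynamics:
no spatial structure, no demographic noise (extinction is a hard density
threshold, not a stochastic event), no contact-dependent interactions, no
host feedback, no mediator decay, one invader at a time, and a single
implicit or explicit resource axis. Passing trends in this ensemble show
that chemical-mediator interaction structure *can* produce them, and under
which interaction regimes; they do not quantify any real community, and
parameter magnitudes (rates, thresholds, propagules) matter only through
the dimensionless balances described above.
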