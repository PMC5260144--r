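---
title: "Model and methods: multiscale simulation of macrophage polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: multiscale simulation of macrophage polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macpol)
```

`macpol` couples two levels of description of the immune response to an
antigenic challenge:

* a **microscopic** level: every macrophage agent carries a synchronous
  Boolean gene regulatory network (GRN) whose fixed points define terminal
  polarization into the pro-inflammatory M1 or the anti-inflammatory M2
  phenotype;
* a **mesoscopic** level: macrophages, B cells and helper T cells, together
  with discrete tokens of antigen, antibody and the cytokines IFN-γ, IL-4
  and IL-10, diffuse on a periodic `L × L × L` lattice and interact through
  local stochastic contact rules (a reactive lattice gas automaton).

The two levels are joined by the differentiation rule: at every step, each
undifferentiated, activated macrophage clamps its GRN inputs to the locally
sensed stimuli and advances the network; reaching the marker fixed point
commits it irreversibly.

## The regulatory network

The bundled network (`default_network()`) has 18 nodes: four stimulus
inputs (IFNg, IL-10, IL-4, LPS), four receptors (IFNgR, IL-10R, IL-4Ra,
TLR4), and ten internal transducers/transcription factors/target genes. The
M1 branch is LPS→TLR4→NF-kB→NOS2 plus IFNg→IFNgR→STAT1→{SOCS3, NOS2}; the
M2 branch is IL-4→IL-4Ra→STAT6→{PPARg, SOCS1, KLF4, Arg1} plus
IL-10→IL-10R→STAT3→IL-4Ra. Cross-inhibition couples the branches: SOCS1
silences STAT1, SOCS3 silences STAT3, and KLF4, PPARg and STAT3 all repress
NF-kB. One note on SOCS1: some experimental literature describes SOCS1 as
promoting M1; here it is STAT6-induced and M2-associated, consistent with
its inhibition of STAT1 in the wiring above.

The update rule is the standard activation/inhibition map: a node switches
on iff at least one activating parent is on and no inhibiting parent is on.
Input nodes have no parents and are only changed by clamping, so the
clamped dynamics hold them constant.

```{r}
net <- default_network()
net
```

### Attractors, exhaustively

With 18 nodes the full transition table (`transition_table()`) and exact
fixed-point enumeration per stimulus (`enumerate_fixed_points()`) are
cheap, so nothing about the attractor landscape is approximated:

```{r}
rep <- attractor_report(net)
rep[rep$label != "none", c("stimulus", "active", "label")]
```

Two structural facts drive everything downstream:

* **The M1/M2 attractors are stimulus-indexed families.** Under clamping,
  the input bits are part of the state, so the NOS2-active fixed point
  under IFNg alone differs from the one under LPS alone or under both. The
  package therefore defines commitment through the *marker*: for each of
  the 16 stimulus vectors, validation requires at most one NOS2-active and
  at most one Arg1-active fixed point, and no fixed point carrying both
  markers. `classify()` reads the stimulus off the state's own input bits.
  This is also what guarantees, operationally, that a macrophage can reach
  at most one committed phenotype per update (the probability functions of
  the two commitment transitions can never both be 1).
* **Anti-inflammatory dominance.** Whenever IL-4 or IL-10 is part of the
  stimulus the network resolves to the Arg1-active fixed point (STAT3 and
  the STAT6 targets jointly silence NF-kB and STAT1); NOS2-active fixed
  points exist only under pure IFNg/LPS regimes.

Under *conflicting* mixed stimuli (e.g. IFNg and IL-10 on, with IL-4 and
LPS off) the negative loop STAT1→SOCS3⊣STAT3→IL-4Ra→STAT6→SOCS1⊣STAT1 has
no stable resolution from some starts and the synchronous dynamics orbit a
limit cycle. `iterate_until_convergence()` detects and reports cycles; a
cycling macrophage is simply never committed. Asynchronous or probabilistic
update schemes, which would break such cycles, are out of scope.

## The mesoscopic rules

`rule_table()` lists the 15 contact rules: macrophage activation by IFN-γ
(consuming the token), antigen phagocytosis/presentation by macrophages and
B cells, reversion of presenting/active states, cytokine release upon
presentation to the three helper classes (Th1→IFN-γ, Th2→IL-4, and
Treg→IL-10 on contact with M2 presenters), B-cell/helper duplication with
antibody release, helper activation by presenting cells, and
antibody–antigen neutralisation. All rules fire with probability 1 whenever
their reactants co-occur on a site; the rule order is shuffled at every
site and step to avoid scheduling bias. Within a step, an entity consumed
or state-changed by one firing cannot take part in another rule; catalytic
participants (unchanged by their rule) remain available, but each rule
fires at most once per disjoint reactant pair per pass. In the type-2
duplication rule the duplicated helper class is Th2, matching its gloss
("same as the type-1 rule, for type-2").

Two completions were needed to make the printed rule set a closed, living
system, and both are configurable:

* **B-cell presentation to helpers** (`b_cell_presentation`, default on).
  As printed, helper activation requires a presenting *macrophage*;
  presenting macrophages require activation by IFN-γ; and every IFN-γ
  source requires an already-active Th1. From any all-resting start this
  system is provably inert. B cells are professional antigen-presenting
  cells, and the model's own definition of "presenting" (processed antigen
  displayed with MHC) applies verbatim to presenting B cells, so rule 12
  accepts either presenter. A small tonic activation rate for resting
  helpers (`helper_background_activation`, default 0.01 per step) keeps a
  standing bystander-activated pool, as observed in vivo.
* **IL-10 immunosuppression** (`il10_suppression`, default on). As
  printed, IL-10 appears only as a product and as a GRN input, with no
  effect on any cell-level rule — yet IL-10 is a potent down-regulator of
  antigen presentation (via MHC-II) and of pro-inflammatory cytokine
  release. At any site holding at least one IL-10 token, the
  antigen-presentation rules (2, 8) and the IFN-γ-release rules (5, 14) are
  vetoed. The action is binary locally but dose-graded at the system level
  through spatial coverage, which is what makes the dampening experiment
  calibratable.

Two bookkeeping extensions bound an otherwise unbounded system: antigen
replicates (`ag_replication`, default 0.05 per token-step) under a logistic
carrying capacity (`ag_capacity`, default 40 000 at `L = 16`), and each
cell kind is capped at a multiple of its initial count
(`cell_cap_mult`, default 6) so the duplication rules cannot run away in
uncontrolled infections. Cytokines and antibodies decay with a 20-step
half-life; without decay, token counts grow without limit.

## The lattice and the step

Agents and tokens occupy integer counts per site of a periodic `L³`
lattice; all species diffuse identically (one of the six von Neumann
neighbours or the current site, uniformly). Each step runs: contact rules
at every site (site order shuffled) → differentiation of eligible
macrophages → diffusion → replication/decay/injections → census. The
differentiation phase reads each macrophage's local stimulus (cytokine
token presence; LPS from co-located LPS-bearing antigen), advances its GRN
`k` times, and tests attractor membership.

`k = 6` by default: every pure-stimulus attractor of the bundled network
lies at depth ≤ 6 from the naive all-zero state, so a macrophage under a
sustained local stimulus can commit within a single eligible step. This
matters because the unit-probability reversion rules make activation
episodes short (an active macrophage not meeting antigen rests again
immediately); with `k = 1`, commitment would require 4–6 *consecutive*
eligible steps under uninterrupted stimulus, which the churn makes
vanishingly rare at realistic densities. Biologically, `k = 6` states that
transcriptional cascades are fast relative to the ~3-hour mesoscopic step.

Determinism: one R RNG stream drives the whole replicate (the compiled
engine draws from R's generator), so a configuration plus seed reproduces a
run byte for byte.

## Study conditions and what the generator does not emulate

The reference conditions (`simulation_config()` defaults) are a 16³
lattice with 500 macrophages and 2 500 lymphocytes — the ≈5:1
lymphocyte:monocyte ratio of a standard human differential count — run for
800 steps at 8 steps per day. The simulated volume is a well-mixed,
homogeneous medium: no chemotaxis, no tissue structure, no receptor
kinetics, no cell death or aging, no clonal selection (lymphocytes are
antigen-specific by construction). Cytokine "concentrations" are discrete
unit tokens; stimulus sensing is presence/absence, not dose-response.
Passing tests therefore demonstrate the coherence of the regulatory logic
under the stated interaction rules, not quantitative agreement with any
wet-lab kinetics.

## The three challenge experiments

`scenario()` packages the three experiments; `run_scenario()` runs seeded
replicate ensembles (replicate *r* uses `base_seed + r`) and aggregates
mean ± sd kinetics and outcome labels.

* `gram_negative`: 4 000 LPS-bearing, replicating antigen tokens at step 0.
  The presentation cascade ignites, IFN-γ dominates the cytokine field, and
  macrophages commit M1 via LPS/IFN-γ exposure while the infection is
  cleared.
* `vaccine_il4`: 10 000 inert LPS-free tokens at step 0 (a large bolus, so
  that the presentation wave overlaps the cytokine schedule), plus 3 000
  IL-4 tokens daily from day 3 for a week. IL-4 blankets the lattice while
  macrophages are being activated, and the IL-4-containing stimuli all
  resolve to the Arg1 attractor: M2 exceeds M1.
* `bacterium_il10`: the gram-negative challenge followed by daily IL-10
  from day 3 for a week. IL-10 coverage vetoes presentation and IFN-γ
  release; whether the bacterium escapes to its carrying capacity before
  the IL-10 pulse decays is a stochastic race, so the ensemble splits into
  *controlled* and *dampened* replicates. The outcome is read at the
  25-day acute window (200 steps): because cells are immortal here, no
  dampened state is absorbing — given unbounded time the intact machinery
  always clears a capacity-bounded infection — so "not controlled" is, as
  in the underlying experiments, a statement about the acute window.

A replicate is *dampened* iff its final antigen count is at least the
count at injection (`classify_outcome()`, threshold configurable).

### Calibrating the dampened fraction

The IL-10 dose behind a given dampening probability is a free parameter.
`calibrate_dampening()` implements the documented procedure: pilot
ensembles (default 40 replicates) at each dose of a ≤10-level grid spanning
the escape transition, pooled into a binomial logistic dose–response fit;
the selected dose is the inverse prediction at the target fraction. The
acceptance script (`scripts/acceptance.R`) runs this calibration from
scratch at the given seed and then measures the dampened fraction on 100
fresh replicates at the calibrated dose.

```{r, eval = FALSE}
cal <- calibrate_dampening(n_pilot = 40, base_seed = 1)
ens <- run_scenario(scenario("bacterium_il10", il10_dose = cal$dose),
                    n_replicates = 100, base_seed = 500001)
dampened_fraction(ens)
```

## Numerical and engineering choices

* States pack into one integer (networks are capped at 30 nodes; exhaustive
  machinery at 22), so enumeration over all 2¹⁸ states is exact and fast.
* Antigen consumption prefers LPS-bearing tokens (a fixed, documented
  tie-break); within-site matching follows the stored agent order after the
  seeded site shuffle.
* Injected tokens are placed uniformly at random; step-0 injections are
  placed before the initial census so the challenge dose is the first
  row's reference value for outcome classification.
* The per-step audit log (rule firings, spawns, commitments, injections,
  decay, replication, tonic activations) reconciles the census deltas
  exactly (`audit_reconcile()`); any discrepancy is a bug, and the
  acceptance suite asserts there are none over a full challenge run.
* Mean/sd ensemble kinetics are accumulated in streaming form; per-series
  standard deviations use the *n − 1* denominator.

## Known limitations

* Helper polarization (H1 vs H2 dominance) is not modelled: the printed
  helper rules are class-symmetric, so only macrophage polarization is
  asserted in the experiments.
* The dampened/controlled dichotomy depends on the acute-window horizon
  (see above); the dampened state is long-lived but not absorbing.
* Commitment depends on token *presence*, so cytokine doses act through
  spatial coverage; absolute dose numbers are meaningful only relative to
  the lattice volume.
* The network file format fixes the four stimulus names (IFNg, IL10, IL4,
  LPS) for lattice coupling; purely GRN-level analyses accept any signed
  network up to 22 nodes.
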