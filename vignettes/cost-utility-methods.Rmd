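---
title: "Model and methods: proton beam therapy versus 3D-CRT for locally advanced esophageal cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtcea)
```

## The decision problem

Patients with locally advanced esophageal cancer (LAEC) who cannot or will
not undergo surgery receive definitive chemoradiotherapy. Proton beam therapy
(PBT) deposits its dose more precisely than three-dimensional conformal
radiotherapy (3D-CRT), so the heart and lungs receive less radiation and late
toxicities — radiation pneumonitis (RP), pleural effusion (PE), pericardial
effusion (PCE) — are rarer and milder. PBT's radiotherapy fee, however, is
2,375,000 yen under Japan's rare-cancer fee schedule (1,600,000 yen under the
non-rare schedule) against 727,600 yen for 3D-CRT. The package quantifies
that trade-off as an incremental cost-effectiveness ratio (ICER, yen per
quality-adjusted life year) under the deliberately conservative premise that
overall and progression-free survival do not differ between the arms: every
benefit of PBT comes from avoided toxicity, none from longer life.

## Model structure

A decision tree assigns the cohort to one of the two arms; each arm then runs
the same Markov state-transition structure in 3-month cycles for 60 months
(20 cycles). The 17 states are:

* `no_late_ae` — alive, free of late adverse events (the start state);
* graded toxicity states `rp_g1`–`rp_g3`, `pe_g1`–`pe_g3`, `pce_g2`,
  `pce_g3` (CTCAE grading; PCE has no grade 1);
* overlap states `rp_g1_pe_g1`, `rp_g1_pce_g2`, `pce_g3_pe_g2` for the
  combinations seen clinically;
* the PCE care pathway: `drainage` and `pericardiotomy` (one-cycle tunnel
  states) and `resolved_pce`;
* `bsc` — best supportive care, the terminal-care state; and `death`.

Onset probabilities move patients out of `no_late_ae`: RP-family onsets
(including the two RP G1 overlap states) apply during cycles 1–4, i.e. the
first year after chemoradiotherapy, and PE/PCE onsets during cycles 1–8,
after which late onset is taken as zero. Recovery transitions run RP G3 →
G2 → G1 at 0.25 per cycle, PE G3 → PE G2 (the treatment episode resolves
within one cycle), and PCE G3 (with or without PE G2 overlap) → drainage at
0.1 per cycle, drainage → PCE G2 with 0.617 (else pericardiotomy, then
resolved PCE). A shared hazard of 0.0542 per cycle moves every alive state to
BSC — this single number carries all mortality, so survival is identical
across arms by construction — and BSC leads to death after exactly one cycle.

Two structural conventions deserve a note:

* **Residual targets.** Each row's leftover probability goes to the state's
  *residual target* — the state itself for ordinary states (the "stay"
  probability), the forced exit for tunnel states. This keeps every row sum
  at exactly 1 even where a nominal "probability 1" transition (PE G3 → PE
  G2, pericardiotomy → resolved PCE) coexists with the BSC hazard: the
  improvement receives the complement `1 − 0.0542`.
* **Tunnel utilities.** No utility is published for the drainage and
  pericardiotomy episodes; both default to the PCE G3 utility (0.63), on the
  view that the patient remains in a decompensated cardiac state while the
  intervention is under way. `build_laec_model(drainage_utility = ...)`
  exposes the choice, and the convention sweep (below) quantifies it.

## Valuation

Utilities (0.91 event-free down to 0.32 in BSC) weight time in state;
each cycle contributes `utility × 0.25` QALY. Costs are social-insurance
fees: an upfront cost at time zero (radiotherapy fee plus 1,325,370 yen of
admission and chemotherapy), routine follow-up per cycle (45,615 yen in the
first year, 28,480 yen later) in every alive non-BSC state, state-specific
per-cycle treatment costs (RP G2 adds 62,160 yen on top of follow-up; PE G2's
published 47,165/30,030 yen *includes* the follow-up fee and replaces it),
and one-off hospitalization costs charged on entry (RP G3 571,120; PE G3
302,700; drainage 448,220; pericardiotomy 595,641; BSC 632,100 yen). Costs
and QALYs are discounted at 3% per year.

### Accrual and discounting conventions

Cohort software differs in how per-cycle rewards are attached, and the
original implementation (TreeAge) does not pin these choices down in print.
The package exposes them as settings and fixes defaults as follows:

* `reward_timing = "start"` (default): rewards for cycle `t` are weighted by
  the state occupied *during* the cycle, i.e. the occupancy after `t − 1`
  transitions — the stage-reward convention of TreeAge-style Markov models.
  `"end"` weights by post-transition occupancy; `"half"` averages the two
  (the half-cycle correction). End-weighting depresses total QALYs by about
  7% relative to the published values because it denies the whole cohort its
  first healthy cycle, which is why start-weighting is the default.
* `discount_timing = "end"` (default): cycle `t` is discounted by
  `1.03^(−t/4)`; `"start"` uses exponent `t − 1`.
* Entry costs are discounted with the cycle in which the entry occurs; the
  upfront cost at time zero is undiscounted.
* The model stops at the horizon with no terminal valuation: cohort mass
  still alive at cycle 20 simply stops accruing.

`convention_sweep()` recomputes the base case over the full grid of reward
timing × discount timing × drainage utility {0.63, 0.57, 0.87} × RP-cost
stacking (whether RP G2's 62,160 yen adds to or replaces follow-up):

```{r sweep}
sw <- convention_sweep("rare")
sw[which.min(abs(sw$icer - 14025268)),
   c("reward_timing", "discount_timing", "drainage_utility", "icer")]
range(sw$icer)
```

Under the default conventions the deterministic results sit within about 1%
(QALYs) to 2% (costs) of the published table, while the incremental
effectiveness is about 2% high and the ICERs consequently 3.5–5% low; no
convention combination closes every gap simultaneously, which bounds how
precisely the published build can be identified from its printed outputs.

```{r base}
run_base_case("rare")
```

## One-way sensitivity analysis

`run_owsa()` perturbs each published scalar to ±20% of its base value and
ranks parameters by the width of the resulting ICER interval. Design points:

* A "parameter" is one scalar of the published table. Probability rows carry
  one cell per arm; cells that differ (the onset probabilities) perturb
  independently per arm, cells that are equal by assumption (the BSC hazard,
  the recovery probabilities, all utilities and costs) perturb jointly in
  both arms.
* Utilities and probabilities are clamped at 1 (0.87 × 1.2 exceeds 1);
  clamping is flagged in the output, never silent.
* The radiotherapy fees are fee-schedule decision variables, not uncertain
  parameters: the PBT fee defines the two base cases and the 3D-CRT fee is
  likewise excluded from perturbation. Consistent with that reading, the most
  sensitive *cost* parameter is the pericardial drainage fee.
* A single perturbed utility may legitimately break the grade ordering
  (lowering RP G1 below RP G2 is the whole point of a one-way deviation), so
  one-way models are built without the family-ordering validity claim.

The event-free utility dominates the tornado by a wide margin — the PBT
advantage is concentrated in time spent event-free, so the value of that
time drives the ratio. Nine of the top ten entries are utilities; the
remaining probability entry in our build is the BSC hazard, with the 3D-CRT
PCE Grade 3 onset two ranks below it — an ordering sensitive to the accrual
conventions above, as the three ICER ranges involved differ by well under
half a million yen.

## Probabilistic sensitivity analysis

`run_psa()` samples every perturbable scalar from a triangular distribution
with mode at the base value and limits at ±20%, evaluates *both arms on the
same sampled parameter set*, and records incremental cost and effectiveness
per draw; `ceac()` turns the draws into a cost-effectiveness acceptability
curve via the net-monetary-benefit rule (fraction of draws with
`wtp × ΔE − ΔC > 0`, which equals the "ICER below threshold" rule whenever
every draw gains QALYs).

Correlation across arms is the one genuinely open design choice, and it has
a first-order effect on the acceptability probabilities:

* utilities and unit costs are physical properties of health states and
  treatments, identical in both arms, so they use **one draw applied to both
  arms**;
* every transition-probability cell is drawn **independently per arm** — the
  parameter table lists a separate cell per arm in every probability row,
  including the BSC hazard, and per-cell distributions are how such a table
  transcribes into per-subtree software variables. The independent hazard
  draws dominate the spread of incremental effectiveness (survival noise
  between arms), tripling its standard deviation relative to fully shared
  draws; with `shared_probabilities = TRUE` the analysis collapses to the
  fully-correlated reading, under which PBT is almost never cost-effective
  at the higher fee (the acceptability probability falls from ~26% to under
  1%), far below the published behaviour.
* cells at the structural boundaries 0 and 1 (toxicities PBT does not cause;
  the certain BSC → death step) are certainties, not sampled — a clamped
  triangular around 1 would otherwise bias the BSC survival downward.
* the published utility-ordering adjustment is enforced per adverse-event
  family (RP G1 ≥ G2 ≥ G3; PE G1 ≥ G2 ≥ G3; PCE G2 ≥ G3 ≥ G3+PE G2) by
  redrawing the family up to 100 times, then sorting the drawn values as a
  deterministic fallback; draws pushing an outgoing row sum above 1 are
  redrawn the same way. Both fallbacks are flagged per draw.
* one master seed spawns a sub-seed per draw, so enlarging `n_draws` never
  changes earlier draws, and the same master seed yields the same draws for
  both fee levels (their incremental costs then differ by exactly the
  775,000 yen fee difference, which is why the non-rare acceptability curve
  dominates the rare one pointwise).

```{r psa}
ps <- run_psa("non_rare", n_draws = 200, seed = 1)
ps
```

## Validation apparatus

* **Microsimulation oracle.** `simulate_patients()` re-implements the model
  at the individual level — per-patient trajectory sampling from the same
  transition matrices, with independently coded accrual — and returns Monte
  Carlo standard errors. The cohort engine and the oracle agree within three
  standard errors on the packaged model (tested at n = 200,000) and on
  batteries of random synthetic models.
* **Synthetic models.** `random_model()` emits random valid models with the
  same statistical anatomy (graded families with monotone utilities,
  windowed onsets, a shared terminal-care hazard, two arms differing in
  onset probabilities and upfront cost), so every pipeline stage is tested
  on structure it has never seen. With `n_ae_states = 0` the model reduces
  to a three-state chain whose discounted QALY total has a geometric closed
  form; the engine matches it to 1e-10 across 100 random parameterizations,
  under all three accrual conventions. What the generator does *not*
  emulate: real epidemiology (its rates are draws, not clinical estimates),
  competing mortality differences between arms, or parameter correlation —
  so passing synthetic tests demonstrates mechanical correctness of the
  engine, not clinical validity of any particular parameterization.
* **Round-trip I/O.** Models serialize to a JSON schema
  (`write_model()`/`read_model()`) at 17 significant digits, making the
  round trip exactly identity; malformed configurations are rejected with
  the offending key named.

## Problem sizes and numerical choices

The test suite runs the packaged model (17 states, 20 cycles), 1000-draw
sensitivity analyses over 20 master seeds, a 200,000-patient microsimulation
of the packaged model plus 50 random models at 2,000 patients each, and
100-seed closed-form sweeps; the whole suite completes in minutes on one
core. Row-stochasticity is enforced to 1e-12 at matrix construction,
occupancy conservation verified to 1e-10 per cycle, and an outgoing row sum
above 1 is a hard error naming the state and cycle. Ties in the tornado
ranking break lexicographically by parameter id so output order is
deterministic.

## Known limitations

* The published implementation's accrual conventions are not fully
  identifiable from its printed results: our defaults reproduce absolute
  QALYs and costs to 1–2% but leave the incremental effectiveness ~2% high
  and the ICERs 3.5–5% low, and the PSA acceptability probability at the
  higher fee runs ~6 percentage points above the published 20.1%. Both gaps
  are documented rather than calibrated away.
* Recurrence, metastasis and second-line therapy are outside the model (the
  arms are assumed identical in progression), as are capital and facility
  costs of proton therapy and any currency conversion.
* The BSC hazard is a single exponential-style per-cycle probability
  estimated from trial survival; the model inherits its lack of age or
  time dependence beyond the onset windows.
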