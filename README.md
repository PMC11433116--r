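# pbtcea

Cost-utility analysis of proton beam therapy (PBT) versus three-dimensional
conformal radiotherapy (3D-CRT) for locally advanced esophageal cancer
(LAEC), from the perspective of Japan's social insurance payer.

## The problem

Definitive chemoradiotherapy is standard care for LAEC when surgery is not an
option. PBT spares heart and lung tissue and so causes fewer late toxicities
than 3D-CRT — notably radiation pneumonitis (RP), pleural effusion (PE) and
pericardial effusion (PCE) — but its radiotherapy fee is three times higher.
Whether the toxicity advantage is worth the price is a cost-utility question:
the package implements the decision model that answers it and is aimed at
health-economics analysts who want to reproduce, stress or extend that
analysis.

## The model

A decision tree splits the cohort between the two treatment arms; each arm
then follows a Markov cohort model in 3-month cycles over 60 months. Health
states cover the graded late toxicities (RP G1–G3, PE G1–G3, PCE G2–G3),
three overlap states, the pericardial-effusion care pathway (drainage,
pericardiotomy, resolved PCE — the first two are one-cycle tunnel states),
best supportive care (BSC) and death. Onset probabilities act on the
event-free state during the first year (RP) or first two years (PE/PCE); a
shared per-cycle hazard of 0.0542 moves every alive state to BSC, and BSC is
followed by death one cycle later. Survival is identical by design in both
arms; the arms differ only in toxicity incidence and upfront cost.

Each strategy accrues, per cycle `t` with discount factor
`(1.03)^(-t/4)`:

* **QALYs** — state utility × 1/4 year, weighted by the state occupied
  during the cycle;
* **costs** — upfront fee at time zero (radiotherapy + admission and
  chemotherapy), per-cycle follow-up and treatment costs, and one-off
  hospitalization costs charged on state entry.

Results are reported as the incremental cost-effectiveness ratio
`ICER = ΔC / ΔE` (yen per QALY) against Japan's anticancer willingness-to-pay
threshold of 7,500,000 yen/QALY, for the two existing PBT fee levels:
2,375,000 yen ("rare-cancer" schedule) and 1,600,000 yen ("non-rare").
One-way sensitivity analysis perturbs every published scalar by ±20%
(tornado ranking by ICER range); probabilistic sensitivity analysis samples
all scalars from triangular distributions at the same limits, evaluates both
arms per draw, and summarises the 1000 draws as a cost-effectiveness
acceptability curve (fraction of draws with positive net monetary benefit
`wtp × ΔE − ΔC`).

## Worked example

```r
library(pbtcea)
run_base_case("rare")
```

```
Base case (rare fee level)
 strategy cost_yen incremental_cost_yen effectiveness_qaly
      PBT  4502727              1528938             2.5918
    3DCRT  2973789                   NA             2.4788
 incremental_effectiveness_qaly icer_yen_per_qaly
                          0.113          13531574
                             NA                NA
Verdict at 7,500,000 yen/QALY: not cost-effective
```

PBT gains 0.113 QALYs (about 41 quality-adjusted days) over five years for
1.53 million yen extra — 13.5 million yen per QALY at the higher fee, well
above the threshold. At the lower fee the same effectiveness gain costs
775,000 yen less:

```r
run_base_case("non_rare")$result$icer
#> 6672583    # below the 7.5M yen/QALY threshold: cost-effective
```

The tornado analysis shows which inputs the ratio actually hinges on — the
utility of the event-free state towers over everything else:

```r
head(run_owsa("rare"), 3)
#> One-way sensitivity analysis (rare fee level), base ICER 13,531,574 yen/QALY
#>       entry_id base icer_low icer_high icer_range clamped
#>   u_no_late_ae 0.91 38143013  10258379   27884634    TRUE
#>        u_rp_g1 0.87 18854417  11174591    7679825    TRUE
#>  u_rp_g1_pe_g1 0.87 18671787  11223200    7448587    TRUE
```

`run_psa()` adds the probabilistic layer, `simulate_patients()` checks any
model against an independent patient-level simulation, `random_model()`
generates synthetic models for testing, and `read_model()` / `write_model()`
round-trip any model through a JSON configuration file.

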