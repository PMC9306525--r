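# Default configuration: 14-event chain, three harms, two populations.
#
# The chain structure, harms and populations are the full model. The input
# DISTRIBUTIONS below are uniform placeholder bands around plausible
# values, marked as such in every source_note. To reproduce a published
# risk assessment, transcribe its input distributions (one per N1-N14)
# over these placeholders and re-run; the model itself needs no other
# change.
schema_version: 1

inputs:
  - id: N1
    family: uniform
    params: {a: 0.12, b: 0.18}
    description: P(recipient is D-negative)
    source_note: "placeholder band around ~15% D-negative prevalence; transcribe study inputs to reproduce published results"
  - id: N2
    family: uniform
    params: {a: 0.55, b: 0.80}
    description: P(recipient survives the index event)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N3
    family: uniform
    params: {a: 0.002, b: 0.010}
    description: P(pre-existing anti-D in an unselected recipient)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N4
    family: uniform
    params: {a: 0.05, b: 0.40}
    description: P(HTR given pre-existing anti-D and D-positive transfusion)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N5
    family: uniform
    params: {a: 0.02, b: 0.15}
    description: P(major morbidity or death given index HTR)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N6
    family: uniform
    params: {a: 0.10, b: 0.40}
    description: P(D-alloimmunization after index D-positive transfusion)
    source_note: "placeholder band spanning the 10-40% range discussed for trauma recipients; transcribe study inputs to reproduce published results"
  - id: N7
    family: uniform
    params: {a: 0.10, b: 0.30}
    description: P(recipient receives a future transfusion)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N8
    family: uniform
    params: {a: 0.005, b: 0.05}
    description: P(future transfusion is D-positive despite known anti-D)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N9
    family: uniform
    params: {a: 0.05, b: 0.40}
    description: P(HTR at the future transfusion)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N10
    family: uniform
    params: {a: 0.02, b: 0.15}
    description: P(major morbidity or death given future HTR)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N11
    family: uniform
    params: {a: 0.20, b: 0.25}
    description: P(recipient is a female of childbearing potential, <50 years)
    source_note: "placeholder band consistent with 75-80% of trauma patients being male; transcribe study inputs to reproduce published results"
  - id: N12
    family: uniform
    params: {a: 0.20, b: 0.60}
    description: P(future pregnancy after the index event)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N13
    family: uniform
    params: {a: 0.55, b: 0.75}
    description: P(foetus is D-positive)
    source_note: "placeholder; transcribe study inputs to reproduce published results"
  - id: N14
    family: uniform
    params: {a: 0.01, b: 0.10}
    description: P(foetal death or lifelong disability given HDFN-affected pregnancy)
    source_note: "placeholder; transcribe study inputs to reproduce published results"

events:
  - id: X1
    label: Recipient is D-negative
    input: N1
    population_overrides:
      dneg_females_cbp: {family: point, params: {p: 1.0}}
  - id: X2
    label: Recipient survives index event
    input: N2
  - id: X3
    label: Recipient has pre-existing anti-D
    input: N3
  - id: X4
    label: HTR occurs at index D-positive transfusion
    input: N4
  - id: X5
    label: Major morbidity or death given index HTR
    input: N5
  - id: X6
    label: D-alloimmunization after index transfusion
    input: N6
  - id: X7
    label: Recipient receives a future transfusion
    input: N7
  - id: X8
    label: Future transfusion is D-positive
    input: N8
  - id: X9
    label: HTR occurs at future transfusion
    input: N9
  - id: X10
    label: Major morbidity or death given future HTR
    input: N10
  - id: X11
    label: Recipient is a female of childbearing potential
    input: N11
    population_overrides:
      dneg_females_cbp: {family: point, params: {p: 1.0}}
  - id: X12
    label: Future pregnancy occurs
    input: N12
  - id: X13
    label: Foetus is D-positive
    input: N13
  - id: X14
    label: Foetal death or lifelong disability due to HDFN
    input: N14

harms:
  - id: htr_index
    label: Major morbidity or mortality due to HTR from index D-positive transfusion
    chain: [X1, X2, X3, X4, X5]
  - id: htr_future
    label: Major morbidity or mortality due to future HTR
    chain: [X1, X2, X6, X7, X8, X9, X10]
  - id: hdfn
    label: Foetal death or permanent disability due to anti-D HDFN in future pregnancy
    chain: [X1, X2, X6, X11, X12, X13, X14]

populations:
  - id: all_recipients
    label: All prehospital trauma recipients (England)
    incidence_per_million_per_year: 83.0
    population_size: 67000000
    subgroup_fraction: 1.0
  - id: dneg_females_cbp
    label: D-negative females of childbearing potential (<50 years)
    incidence_per_million_per_year: 83.0
    population_size: 67000000
    # chosen so the subgroup sees ~100 prehospital transfusions per year
    subgroup_fraction: 0.01798

mc:
  iterations: 1000
  seed: 1
  ci_level: 0.95

life_years:
  years_lost_per_hdfn_event: 83.0
  bootstrap_samples: 10000
  # placeholder survivor life-years model (years gained per life saved);
  # transcribe the study's survival model to reproduce published results
  survivor_life_years:
    family: uniform
    params: {a: 30.0, b: 50.0}
    source_note: "placeholder; transcribe study survival inputs to reproduce published results"
  survival_benefit_grid: [0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0,
                          1.2, 1.4, 1.6, 1.8, 2.0, 2.5, 3.0, 4.0, 5.0]
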