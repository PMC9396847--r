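parameters:
- name: cAE
  base: 705.0
  low: 10.0
  high: 1800.0
  distribution: normal
  role: cost
  description: Hospitalisation cost of a severe antibiotic adverse event (DRG tariff)
- name: cAntibiotics
  base: 10.2
  low: 5.0
  high: 100.0
  distribution: normal
  role: cost
  description: Cost of a single prophylactic antibiotic course (amoxicillin)
- name: cAntibioticResistance
  base: 13.97
  low: 2.9
  high: 32.16
  distribution: normal
  role: cost
  description: Societal cost of antibiotic resistance per course
- name: cImplantPlacement
  base: 1002.0
  low: 500.0
  high: 1500.0
  distribution: normal
  role: cost
  description: Cost of implant placement
- name: cImplantReplacement
  base: 1102.0
  low: 0.0
  high: 1600.0
  distribution: normal
  role: cost
  description: Cost of implant replacement after failure
- name: effImplant
  base: 0.88
  low: 0.5
  high: 0.9
  distribution: beta
  role: utility
  description: Oral-health utility with a functioning implant (GOHAI)
- name: effNoImplant
  base: 0.71
  low: 0.3
  high: 0.8
  distribution: beta
  role: utility
  description: Oral-health utility after implant loss (GOHAI)
- name: pAE
  base: 2.3e-05
  low: 1.0e-05
  high: 0.05
  distribution: fixed
  role: probability
  description: Probability of a non-fatal antibiotic adverse event per course
- name: pantsurv
  base: 0.9878
  low: 0.6
  high: 0.9878
  distribution: fixed
  role: probability
  description: 1-year implant survival probability with antibiotic prophylaxis
- name: pnoantsurv
  base: 0.9567
  low: 0.6
  high: 0.9567
  distribution: fixed
  role: probability
  description: 1-year implant survival probability without antibiotics
- name: preplac
  base: 0.85
  low: 0.3
  high: 0.9
  distribution: fixed
  role: probability
  description: Probability a failed implant is replaced within the year
- name: psurvsecond
  base: 0.89
  low: 0.6
  high: 0.89
  distribution: fixed
  role: probability
  description: Survival probability of the replacement implant
tree:
  label: prophylaxis
  strategies:
  - name: Antibiotics
    node:
      kind: chance
      label: implant survival
      branches:
      - prob: pantsurv
        node:
          kind: terminal
          cost:
          - cImplantPlacement
          - cAntibiotics
          - ref: 10.0
            weight: pAE
          effect: effImplant
      - prob: 1 - pantsurv
        node:
          kind: chance
          label: replacement
          branches:
          - prob: preplac
            node:
              kind: chance
              label: replacement outcome
              branches:
              - prob: psurvsecond
                node:
                  kind: terminal
                  cost:
                  - cImplantPlacement
                  - cImplantReplacement
                  - cAntibiotics
                  - ref: 10.0
                    weight: pAE
                  effect: effImplant
              - prob: 1 - psurvsecond
                node:
                  kind: terminal
                  cost:
                  - cImplantPlacement
                  - cImplantReplacement
                  - cAntibiotics
                  - ref: 10.0
                    weight: pAE
                  effect: effNoImplant
          - prob: 1 - preplac
            node:
              kind: terminal
              cost:
              - cImplantPlacement
              - cAntibiotics
              - ref: 10.0
                weight: pAE
              effect: effNoImplant
  - name: No Antibiotics
    node:
      kind: chance
      label: implant survival
      branches:
      - prob: pnoantsurv
        node:
          kind: terminal
          cost:
          - cImplantPlacement
          effect: effImplant
      - prob: 1 - pnoantsurv
        node:
          kind: chance
          label: replacement
          branches:
          - prob: preplac
            node:
              kind: chance
              label: replacement outcome
              branches:
              - prob: psurvsecond
                node:
                  kind: terminal
                  cost:
                  - cImplantPlacement
                  - cImplantReplacement
                  effect: effImplant
              - prob: 1 - psurvsecond
                node:
                  kind: terminal
                  cost:
                  - cImplantPlacement
                  - cImplantReplacement
                  effect: effNoImplant
          - prob: 1 - preplac
            node:
              kind: terminal
              cost:
              - cImplantPlacement
              effect: effNoImplant
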