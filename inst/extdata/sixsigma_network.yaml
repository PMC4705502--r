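# Decision network of the bundled healthcare six-sigma case study:
# 3 strategies, 15 sub-criteria in four criteria clusters, 6 project
# alternatives. Element ordering is authoritative.
goal: Select the most suitable six-sigma project
clusters:
  - label: Strategies
    kind: strategy
    elements: [OE, RG, HP]
  - label: Benefit
    kind: criterion
    elements: [S1, S2, S3, S4, S5]
  - label: Opportunity
    kind: criterion
    elements: [S6, S7, S8, S9]
  - label: Cost
    kind: criterion
    elements: [S10, S11, S12]
  - label: Risk
    kind: criterion
    elements: [S13, S14, S15]
alternatives: [C1, C2, C3, C4, C5, C6]
blocks:
  - {from: Strategies, to: Strategies}
  - {from: Benefit, to: Benefit}
  - {from: Opportunity, to: Opportunity}
  - {from: Cost, to: Cost}
  - {from: Risk, to: Risk}
  - {from: Benefit, to: alternatives}
  - {from: Opportunity, to: alternatives}
  - {from: Cost, to: alternatives}
  - {from: Risk, to: alternatives}
cluster_weights:
  Benefit: 0.25
  Opportunity: 0.25
  Cost: 0.25
  Risk: 0.25
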