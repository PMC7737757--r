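# Synthetic-collection spec: one peptidase per block; keys mirror
# the peptidaseSpec() arguments.
- identifier: S01.151
  nRecords: 60
  duplicateFraction: 0.1
  plantedRestrictions:
  - site: P1
    residues: [R, K]
- identifier: M01.001
  nRecords: 35
  activityKind: aminopeptidase
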