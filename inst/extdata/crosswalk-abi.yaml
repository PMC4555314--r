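# Crosswalk for the acquired-brain-injury evaluation battery.
#
# The Barthel feeding rule is the published worked example (scores 10/5/0 ->
# eating d550 qualifiers 0/2/4). All other rules are illustrative fixtures in
# the same style so the pipeline runs end-to-end; they are NOT clinically
# validated mappings. Higher ICF qualifier = worse functioning, so
# instruments where a higher raw score means better functioning invert here.
version: "1.0"
instruments:
  - instrument: Barthel
    items:
      - item: feeding
        icf_code: d550
        values:
          - {raw: 10, qualifier: 0}
          - {raw: 5, qualifier: 2}
          - {raw: 0, qualifier: 4}
      - item: dressing
        icf_code: d540
        values:
          - {raw: 10, qualifier: 0}
          - {raw: 5, qualifier: 2}
          - {raw: 0, qualifier: 4}
  - instrument: CIQ
    items:
      - item: home_feeding
        icf_code: d550
        values:
          - {raw: 2, qualifier: 0}
          - {raw: 1, qualifier: 2}
          - {raw: 0, qualifier: 4}
      - item: family_relationships
        icf_code: d760
        values:
          - {raw: 2, qualifier: 0}
          - {raw: 1, qualifier: 2}
          - {raw: 0, qualifier: 4}
      - item: recreation_leisure
        icf_code: d920
        values:
          - {raw: 2, qualifier: 0}
          - {raw: 1, qualifier: 2}
          - {raw: 0, qualifier: 4}
  - instrument: PCRS
    items:
      - item: emotional_control
        icf_code: b152
        values:
          - {raw: 5, qualifier: 0}
          - {raw: 4, qualifier: 1}
          - {raw: 3, qualifier: 2}
          - {raw: 2, qualifier: 3}
          - {raw: 1, qualifier: 4}
      - item: organization_planning
        icf_code: b1641
        values:
          - {raw: 5, qualifier: 0}
          - {raw: 4, qualifier: 1}
          - {raw: 3, qualifier: 2}
          - {raw: 2, qualifier: 3}
          - {raw: 1, qualifier: 4}
  - instrument: DRS
    items:
      - item: total_score
        icf_code: d230
        values:
          - {from: 0, to: 3, qualifier: 0}
          - {from: 4, to: 6, qualifier: 1}
          - {from: 7, to: 11, qualifier: 2}
          - {from: 12, to: 21, qualifier: 3}
          - {from: 22, to: 29, qualifier: 4}
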