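# Default exclusion rules for the CAN annotator.
# Each rule suppresses dictionary mentions arising from one of the five
# false-positive categories seen in real pediatric notes. Rules are data:
# copy this file and pass your own via read_exclusion_rules().
rules:
  - rule_id: r1
    kind: non_patient_subject
    scope: sentence
    description: >
      Event concerns a relative of the patient, not the patient: a kin token
      shortly before the mention together with a history marker.
    kin_tokens: [mother, father, grandmother, grandfather, grandparents,
                 aunt, uncle, stepmother, stepfather, mom, dad]
    history_markers: [history, hx, ago, prior, remote]
    window_tokens: 6
  - rule_id: r2
    kind: template_pattern
    scope: sentence
    description: Abbreviation-legend boilerplate ("AV = alleged victim").
    patterns:
      - '\b(av|ao)\s*=\s*alleged'
      - 'abbreviations\s*:'
  - rule_id: r3
    kind: template_pattern
    scope: sentence
    description: First-aid / emergency-instruction templates.
    patterns:
      - '^\s*first aid\s*:'
      - '\bcall 911\b'
  - rule_id: r4
    kind: section_header
    scope: sentence
    description: >
      Mention inside a header fragment ending in ":" with no verb
      ("sexual abuse health since last visit: ...").
  - rule_id: r5
    kind: template_pattern
    scope: sentence
    case_sensitive: true
    mention_after_match: true
    description: >
      Parenthetical abbreviation expansion ("STD (sexually transmitted
      disease"); suppress mentions inside the expansion.
    patterns:
      - '\b[A-Z]{2,6}\s*\('
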