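# Keyword-cleaning rules applied to the whole text before sectioning and
# matching. Each rule suppresses a known false-positive collision for one
# item. Patterns are matched case-insensitively.
- rule_id: random_primer
  pattern: 'random\s+primers?'
  target_item: randomization
  rationale: reverse-transcription reagent, not study-design randomization
- rule_id: random_hexamer
  pattern: 'random\s+hexamers?'
  target_item: randomization
  rationale: cDNA synthesis reagent
- rule_id: husbandry_cage_randomization
  pattern: 'randomly\s+assigned\s+to\s+cages\s+for\s+husbandry'
  target_item: randomization
  rationale: housing logistics, not allocation to experimental groups
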