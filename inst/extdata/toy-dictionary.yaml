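version: toy-1.0
entries:
- cui: WANDER
  description: Wandering or getting lost
  role: feature
  max_gap: 2
  patterns:
  - wander
  - getting lost
- cui: DECLINE
  description: Declining memory or cognitive abilities
  role: feature
  max_gap: 2
  patterns:
  - loss cognitive ability
  - memory loss
- cui: NEGATE
  description: Medication-reminder boilerplate language
  role: feature
  max_gap: 2
  patterns:
  - remember to take
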