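# Concept dictionary file schema

A dictionary is a YAML document with two top-level keys:

```yaml
version: <free-text version label>
entries:
- cui: WANDER                # short uppercase identifier, unique in the file
  description: <free text>
  role: feature              # feature | patient_exclusion |
                             # mention_exclusion | negation_guard
  max_gap: 2                 # max intervening words between consecutive
                             # pattern words (ignored for single-word patterns)
  patterns:                  # zero or more term/phrase patterns
  - wander                   # single word
  - getting lost             # phrase: words separated by single spaces
```

Rules:

* `cui` must be unique within the file; duplicates are a load error.
* `role` must be one of the four strings above; anything else is a load error.
* A pattern is a space-separated sequence of words; words contain no
  whitespace. An empty `patterns` list is allowed (the entry loads but is
  flagged by `validate_dictionary()`).
* Matching is case-insensitive. At load time each pattern word is expanded
  into its regular inflectional family (`call` -> `called`, `calling`,
  `calls`), so base forms are sufficient; irregular forms (`forgot`) must be
  listed as separate patterns if wanted.
* `save_dictionary()` writes exactly these fields, so load -> save -> load
  round-trips to an identical dictionary.

Bundled fixtures:

* `mci-dictionary.yaml` — the full 42-CUI dictionary, reconstructed
  from published concept descriptions (version `concept-reconstruction-1.0`);
  an approximate stand-in, not a verbatim clinical term list.
* `toy-dictionary.yaml` — a 3-CUI toy for tests and examples.
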