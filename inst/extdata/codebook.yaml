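# Example codebook override for PERSNET-style exports.
# Entries merge over persnet_codebook() defaults; see read_codebook().
kin_codes:
  - spouse
  - partner
  - parent
  - child
  - sibling
  - in_law
  - other_family
diversity_race_k: codebook
max_alters: 25
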