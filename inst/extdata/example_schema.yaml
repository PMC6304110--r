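# Example column-mapping override: a trait table whose headers use
# abbreviated field names, and an isotope table with delta-prefixed
# columns.
trait:
  specimen_id: id
  body_mass: mass_g
  traits:
    GSKL: skull_length
isotope:
  d13C: delta13C
  d15N: delta15N
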