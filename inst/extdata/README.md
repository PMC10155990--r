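# extdata

- `synthetic_tuning_table.tsv` — a SYNTHETIC per-neuron tuning table in the
  layout of the deposited tuning-property tables (neuron id, mouse id,
  group, per-eye preferred orientation/SF, per-eye dF/F at the preferred
  stimulus, ODI, OD category). Generated from this package's own
  ground-truth simulator; used only to exercise the ingest mode. It is not
  experimental data.
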