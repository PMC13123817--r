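# Demo pipeline configuration: a 30-year single-region scenario with a
# rising sex ratio at birth and declining fertility.
scenario:
  region_id: DEMO
  start_year: 1950
  end_year: 1979
  srb: [105, 105, 105, 105, 105, 106, 106, 106, 107, 107,
        108, 108, 109, 109, 110, 110, 111, 111, 112, 112,
        113, 113, 114, 114, 115, 115, 115, 115, 115, 115]
  tfr: [4.0, 3.9, 3.8, 3.7, 3.6, 3.5, 3.4, 3.3, 3.2, 3.1,
        3.0, 2.9, 2.8, 2.7, 2.6, 2.5, 2.4, 2.3, 2.2, 2.1,
        2.0, 1.95, 1.9, 1.85, 1.8, 1.75, 1.7, 1.65, 1.6, 1.55]
out_dir: demo-run
seed: 1
log_level: info
decompose_max_age: 80
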