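# Example end-to-end pipeline configuration for run_pipeline().
# Simulates an ISW2-remodeled origin template library and calls
# consensus dyads; swap the `simulate` block for `input_path` /
# `input_format` to analyze aligned fragments instead.
template_id: ARS1_tpl
length_bp: 3800
acs_offset: 1700
orientation: forward
size_lo: 125
size_hi: 175
bandwidth_bp: 20
truncation_sd: 3
threshold: 2
min_separation: 120
pairing_window: 100
seed: 1
simulate:
  preset: ISW2
  n: 50000
  fuzz_sd: 10
  background_frac: 0.1
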