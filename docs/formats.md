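# gripscan on-disk formats

All artifacts are plain UTF-8 CSV with `.` as decimal separator. The first
line of every file is a schema header `# gripscan <what> v<major>`; readers
refuse files whose major version does not match. Time is integer
milliseconds (1 sample = 1 ms at the fixed 1000 Hz rate); forces are mN
serialised at 6-decimal precision, so write → read → write reproduces a
file byte for byte.

## recording (`# gripscan recording v1`)

One continuous two-channel recording per participant.

| column         | type    | meaning                                   |
|----------------|---------|-------------------------------------------|
| time_ms        | int     | strictly increasing sample time            |
| force_left_mN  | numeric | left-hand vertical (Fz) force              |
| force_right_mN | numeric | right-hand vertical (Fz) force             |
| trigger        | int     | trial id at its onset sample, else 0; ids strictly increasing |

## trials (`# gripscan trials v1`)

Per-trial metadata: `trial_id` (unique), `participant_id`,
`experiment_kind` (stars/arrows/words), `side_code` (−1/0/+1, empty for
symbol arrays), `is_go`, `stimulus_class` (star/arrow/word/symbol_array),
`response_correct`, `onset_sample` (1-based index into the recording).

## epochs (`# gripscan epochs v1`) + sidecar `<file>.mask`

Long format, 1200 samples per trial and hand: `participant`, `trial`,
`hand` (left/right), `t_ms` (−200…999), `force_mN`. The sidecar
(`# gripscan epochmask v1`) carries one row per trial — `trial`, `accept`,
`reason` (threshold/error_response/go_trial) — and a provenance comment
line recording the filter, baseline window and rejection state.

## ground truth (`# gripscan truth v1`)

`participant`, `hand`, `intercept_mN` (holding force), `side_slope_mN`
(injected mN per side-code unit, sign included).

## configuration (YAML)

Top-level keys `experiment`, `n_participants`, `seed`, `spec`, `effect`,
`noise`, `analysis`; nested keys are the arguments of
`experiment_spec()`, `effect_params()`, `noise_params()` plus
`analysis: {n_perm, alpha, close_alpha, tfce_e, tfce_h}`. Unknown keys are
rejected; omitted keys take the documented defaults; out-of-range values
(e.g. a holding force outside 1500–3000 mN) are validation errors.
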