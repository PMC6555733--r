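# gaitwatts on-disk dataset schema

One directory per subject x condition:

    root/
      <subject_id>/
        <condition_id>/
          signals.csv     # RFC-4180 CSV, header row required
          breaths.csv     # RFC-4180 CSV, header row required
          meta.json

## signals.csv

One column per synchronized signal channel, one row per sample.  All
channels share the sampling rate declared in `meta.json`.  Column names
follow `"<kind>_<side>_<axis|muscle>"`:

* `kind`: `grf` (ground reaction force, N) or `emg` (electromyography,
  arbitrary units)
* `side`: `r` or `l`
* final token: force axis `x` (mediolateral), `y` (anteroposterior),
  `z` (vertical), or a muscle label (e.g. `soleus`)

At least one `grf_r_z` column must exist; it anchors heel-strike detection.
Numbers are written at full double precision (`%.17g`).

## breaths.csv

Columns `time` (s, strictly increasing), `vo2` (L/min), `vco2` (L/min);
one row per breath.

## meta.json

```json
{
  "subject":   {"subject_id": "S01", "mass": 77.5, "leg_length": null},
  "condition": {"condition_id": "assist00", "incline_grade": 0,
                "load_fraction": 0, "assistance_work": 0,
                "is_baseline_normal_walk": true},
  "sampling_rate": 2000
}
```

`mass` is in kg, `incline_grade` and `load_fraction` are fractions,
`assistance_work` is J per gait cycle.  Exactly one condition per subject
has `is_baseline_normal_walk = true`; its EMG envelope maxima normalize
that subject's EMG in every condition.
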