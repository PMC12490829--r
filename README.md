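# axztools

Read, validate, quality-control and export AFM-IR instrument files from R.

## The problem

AFM-IR (Atomic Force Microscopy-based Infrared spectroscopy) measures the
local thermal expansion of a sample absorbing pulsed infrared light through
an AFM probe, producing nanoscale chemical maps and per-location spectra.
The instruments write their sessions into compressed XML containers —
optical images, multi-channel scan maps (Height, Deflection, IR Amplitude,
IR Phase, PLL Frequency; trace and retrace), and rendered spectra, each with
extensive acquisition metadata — that mainstream open-source image-analysis
software cannot open. That makes the raw data hard to review and audit, and
acquisition problems (poor surface tracking, a mis-configured phase-locked
loop, data silently flattened before saving) easy to miss.

`axztools` is for AFM-IR practitioners and reviewers who need to open those
files, see the *unprocessed* data, and check it against simple quality
heuristics — from R scripts or a shell pipeline, without the instrument's
own software.

## What it does

* **Container + XML round trip.** `read_axz()` detects gzip, zip or plain
  XML from magic bytes, decompresses, parses the document and decodes every
  base64 array (little-endian float32, row-major) bit-exactly; every XML
  attribute lands verbatim in the owning object's metadata map.
  `write_axz()` is the exact inverse: `read_axz(write_axz(d)) == d`.
  Files above the 200 MB ingest limit are rejected before decompression.
* **Minimal display processing.** `level_height()` subtracts a per-scan-line
  first-degree least-squares fit (the standard removal of scanner tilt);
  `subtract_setpoint()` recenters deflection maps on their feedback
  setpoint. Nothing else is ever altered: `extract_profile()` and
  `to_labeled_map()` return raw values bit-exactly.
* **Heuristic QC.** `run_qc()` applies four rules per eligible map:
  * `APPARENT_PROCESSING` (warn) — height/deflection/PLL images whose scan
    lines all average to nearly zero were flattened before saving;
  * `AFM_TRACKING` (fail) — deflection more than 0.01 V from the setpoint
    on more than 1% of pixels;
  * `PLL_PHASE` (fail) — IR phase more than 20° from the setpoint (wrapped
    to (−180°, 180°]);
  * `PLL_SATURATION` (fail) — pixels pinned at the PLL frequency limits.
  All thresholds are configurable via `qc_config()`.
* **Exports.** `spectra_to_csv()` (lossless at 9 significant digits),
  `metadata_table()`, `group_cotemporal_maps()`, and a per-group PDF/HTML
  QC report (`render_qc_report()`) with channel-specific colormaps,
  colorbars and raw trace/retrace line profiles.
* **Synthetic data.** `make_document()` deterministically generates valid
  documents — tilted, featured topography; setpoint-centered noise;
  Lorentzian amide-I/II band spectra — with injectable artifacts
  (`flattened_height`, `deflection_error`, `phase_error`,
  `pll_saturation`), each of which triggers exactly its one QC flag.
* **CLI.** `inst/exec/axztools` exposes `info`, `qc [--json]`,
  `export-spectra`, `export-report`, `metadata` and `synth` with stable
  exit codes (0 ok, 1 usage, 2 parse error, 3 fail-severity QC flags) for
  scripted pipelines.

## Worked example

```r
library(axztools)

# a synthetic session with a deliberate 0.05 V deflection offset in group 1
doc <- make_document(synthetic_spec(
  seed = 42,
  artifacts = list(artifact_injection("deflection_error", 1, 0.05))))
doc
#> AFM-IR document
#>   optical images: 1
#>   channel maps:   10
#>     (Deflection: 2, Height: 2, IRAmplitude: 2, IRPhase: 2, PLLFrequency: 2)
#>   spectra:        3

report <- run_qc(doc)
report
#> QC report: 1 flag(s) over 12 rule evaluations
#>   [fail] AFM_TRACKING (group01/Deflection): map 'group01/Deflection': 100.0%
#>   of pixels have deflection more than 0.01 V from the setpoint
#>   (max deviation 0.064427 V)
```

Ten maps (2 groups × 5 channels) were generated; 12 rule evaluations ran
(per group: three apparent-processing checks plus tracking, phase and
saturation); only the perturbed deflection map is flagged — its pixels sit
0.05 V ± noise from the 0.5 V setpoint, beyond the 0.01 V tracking
tolerance, and the maximum observed deviation was 0.064 V. Round-trip the
document and export its spectra:

```r
write_axz(doc, "session.axz")          # gzip container
identical(read_axz("session.axz"), doc)
#> [1] TRUE
cat(substr(spectra_to_csv(doc), 1, 120))
#> wavenumber_cm-1,spectrum01/IRAmplitude,spectrum01/IRPhase,spectrum01/PLLFrequency,...
render_qc_report(doc, report, "session-qc.pdf")
```

The same from a shell:

```sh
inst/exec/axztools qc session.axz --json   # exit code 3: fail-severity flag
```

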