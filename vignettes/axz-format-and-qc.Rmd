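---
title: "The AXZ dialect, minimal processing, and heuristic QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The AXZ dialect, minimal processing, and heuristic QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axztools)
```

# Scope and premise

AFM-IR instruments couple an AFM probe to a pulsed infrared laser: the
cantilever reads the sample's photothermal expansion, so the recorded
signal is proportional to local IR absorption at nanometre resolution.
One measurement session yields optical reference images, sets of
simultaneously recorded channel maps (topographic Height in nm, cantilever
Deflection in V, IR Amplitude in V, IR Phase in degrees, PLL Frequency in
kHz — forward *trace* and backward *retrace* passes of each scan line),
and per-location spectra over a wavenumber axis.

The premise of this package is fidelity to the **unprocessed** data: the
reader drops nothing, converts no units, and resamples nothing; display
processing is limited to the two corrections every practitioner applies by
eye anyway; and quality control reads the raw numbers against the tracking
tolerances used at acquisition time.

# The AXZ dialect

Instrument files are XML documents inside a compression container. The
element vocabulary of the real vendor schema is not public, so this package
defines a documented, self-consistent dialect rather than a byte-level
clone: a root `<Document>` with children `<Images>`, `<HeightMaps>` and
`<RenderedSpectra>`; each map element carries its label, channel, units,
geometry, timestamp and setpoints as attributes, one `<SampleBase64>` child
per scan direction, and a `<Metadata>` block of key–value entries; spectra
carry one `<SampleBase64>` per data channel plus axis attributes.

Concrete choices, fixed so that round trips can be bit-exact:

* **Containers.** gzip (RFC 1952), zip (PKZIP; the member ending `.axd`,
  or the sole member, is the document), or plain XML. Detection is purely
  by magic bytes, so the file extension never matters. Whether real
  containers are gzip or zip is not something this package assumes — both
  are read, and the parsed document is independent of the container.
* **Arrays.** Base64 (RFC 4648, no line wrapping) of little-endian IEEE-754
  float32, filled row-major; row 1 is the first-acquired scan line and
  columns advance along the fast scan axis. NaN/Inf are legal and preserved
  bit-exactly; QC excludes NaN pixels from every statistic.
* **Metadata.** All attributes of an element are carried verbatim — as
  strings, in document order — in the owning object's metadata map,
  followed by the `<Metadata>` entries. Unknown elements under known
  parents are preserved into that map under their element name (a strict
  mode turns them into parse errors instead), so fields this dialect never
  anticipated are not silently lost. When objects are constructed
  programmatically, numeric fields are rendered with 17 significant digits,
  which reparses to the identical double.
* **Ingest limit.** `read_axz()` refuses files above 200 MB (configurable)
  *before* decompressing, as a guard against pathological inputs.
* **Physical coordinates.** Pixel centers along an axis of `n` pixels with
  center `c` and extent `s` are `c − s/2 + (j + 0.5)·s/n` for 0-based `j`.
  This raster convention is the common SPM one; it is stated here because
  nothing in the file format pins it down.

# Minimal processing

Two display corrections are implemented, both returning new maps and
tagging their provenance in metadata (`processing = "line_linear_fit"` or
`"setpoint_subtraction"`); the stored arrays in a document are never
overwritten.

**Height leveling.** Raw topography is dominated by scanner tilt. Because
acquisition is line-by-line (and line-to-line offsets from drift are
common), "linear fit" is interpreted as an independent first-degree OLS fit
per scan line, subtracted from that line — not a single global plane. The
global plane variant is available (`method = "plane"`) for surfaces where
line-wise fitting would erase real steps. NaN pixels are excluded from each
fit; a line with fewer than two finite pixels passes through unchanged.
Per-line OLS residuals are orthogonal to a refit, so leveling is idempotent
to machine precision — a property the tests assert directly.

**Deflection setpoint subtraction.** The feedback loop holds deflection at
a setpoint; what carries information is the *error* around it, so display
subtracts the stored setpoint uniformly.

Line profiles and labeled-map conversion deliberately bypass both: a
profile of a leveled rendering and of the raw map will disagree wherever a
slope existed, and that contrast is the point — the viewer shows processed
images but raw numbers.

# Heuristic QC

Four rules, each a pure function of one map and a `qc_config()`:

| rule | channel | trigger | severity |
|---|---|---|---|
| `APPARENT_PROCESSING` | Height, Deflection, PLLFrequency | every scan line's mean within `flat_tolerance` of zero | warn |
| `AFM_TRACKING` | Deflection | fraction of pixels with \|value − setpoint\| > 0.01 V exceeds trigger | fail |
| `PLL_PHASE` | IRPhase | fraction with wrapped \|value − setpoint\| > 20° exceeds trigger | fail |
| `PLL_SATURATION` | PLLFrequency | fraction of pixels within `saturation_tol`·span of a range limit exceeds `saturation_fraction` | fail |

Design decisions where the ground truth is genuinely open:

* **Per-pixel thresholds vs. map verdict.** The 0.01 V and 20° tolerances
  are per-pixel; how many offending pixels condemn a map is a tool
  decision. The default `exceed_fraction_trigger = 0.01` (1% of finite
  pixels, trace and retrace pooled) suppresses single-pixel noise; setting
  it arbitrarily close to zero recovers strict any-pixel semantics.
* **Phase wrapping.** Phase is circular, so deviations are wrapped into
  (−180°, 180°] before comparison: a +350° offset is a −10° error and does
  not flag.
* **"Values very close to zero".** The flattening signature of line-wise
  leveling is that *every* line mean is ≈ 0, which is what the default
  per-line mode tests (`flat_tolerance = 1e-6` channel units — far below
  any plausible raw offset, far above float32 rounding of leveled data);
  a global-mean variant exists for globally-centered processing. The
  numeric tolerance is this package's choice, not an instrument constant.
* **Severities.** Tracking, phase and saturation failures invalidate
  quantitative comparison, hence `fail` (and CLI exit code 3 so CI
  pipelines can gate on them); apparent processing means the file no longer
  holds raw data but may still be interpretable, hence `warn`.

`run_qc()` visits maps in label order and rules in a fixed order, so
identical inputs give identical reports. A deflection map without a stored
setpoint (likewise phase/PLL maps without theirs) is an error at QC time:
the rule cannot run, and silently skipping it would look like a pass.

`qc_flag_boundary()` exposes the sharpness of the thresholds: with uniform
deviation the offending fraction jumps from 0 to 1 exactly at the per-pixel
threshold, and bisection recovers the boundary to the requested tolerance
(1e-6 V and 1e-4° in the tests). `scripts/acceptance.R` recomputes both
boundaries end-to-end through a generated file.

# The synthetic generator

All testing runs on generated documents; no instrument data ships with the
package. `make_document()` emulates the *structure and statistics* of a
session:

* topography = tilted plane (≈ 28 nm across the field) + two Gaussian
  features (30 and 18 nm) + 0.5 nm Gaussian noise;
* deflection and IR phase = their setpoints (0.5 V, 90°) + Gaussian noise
  with standard deviation fixed at **one third of the QC threshold**
  (0.0033 V, 6.7°), so pristine documents are flag-free with wide margin
  (the offending-pixel probability is ≈ 0.3%, far under the 1% trigger,
  and the binomial fluctuation over thousands of pixels cannot reach it);
* PLL frequency = 200 kHz ± 1 kHz inside a 180–220 kHz range;
* spectra = sums of Lorentzian bands — amide-I at 1655 cm⁻¹ and amide-II
  at 1545 cm⁻¹ by default, echoing protein-structure applications — on a
  linear 1000–1800 cm⁻¹ axis, plus noise;
* defaults 64 × 64 pixels, two co-temporal groups of five channels, three
  spectra of 256 points.

Each artifact injection reproduces exactly the signature its QC rule
detects: `flattened_height` applies line-wise leveling at generation time;
`deflection_error` and `phase_error` add uniform offsets (defaults 0.05 V,
30°); `pll_saturation` pins a pixel fraction (default 10%) at the range
limit. The pristine-is-clean / one-artifact-one-flag pairing is the core
QC test harness. All grids are snapped to float32 — the storage type — so
written files round-trip bit-exactly.

What the generator does **not** emulate: probe dynamics, thermal drift,
water-vapour absorption lines, scratching or melting (listed pitfalls for
which no heuristic is defined), correlated scan noise, or vendor-specific
metadata vocabularies. Passing tests therefore demonstrate correctness of
parsing, processing, flag logic and exports — not that the four heuristics
catch every real-world artifact.

# Numerical choices and degenerate inputs

* Bisection tolerances: 1e-6 V (deflection) and 1e-4° (phase), matching
  the precision at which the boundaries are meaningful.
* CSV export renders 9 significant digits — lossless for float32 data —
  with RFC 4180 quoting, LF endings, and errors (rather than resampling)
  on mixed wavenumber axes.
* Timestamp grouping uses exact string equality by default; a seconds
  tolerance is available for instruments that stagger channel writes.
  Maps without timestamps become singleton groups.
* Empty documents are valid: they round-trip, produce empty QC reports,
  and render a summary-only report page.
* Report determinism: HTML output is deterministic by construction; PDF
  output is written uncompressed and its embedded creation/modification
  dates rewritten to a fixed epoch, so identical inputs give identical
  bytes.
* Test and acceptance runs use reduced problem sizes (16 × 16 to 32 × 32
  maps, 64–400-point spectra) — the properties under test are
  size-invariant, and these sizes keep the whole suite in seconds.

# Known limitations

* The dialect is self-consistent but not byte-compatible with proprietary
  vendor files, and the newer-generation instrument format is out of scope.
* No polynomial/facet leveling, scar removal, drift correction, spectral
  smoothing or baseline correction — by design, this is a raw-data tool.
* No multivariate spectral analysis; exports hand the data to tools built
  for that.
* Whether real acquisitions pool trace and retrace for threshold checks is
  unknowable from the outside; this package pools them, and the
  configuration point is the trigger fraction rather than the pooling.
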