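---
title: "Methods: converting Bruker 1D-NMR studies into analysis-ready matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: converting Bruker 1D-NMR studies into analysis-ready matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrbridge)
```

This vignette documents the conversion model behind `nmrbridge`, the
meaning of every tunable parameter, the synthetic data generator used to
validate the pipeline, and the numerical and design decisions a user
should know about before trusting the outputs.

## 1. The problem

Untargeted 1D-NMR metabolomics studies deposited in public repositories
(MetaboLights, Metabolomics Workbench) or collected locally consist of
raw Bruker spectrometer directories: one directory per biological
sample, holding one subdirectory per experiment number (*expno*), each
with acquisition parameters (`acqus`), the raw FID, and processed data
under `pdata/<procno>/` — the processing parameters (`procs`) and the
processed real spectrum (`1r`).  Analysis platforms such as
MetaboAnalyst and Workflows4Metabolomics (W4M) instead expect a single
numeric *samples × features* matrix.  Two obstacles stand between the
two representations:

* **Layout heterogeneity.**  Depositors wrap, flatten, rename and
  archive the Bruker tree in incompatible ways.  The spectral payload is
  identical; only the directory shape differs.
* **Binary decoding.**  The `1r` file is a headerless binary vector
  whose word type, byte order, length and scaling are specified in
  `procs`; the chemical-shift axis is implicit in three more `procs`
  parameters.

`nmrbridge` solves both with a fixed pipeline: detect → standardize →
validate → import → clean → bin → export.

## 2. The canonical study layout

All downstream stages consume exactly one layout:

```
<study>/
  a_*.txt i_*.txt m_*.txt s_*.txt audit*        (study metadata, optional)
  <sample>/<sample>/<expno>/acqus               (plus acqu, fid)
  <sample>/<sample>/<expno>/pdata/<procno>/procs
  <sample>/<sample>/<expno>/pdata/<procno>/1r
```

The doubled sample directory (`<sample>/<sample>/…`) mirrors how Bruker
TopSpin exports a dataset named after the sample into a folder of the
same name; it is the dominant shape among repository deposits, which is
why it is the canonical one rather than the flatter alternative.

## 3. Layout-variant detection

Each catalogued dialect is a `layout_variant`: a **structural
signature** plus an ordered **transform plan**.  A signature is a set of
*required* and *forbidden* path patterns matched against the full list
of relative paths in the study.  Pattern components are `#` (an
all-digit name — expno/procno), `=N` (a backreference equal to the N-th
component, which is how the doubled sample directory is expressed), or a
shell glob.  Patterns match complete relative paths, so component counts
must agree; this keeps e.g. the flat and doubled layouts structurally
disjoint.

Detection tests variants in registry order and returns the first match
(`STD` first, so an already-canonical study is a no-op).  Signatures are
deliberately written against directory structure (`…/pdata/#`), not
against the presence of `1r` files: a study with deleted spectra should
still *detect* correctly and then fail *validation* with a precise
per-sample report, rather than being declared "unrecognized".

The bundled catalogue covers six dialects:

| id | shape |
|----|-------|
| `STD` | canonical doubled-sample layout |
| `FLAT` | sample directory not doubled: `<sample>/<expno>/…` |
| `DOUBLE_WRAP` | an extra wrapper directory above every sample |
| `ZIPPED` | one zip archive per sample at the top level |
| `NO_PDATA_PROCNO` | `procs`/`1r` directly under `pdata/`, no procno |
| `LOOSE_META` | canonical samples, study metadata in a subdirectory |

Published descriptions of repository practice report more dialects than
they specify; this catalogue is therefore a *documented test surface*,
not a closed list.  New dialects are added at run time with
`register_variant()` (with collision checks against the bundled
fixtures) and persisted with `write_variant_registry()` /
`read_variant_registry()` (YAML).

## 4. Standardization

A variant's transform plan is a sequence of pure path-rewriting steps
(`wrap_dir`, `unwrap_dir`, `rename_by_pattern`, `extract_archive`,
`create_missing_dir`, `move_files`).  Standardization always operates on
a **copy** (`copy_tree` first, then transforms), so the raw deposit is
never touched — important both for reproducibility and because the raw
tree may be the only copy.  Two invariants are enforced by tests:

* **Content preservation.**  The multiset of file contents before and
  after standardization is identical (only paths change), and every
  variant of the same synthetic study standardizes to a tree
  byte-identical to the canonical reference.
* **Idempotence.**  Standardizing an already-canonical tree reproduces
  it exactly.

Zip archives in `ZIPPED` studies are extracted with `utils::unzip`;
output bundles are written by an internal deterministic store-only zip
writer (lexicographic member order, zeroed timestamps, table-driven
CRC-32), so identical inputs yield byte-identical archives — the
system `zip` tool does not guarantee this.

## 5. Validation

A sample is *usable* when at least one expno offers a readable `acqus`
and a `pdata/<procno>/` containing both `procs` and `1r` (the lowest
such procno is used).  The default policy is **per-sample salvage**:
unusable samples are dropped with a warning and listed in the report,
and the study remains valid while at least one usable sample remains.
`strict = TRUE` turns any defect into a study-level
`validation_error`.  Salvage is the right default for repository data,
where one corrupt sample among dozens is common; strictness is the right
default for pipelines feeding publications, and is a single flag away.

## 6. Decoding `1r` and the ppm axis

`procs` is a JCAMP-DX-style parameter file (`##$KEY= value` records,
with `(0..N)` multi-line arrays and `<…>` string delimiters).  Decoding
follows the Bruker conventions exactly:

* word type from `DTYPP`: 0 → int32, 2 → float64 (others are an
  explicit `unsupported_dtype_error`);
* byte order from `BYTORDP`: 0 little-endian, 1 big-endian; a missing
  `BYTORDP` defaults to 0 with a warning;
* length from `SI`; a shorter file is a `truncated_file_error`,
  trailing bytes are a warning;
* physical intensity = stored integer × `2^NC_proc` — `NC_proc` is the
  number of binary shifts applied during processing, so this single
  multiplication restores the processed scale.

The chemical-shift axis is

```
ppm[i] = OFFSET − i · SW_p / (SF · SI),   i = 0 … SI−1
```

descending from `OFFSET` (the ppm of the first point) with constant
spacing `SW_p/(SF·SI)` (spectral width in Hz over spectrometer frequency
in MHz gives the window in ppm).  Both the decoder and the axis are
checked in the test suite against *independent* oracles: a numpy
`fromfile` reader invoked through `system2("python", …)`, a pure-R
byte-assembly reader that reconstructs each int32 from its raw bytes,
and a literal loop evaluation of the axis formula.

## 7. Grid harmonization ("alignment")

Spectra from different samples may sit on slightly different axes
(different `OFFSET`/`SW_p`/`SI`).  `align_to_common_grid()` resamples
every spectrum onto one shared descending uniform grid:

* range = the **intersection** of all per-sample ppm ranges (never
  extrapolate);
* point count = the maximum number of points any input places inside
  that range (never discard resolution the densest spectrum offers);
* interpolation = linear (`stats::approx`), which is exact for affine
  signals, conservative for peaks, and introduces no ringing;
* if all inputs already share a grid they pass through bit-identical;
* an empty intersection raises `no_overlap_error` naming the sample
  that emptied it.

This is **grid harmonization, not peak alignment**: it makes axes
comparable but does not correct chemical-shift drift between samples.
Peak-alignment algorithms (icoshift, CluPA, …) are deliberately out of
scope — they belong to the downstream analysis platforms, and binning
(next section) absorbs drift smaller than the bin width.  Tests bound
the interpolation error via area conservation (< 0.5 % for a half-step
grid shift of a smooth spectrum) and via a brute-force two-point
interpolation oracle.

## 8. Cleaning

`clean_matrix()` applies two rules, in order: columns that are
non-finite in *every* sample are dropped (a dead spectral region carries
no information), then any remaining isolated non-finite value is set to
0 (the spectral baseline), with the count recorded in provenance.
Zeroing is preferred over row-mean imputation because a binned NMR
column is noise-dominated far more often than signal-dominated, and a
deterministic rule keeps outputs reproducible.

## 9. Binning

`bin_matrix()` partitions the harmonized ppm span into `n_bins`
contiguous equal-width intervals; point *i* falls in bin
`floor((hi − ppm[i]) / width) + 1`, i.e. intervals are half-open on the
low-ppm side with the lowest interval closed, so every point lands in
exactly one bin.  The default `n_bins = 1000` is the conventional
dimensionality for exploratory NMR metabolomics (≈ 0.014 ppm buckets
over a 14 ppm window).  The default aggregator is the **mean**, which
keeps binned intensities on the intensity scale of the input and makes
bin values comparable across bin widths; `"sum"` is available for
workflows expecting integrated buckets, and equals mean × per-bin count
exactly.  Requesting more bins than spectral points is an
`over_binning_error`; a bin capturing no point is an `empty_bin_error`
(both are user errors, not silent NA columns).  Bins are labelled by
their **center** ppm rounded to four decimals (`Bin.11.9930`), the
precision the analysis platforms display.

Two semantic caveats, both tested: (a) binning an already-binned matrix
with the same `n_bins` leaves *values* unchanged but the axis now holds
bin centers, so the operation is idempotent on values, not on metadata;
(b) per-bin point counts may differ by one when `SI` is not a multiple
of `n_bins` — the counts are recorded in provenance.

## 10. Exports

* **MetaboAnalyst CSV** — samples in rows: `Sample,Label,Bin.…`.  The
  `Label` (class) column is written empty unless a `labels` mapping is
  supplied, because repositories do not encode sample classes
  uniformly.  Sample names are sanitized (whitespace → underscore).
* **W4M trio** — `dataMatrix.tabular` (features × samples, i.e. the
  transpose), `sampleMetadata.tabular` with `SampleOrder`, and
  `variableMetadata.tabular` with `VariableOrder`; orders are 1-based
  positions in the data matrix.  `plain_ids = TRUE` strips the `Bin.`
  prefix and the dots for platforms that reject non-alphanumeric
  feature ids.

All numbers are written with `%.17g`, the shortest format guaranteed to
round-trip an IEEE-754 double, and files are written with LF line
endings in binary mode; tests confirm bit-for-bit round trips through
both formats and byte-identical outputs across repeated runs.

## 11. Repository client

`fetch_study()` downloads an accession through a pluggable *transport*
(a manifest function plus a fetch function).  Only Bruker-relevant files
are transferred (`acqus`/`acqu`/`fid`/`procs`/`1r`/`1i`, zip archives,
top-level metadata).  Transfers retry with exponential backoff, resume
by size, and verify sizes on completion.  The test suite exercises the
client exclusively through a local-directory transport (including a
deliberately flaky one for the retry logic); the HTTP endpoint templates
shipped in `inst/extdata/endpoints.yaml` are configuration, untested
against the live services by design, since tests must not require
network access.

## 12. The synthetic generator

`synth_spec()` / `generate_study()` produce complete, writable Bruker
studies used as the test bed and by `scripts/acceptance.R`.

**Signal model.** Each sample's spectrum is a Lorentzian mixture

```
L(x) = Σ_k  A_k · w_k² / ((x − c_k)² + w_k²)
```

over a default seven-resonance profile spanning 0.90–8.50 ppm with
line widths of 0.004–0.012 ppm, loosely evoking a serum profile (an
aromatic singlet at 8.4963 ppm, carbohydrate/α-anomeric signals near
4–5 ppm, and dominant aliphatic resonances, the tallest at 1.33 ppm).
Per-sample biological variation is a uniform amplitude jitter of
±15 % per peak; measurement noise is additive Gaussian
(`noise_sd = 50` intensity units by default).  Defaults: 5 samples,
`SI = 16384`, `SF = 600.13` MHz, a 14 ppm window from `OFFSET = 12`,
`NC_proc = −3`, pulse program `noesygppr1d`.

**Realism and limits.**  The generator reproduces what the *pipeline*
is sensitive to — file formats, integer quantization, axis conventions,
layout dialects, defects — not full NMR physics.  It has no J-coupling
multiplets, no baseline distortion, no phase errors, no water residual,
no chemical-shift drift between samples.  Those phenomena live entirely
inside the `1r` values the pipeline copies; they would not exercise any
additional code path, and modelling them would only obscure the
quantization-level error bounds the tests rely on.

**Ground truth and error bound.**  The generator stores the
pre-quantization signal+noise matrix as ground truth, so a correct
import differs from truth by at most the int32 quantization step
`2^NC_proc` (for the defaults, `2^-3 = 0.125`); the acceptance suite
checks end-to-end conversion of every layout dialect against this
bound.  Amplitudes that would overflow int32 raise an
`amplitude_error` at write time instead of wrapping silently.

**Determinism.**  Everything is derived from `seed`; the generator
saves and restores the caller's RNG state, so fixture creation never
perturbs user code.  Defects (`missing_1r`, `missing_procs`,
`missing_acqus`, `empty_sample`) are applied to the canonical tree
first, then `scramble_tree()` applies the *inverse* of a variant's
transform plan — so a generated `FLAT` study is, by construction,
exactly what standardization must undo.

## 13. Problem sizes and performance

The test suite runs studies of 1–5 samples at `SI` 128–2048 in seconds;
the acceptance script uses 5 × 16384 (the default full resolution) for
the main pipeline and 5 × 2048 per layout variant.  All stages are
vectorized (the binner reduces 16384 → 1000 columns via a single
`rowsum` on the transposed matrix); a realistic repository study of ~100
samples at `SI = 65536` is dominated by file copying during
standardization, not by numerics.

## 14. Design decisions and limitations

* **Tool, not estimator.**  The package's unit of work is a study
  conversion with provenance, not a model fit, so the API is a pipeline
  of verbs (`detect_format`, `standardize`, `import_data`, `bin_matrix`,
  exporters) around small S3 value classes (`study_tree`,
  `layout_variant`, `spectral_matrix`) rather than a single fitting
  function with `print`/`summary`/`predict` methods.
* **Structured failures.**  Every anticipated failure is a classed
  condition (`validation_error`, `unrecognized_format_error`,
  `truncated_file_error`, …) mapped to a distinct CLI exit code, so
  batch drivers can triage studies mechanically.
* **Only `1r` is imported.**  The imaginary part (`1i`) and raw FID are
  preserved through standardization but not decoded; re-processing FIDs
  (apodization, FT, phasing) is out of scope.
* **No peak alignment, baseline correction or normalization.**  These
  are analysis-platform responsibilities; the tool's contract is a
  faithful, reproducible matrix of what the depositor processed.
* **First-match detection.**  Variant order matters when signatures
  could overlap; the bundled six are mutually exclusive by construction
  (tested), and `register_variant()` rejects id collisions while
  checking new signatures against the bundled fixture studies.
* **Detection is structural only.**  A study whose *contents* are
  corrupt but whose *shape* is canonical detects as `STD` and fails
  later with a precise error — by design, since content errors deserve
  content-level messages.
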