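---
title: "Methods: Resonant Recognition Model analysis with rrmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Resonant Recognition Model analysis with rrmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmtools)
```

## The model

The Resonant Recognition Model (RRM) postulates that the biological
selectivity of proteins and DNA is carried by periodicities in the
distribution of the energy of delocalized electrons along the macromolecular
backbone, and that these periodicities correspond to electromagnetic
resonances through which interacting molecules recognize each other. The
computational procedure is pure signal processing:

1. each residue is replaced by its electron-ion interaction potential
   (EIIP), giving a numerical series;
2. the Fourier amplitude spectrum of the mean-removed, zero-padded series is
   taken on the dimensionless grid $f = k/N \in [0, 0.5]$ cycles/residue;
3. for a group of sequences sharing a function, the member spectra are
   multiplied pointwise (the cross-spectral function); the surviving common
   peak is the group's *characteristic frequency* $f_0$;
4. $f_0$ maps to a light wavelength via $\lambda = K/f_0$ (nm, $K = 201$)
   and to a physical frequency via $f_0\,v/d$ ($v = 7.87\times10^5$ m/s,
   $d = 3.8$ Å).

Interacting pairs are further proposed to share $f_0$ with *opposite
phase*: a Fourier phase difference of $\pi$ at $f_0$.

The model's physical claims are controversial and are not adjudicated here;
the package implements the computation faithfully and keeps every physical
constant explicit and swappable (`rrm_constants()`).

## Assumptions and tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| scale | `eiip_protein` | Rydberg | residue → potential map |
| `n_points` | 512 | — | transform size; grid step is `1/n_points` |
| `min_snr` | 20 | — | consensus-peak significance threshold |
| `classify_tolerance` | 0.004 | cycles/residue | catalog lookup half-width |
| `K` | 201 | nm | wavelength coefficient |
| `charge_velocity` | 7.87e5 | m/s | physical-frequency route |
| `residue_spacing` | 3.8e-10 | m | physical-frequency route |
| `coverage_threshold` | 0.05 | fraction of source max | light coverage |
| `half_band_nm` | 10 | nm | light coverage band half-width |
| `water_window` | 380–750 | nm | water transparency band |

Choices that the underlying literature leaves open, decided here once:

* **Cross-spectrum definition.** The multiplicative amplitude cross-spectrum
  (pointwise product over members) — the only definition consistent with
  extracting a component common to *all* members: a single member with zero
  amplitude at $f$ annihilates $f$.
* **Unequal lengths.** Members are brought to a common grid by zero-padding
  after mean removal, never by interpolation, which would distort phases.
* **No member normalization by default.** Whether the original analyses
  normalized member spectra before multiplication is unstated; the product
  of raw amplitudes is used, with `cross_spectrum(normalize = TRUE)`
  available as a sensitivity check (normalization rescales the consensus but
  cannot move its argmax).
* **`min_snr = 20`** is the conventional RRM significance cutoff; no
  statistical null model beyond the S/N ratio is offered, because the method
  defines none.
* **Unknown residues** (`X`, `B`, `Z`; `N` in DNA) error under the default
  `strict` policy, since silent substitution changes the spectrum. `skip`
  and `zero` policies are explicit opt-ins. `U` is read as `T` in DNA mode
  so RNA encodes directly.
* **Opposite-phase tolerance** defaults to $\pi/4$; no tolerance is stated
  in the literature.
* **Rounding.** Catalog wavelengths are integer nm obtained by rounding
  half-up (`round_half_up()`), the convention that reproduces the published
  table wherever it is internally consistent.
* **Config format.** JSON (via jsonlite), because it is the one declarative
  format with a parser guaranteed in the package's dependency footprint.

## The catalog and its surfaced inconsistencies

The bundled catalog (`inst/extdata/table1_catalog.csv`, integrity-checked by
MD5 at load) transcribes 68 characteristic frequencies for protein and DNA
functional groups, with super-family blocks: Tumor regulation (0.027–0.054,
12 rows), Viral-bacterial infection (0.0839–0.115, 7), Growth
(0.285–0.3203, 8), Enzymes (0.3281–0.4297, 15), Structural proteins
(0.434–0.449, 3) and Blue (0.475–0.4765, 2). En-dashes in the original
labels are transliterated to ASCII hyphens.

Three inconsistencies in the source table are *surfaced, not repaired*:

* Two rows print wavelengths as **"100 K"** (f = 0.002) and **"20 K"**
  (f = 0.0234). Neither is consistent with $\lambda = 201/f$ (which gives
  100500 and 8590 nm); whether "K" denotes thousands under some other
  convention is unknowable from the source. They are stored verbatim with a
  null numeric wavelength and excluded from every numeric path (fitting,
  round-trips, coverage — where they are reported "unevaluable").
* Three numeric rows disagree with $\mathrm{round}(201/f)$ by 1 nm:
  f = 0.0446 prints 4508 (computed 4507), f = 0.289 prints 695 (computed
  695.50 → 696 half-up), f = 0.297 prints 678 (computed 676.77 → 677). The
  loader flags them (`eq1_consistent = FALSE`). The acceptance test
  asserting exact agreement for all 66 numeric rows is therefore
  **intentionally red**: the claim does not hold of the published table
  itself, and silently excluding the three rows would hide that.
* The narrative gives the tumor-regulation band as 0.031–0.054 while the
  table's colored block starts at 0.027 (Protein A-VHIII).
  `superfamily_band("Tumor regulation")` follows the table — the primary
  data artifact — returning (0.027, 0.054) with a `"note"` attribute
  recording the conflict.

Fitting $\lambda = K/f$ by least squares through the origin over the 66
numeric pairs returns $\hat K = 201.0026$, confirming $K = 201$ to well
within ±1.

## Light-source coverage

`blackbody_spectrum()` is Planck spectral radiance **per unit wavelength**,
normalized to maximum 1 (so a 5778 K sun-like source peaks at 501 nm, per
Wien's displacement law). `line_spectrum()` sums Gaussian bumps (width =
standard deviation in nm). The `light_preset()` sources — "sunlike",
"incandescent", "led_fixture", "cfl_fixture" — are *synthetic stand-ins*
emulating the qualitative continuous-versus-peaked shapes of real sources;
no measured lamp curve is bundled, and none of the presets should be
mistaken for radiometric data.

A catalog record is *covered* when the source's maximum intensity within
±`half_band_nm` of the record's wavelength reaches `coverage_threshold`
times the source maximum. This relative criterion makes one documented
consequence unavoidable: a normalized per-wavelength Planck curve at 5778 K
has relative intensity ≈ 6.6e-3 at 3722 nm and ≈ 5.0e-4 at 7444 nm, so at a
1% threshold the far-infra-red Tumor-regulation records are **not** covered
by the sun-like preset. An acceptance test asserting full coverage at that
threshold is intentionally red; the claim would hold for radiance per unit
*frequency*, but that form contradicts the per-wavelength Wien peak the
other tests pin down. The qualitative contrast the analysis actually needs —
peaked visible sources cover enzyme/growth bands while missing tumor
regulation and viral-bacterial bands entirely — holds at any threshold and
is tested green.

The water-transparency window defaults to the conventional visible band,
380–750 nm; this is a package choice, not a literature value.

## The synthetic-data generator

`synth_group()` emulates exactly one feature of a functional group: a shared
periodicity. Member $i$ of length $L_i$ is
$a\cos(2\pi f_0 j + \varphi_i) + \varepsilon_j$, with
$\varepsilon_j \sim N(0, s^2)$ i.i.d. and phases either supplied or uniform.
Defaults ($n = 5$, $L = 128$, $a = 1$, $s = 0.5$) give a signal-to-noise
regime in which the consensus peak is recovered essentially always; all
generation is a pure function of its arguments including the seed (applied
locally — no global RNG state is touched). `quantize_to_sequence()` maps a
series to the residue with the nearest scale value (ties alphabetical:
the EIIP scale has two such pairs, I/L at 0.0000 and C/S at 0.0829), letting
fixtures round-trip through FASTA and the encoder.

What the generator does **not** emulate: amino-acid composition bias,
homology structure, length distributions of real protein families, or any
biological correlation between noise and signal. A green recovery test
therefore establishes that the pipeline's signal path is correct — encoding,
transform, product, peak call, and file round-trip preserve an embedded
periodicity — and nothing about whether real functional groups share such
periodicities.

## Numerical choices

* Mean removal precedes zero-padding, so the padded series still sums to
  zero and the DC bin is exactly 0; it is excluded from the S/N mean and is
  never callable as a peak.
* Frequencies are reported at grid resolution only (no sub-bin
  interpolation); ties in the peak call break toward the lower frequency.
* Phase differences are computed from the cross term
  $\arg(X_a \overline{X_b})$, which yields exactly $\pi$ for $b = -a$ and
  exactly $0$ for $b = a$ in IEEE arithmetic, rather than by subtracting two
  `atan2` results. Phase is declared undefined (an error) where either
  amplitude is below $10^{-12}$ of that spectrum's maximum.
* Histogram bins are half-open $[kw, (k+1)w)$ covering $[0, 0.5]$ with
  zero-count bins included; rows sharing a frequency each count once.
* Coverage interpolates the source linearly at band endpoints that fall
  between grid points; a band wholly outside the source grid is
  "out of range", which counts as not covered in super-family summaries.

## Verification

The test suite checks the spectral engine against an independent $O(N^2)$
direct Fourier sum on all series lengths 4–64, Parseval's identity on the
padded series, closed-form S/N values, 100-seed consensus-peak and
full-pipeline (quantize → FASTA → encode) recovery runs, and the exact
phase-opposition identities. `scripts/acceptance.R` recomputes the catalog
wavelength mappings and the K fit from the installed package at run time.

## Known limitations

* The catalog is a fixed snapshot; no curation interface is provided.
* No wavelet or sliding-window analysis; characteristic frequencies are
  global per sequence.
* No radiometric or photometric calibration of light sources, and no
  modelling of tissue penetration; coverage output is descriptive only, and
  no health inference is computed.
* The two routes from RRM frequency to physical scale ($K = 201$ nm versus
  $c\,d/v \approx 145$ nm) disagree by ~39%; both are exposed unchanged.
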