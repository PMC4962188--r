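# rrmtools

Tools for the **Resonant Recognition Model (RRM)** of protein and DNA
interactions. The RRM treats a sequence as a discrete signal — the
distribution of the energy of delocalized electrons along the backbone,
obtained by replacing each residue with its electron-ion interaction
potential (EIIP) — and proposes that sequences sharing a biological function
share a periodicity in that signal. The package is for computational
biologists and biophysicists who want to extract characteristic frequencies
from sequence groups, relate them to electromagnetic wavelengths, and ask
which of those wavelengths a given light source actually emits.

## The method

For a group of sequences with a common function:

1. **Encode** each sequence `s` as the series `x[j] = EIIP(s[j])`.
2. **Transform**: subtract the mean, zero-pad to a common grid of `n_points`,
   and take the discrete Fourier amplitude spectrum on the dimensionless
   frequency grid `f = k/n_points`, `f ∈ [0, 0.5]` cycles/residue.
3. **Consensus**: multiply the member amplitude spectra pointwise
   (the cross-spectral function). The consensus peak frequency `f₀` is the
   group's *characteristic frequency*, called significant when its
   signal-to-noise ratio (peak amplitude over the spectrum-wide mean)
   exceeds `min_snr` (default 20).
4. **Map to light**: the characteristic wavelength is `λ = K / f₀` with
   `K = 201` nm; the physical frequency is `f₀ · v / d` with charge velocity
   `v = 7.87e5` m/s and residue spacing `d = 3.8` Å, spanning roughly
   10¹³–10¹⁵ Hz (infra-red through ultra-violet).
5. **Classify**: look the frequency up in the bundled catalog of 68
   characteristic frequencies for known functional groups, organised into
   super families (Tumor regulation, Viral-bacterial infection, Growth,
   Enzymes, Structural proteins, Blue).

Interacting partners are additionally proposed to share `f₀` with phases in
opposition (difference ≈ π); `phase_difference()` tests that predicate.

## Worked example

A synthetic group of five 128-residue sequences with an embedded periodicity
at 0.300 cycles/residue (the simulator quantizes the signal to real residues,
writes FASTA, and the pipeline reads it back cold):

```r
library(rrmtools)
sc <- load_scale("eiip_protein")
fx <- synth_group(f0 = 0.300, n = 5, lengths = 128, noise_sd = 0.5, seed = 42)
fa <- tempfile(fileext = ".fasta")
write_fixture_fasta(fx, sc, fa)
res <- run_group_analysis(fa, rrm_config(out_dir = NULL))
print(res$peak)
res$classification[, c("rrm_frequency", "wavelength_nm", "functional_group")]
```

prints

```
constants: K = 201 nm, v = 787000 m/s, d = 3.8e-10 m
peak at f = 0.300781 (S/N 101.9) -> 668 nm
<rrm_peak> f = 0.300781 cycles/residue, amplitude 1400, S/N 101.9
   rrm_frequency wavelength_nm     functional_group
39         0.300           670     IL-2, IL-4, IL-6
38         0.297           678 CSF, Ubiquitins, EPA
```

The consensus peak lands on the grid bin nearest the embedded 0.300
(154/512 = 0.3008) with S/N far above the default threshold of 20; its
wavelength 201/0.3008 ≈ 668 nm; and the catalog lookup returns the two
functional groups within the default tolerance of ±0.004, nearest first.
Both are Growth super-family records, as expected for a frequency of 0.300.

Light-source coverage of the catalog:

```r
cov <- coverage_report(light_preset("sunlike"), threshold = 0.01)
print(cov)
#> <rrm_coverage> source 'sunlike (synthetic 5778 K blackbody)', threshold 0.01, half-band 10 nm
#>   records: covered=53, uncovered=13, unevaluable=2
#>   super-family coverage:
#>     Blue                       2/2 covered
#>     Enzymes                    15/15 covered
#>     Growth                     8/8 covered
#>     Structural proteins        3/3 covered
#>     Tumor regulation           0/12 covered
#>     Viral-bacterial infection  7/7 covered
```

A narrow-line visible source (`light_preset("led_fixture")` or
`light_preset("cfl_fixture")`, both clearly-labelled synthetic stand-ins)
covers the visible-band super families but misses the far-infra-red
Tumor-regulation band entirely — and, at a 1% relative threshold, so does a
normalized per-wavelength Planck curve (see the vignette for why).

## Command line

```sh
inst/cli/rrm analyze group.fasta --out-dir results --n-points 512
inst/cli/rrm map --frequency 0.25 --to nm
inst/cli/rrm classify --frequency 0.300
inst/cli/rrm coverage --preset cfl_fixture
inst/cli/rrm simulate --f0 0.25 --n 5 --length 128 --out fixtures/
```

Exit codes: 0 success, 2 I/O error, 3 validation error.

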