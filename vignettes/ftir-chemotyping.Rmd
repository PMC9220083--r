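---
title: "Multi-block chemotyping of FTIR fingerprints: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block chemotyping of FTIR fingerprints: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftirfuse)
```

`ftirfuse` analyses whole-cell transmission FTIR spectra of bacterial
isolates cultivated in a crossed nutrient x temperature design: five agar
media (rich BHI plus the defined minimal media MGU, MGY, XGU, XGY) at 4,
10, 18 and 25 degrees C, with three biological and three technical
replicates per condition. This vignette explains the models the package
implements, the parameters that matter, the numerical choices behind them,
and what the bundled synthetic study does and does not demonstrate.

## Spectral container and conventions

Spectra live on one shared, strictly increasing wavenumber grid (cm^-1);
instrument exports listed 4000 -> 500 are reversed on read. No resampling
or interpolation is ever performed: all spectra of a dataset must share the
grid bit-identically, which the generator guarantees and `spectra_set()`
enforces. All interval notation is inclusive, `[lo, hi]` in cm^-1.

## Quality screening

Three transparent criteria screen raw absorbance spectra, applied in order
so each failure has one reason:

* `low_signal` - peak height (max minus min) in the signal window
  (default 1700-1600 cm^-1, covering the Amide I band) below
  `min_peak_absorbance` (default 0.05 AU): too little biomass.
* `saturated` - any absorbance above `max_absorbance` (default 2.0 AU).
* `low_snr` - peak height divided by the noise estimate below `min_snr`
  (default 20). Noise is the standard deviation of the *linearly detrended*
  absorbance in a quiet window (default 2200-1900 cm^-1, with an optional
  exclusion interval for atmospheric CO2); without detrending, a sloping
  baseline would masquerade as noise.

These are deliberately simple, documented heuristics, not a published
quality-test algorithm; every threshold is a config field. QC precedes
replicate averaging, so a failed replicate weakens but does not remove a
condition.

## Region-wise preprocessing

Spectra are split into four biochemical regions - lipid (3050-2800 and
1800-1700), protein (1700-1500), mixed (1500-1200), polysaccharide
(1200-700 cm^-1) - and each region is preprocessed separately: (1)
Savitzky-Golay second differentiation with windows 13/21/17/13
(lipid/protein/mixed/polysaccharide) and a second-order polynomial; (2)
EMSC with linear and quadratic terms.

Differentiation details. The filter matrices come from the `signal`
package; boundary points use the asymmetric window rows (the local
polynomial evaluated off-centre), so output length equals input length.
The two lipid intervals are differentiated per contiguous segment - a
window never spans the gap - but EMSC-corrected jointly, since the lipid
region is one region chemically. Derivatives are scaled by 1/dnu^2
(units absorbance * cm^2), making results invariant to grid spacing. Two
numerical choices keep the filter exact (to ~1e-11) on quadratic test
signals whose absolute values reach 1e7: each segment is row-centred and
linearly detrended before filtering. Both operations are annihilated by a
second-derivative filter in exact arithmetic, but they shrink the
magnitudes entering the dot products by several orders, which is what
makes the "second derivative of 3 nu^2 + 2 nu + 1 equals 6 everywhere"
property hold at tight absolute tolerance.

EMSC details. Each spectrum is regressed on the design
`[1, m, u, u^2]`, where `m` is the reference and `u` is the region's
wavenumber axis min-max rescaled to [-1, 1] (rescaling conditions the
quadratic term). The reference is the mean of the set being corrected -
the derivative-set mean on the multiblock path, the raw wide-region mean
on the correlation path; whether the original analysis used an overall or
per-region mean is unknowable from the outside, so the set mean (the
standard default) is the documented choice. Corrected spectra are
`(z - a - d u - e u^2)/b`. A fitted gain `|b| < 1e-8` means the spectrum
carries essentially no reference signal; dividing by it would amplify
noise arbitrarily, so such spectra are excluded with a `gain_degenerate`
report rather than corrected. EMSC is exactly idempotent when the same
reference is reused; re-estimating the reference from corrected output
changes results at the size of the residual coupling (~1e-4 on the default
study), which is why the package stores the reference it used.

## Fusion and consensus PCA

Replicates are averaged with equal weights - biological and technical
pooled in one arithmetic mean - to one spectrum per strain x medium x
temperature. Each medium then forms one block, rows aligned on the
(strain, temperature) key in lexicographic order; a key missing from any
block (poor growth, failed QC) is removed from all blocks and reported.

Each block is column-centred and scaled to unit Frobenius norm, giving
every medium equal total variance in the fusion - the natural reading of
"each medium is one block" when no block scaling is prescribed. Components
solve the consensus fixed point

    p_b ~ X_b' t,   t_b = X_b p_b,   w ~ T' t,   t = T w

with unit-norm block loadings and super weights, started from the
concatenated column of maximal variance and iterated until the relative
global-score change falls below 1e-10 (at most 500 sweeps, error
otherwise). Blocks are deflated by regression on the global score. This
variant was chosen deliberately because it makes the global scores equal,
up to per-component sign, to the PCA scores of the concatenated scaled
matrix - so an independent SVD acts as an oracle in the tests, and
explained-variance fractions are singular-value ratios. Signs are fixed by
making each global score's largest-magnitude entry positive.

One numerical subtlety: the sweep is exactly a power iteration on the
concatenated cross-product, whose convergence rate degrades without bound
as the leading singular values approach each other (a 0.5% gap needs more
than 700 sweeps to reach 1e-10). If the sweep has not converged after 30
iterations, it is re-seeded from the dominant eigendirection computed by a
restarted Lanczos procedure (own code, full reorthogonalization, Krylov
dimension 30) that shares the fixed point; the convergence criterion and
iteration cap are unchanged, and rank-deficient inputs still return fewer
components with a warning.

Projection. Projecting spectra onto a single block's score space must
reproduce the training block scores exactly, yet the fitting deflation
uses the global score, which a single block cannot see. The package
therefore stores, per block, linear projection weights built by replaying
the deflation symbolically, with the global score of each earlier
component estimated from the block alone through its minimum-norm
regression. Whenever the block spans the centred sample space (columns >=
rows - 1, always true for spectral blocks), that estimate is exact on
training rows, and training reprojection reproduces stored block scores to
1e-10; for blocks with fewer columns than rows the projection is the
least-squares best linear read-out. Projecting the stored column-mean
vector yields exactly zero scores.

## Correlation loadings

The correlation path pools all growth conditions of one genus as rows,
restricts to 3050-2800 and 1800-900 cm^-1, EMSC-corrects *without*
differentiation, and fits an ordinary column-centred PCA. Correlation
loadings are Pearson correlations between component scores and variables:
peak absorbances read at the nearest grid point to each listed wavenumber
(point reading is the minimal choice when no band integration is
prescribed; polysaccharide-region peaks are excluded by default), plus the
design as supplementary variables - 0/1 dummies per medium, per
temperature and per strain - which never enter the fit. Temperature can
instead be coded ordinally (4/10/18/25 as one numeric variable) via
`temperature_coding = "ordinal"`; dummies are the default because
correlation-loading plots conventionally show each level as its own point.
A genus grown only on BHI has no medium variables at all, and any constant
variable is reported as dropped rather than given an undefined correlation.

Peak picking finds strict local minima of the mean second-derivative
spectrum (an absorption band is a negative well at its centre), per
segment, keeping minima at least `prominence_frac` (default 0.01) of the
maximum absolute derivative below zero. Endpoints of a segment cannot be
strict minima and are never reported; on the package's 2 cm^-1 grid a peak
position is resolved to within one grid step.

A note on recovering the temperature effect: with all five media present,
media differences dominate the leading components and temperature
loadings are small - the expected behaviour for this design, in which
nutrient composition is the stronger factor. The package's temperature
recovery check (`temperature_peak_correlation()`) is therefore run on a
genus grown on BHI only, where temperature is the only design factor: the
component most correlated with ordinal temperature then also carries the
2925 cm^-1 CH2 peak at |r| > 0.9 under the generator's default slope.

## Growth scoring

Streak-plate observations map onto the banded 0-10 scale: no growth is
band 0; growth confined to the inoculation/first-streak area without
single colonies is 1-2; growth reaching the second streak area with
colonies under 0.5 mm is 3-4; growth on all four areas scores by colony
diameter (0.5-1.0 mm -> 5-6, 1.5-2.0 mm -> 7-8, > 2.5 mm -> 9-10). The
scale leaves gaps (1.0-1.5 and 2.0-2.5 mm) and unenumerated combinations
(e.g. colonies on all areas under 0.5 mm); both are assigned to the lower
adjacent band - the conservative choice, and the one that keeps the score
monotone in diameter. Bands, not single integers, are the unit of the
scale because only bands are ever distinguished by the colour grading
(0-2 red, 3-4 orange, 5-6 yellow, 7-8 blue, 9-10 green). A strain "grows
on minimal media" when it reaches band 3-4 on any of MGU/MGY/XGU/XGY at
any temperature. The bundled 45-isolate collection and its reconstructed
observation table (synthetic streak-area/diameter entries consistent with
the banded summary; 19 minimal-media growers) live in
`green_snow_strains()` and `green_snow_growth_observations()`.

## The synthetic study

`generate_dataset()` simulates the whole design so every stage is testable
without measured spectra. Clean condition spectra are sums of Gaussian
bands at characteristic wavenumbers; each replicate is
`gain x clean + a + d u + e u^2 + noise` with lognormal gain
(`gain_sigma = 0.05`), uniform baseline coefficients and additive Gaussian
noise (`noise_sigma = 0.001` AU - a high-quality spectrum relative to band
heights of 0.15-0.8 AU). The grid is 500-4000 cm^-1 at 2 cm^-1: denser
than the instrument's 6 cm^-1 resolution so that a 13-point window spans
~26 cm^-1, comparable to band widths. Planted effects:

* Genus - distinct multipliers on the four lipid bands per genus (around
  +-20-30%), mild class-level differences elsewhere; the four default
  genera's profiles are pairwise non-proportional so three consensus
  components separate them. `genus_effect_scale = 0` switches the effect
  off for null experiments.
* Medium - the ester C=O centre moves with the medium (BHI/XGU 1743, MGU
  1741, MGY/XGY 1739 cm^-1) and protein/mixed/polysaccharide classes get
  medium multipliers of up to ~15%. CH-stretch bands carry no medium
  effect, so the temperature effect lives in its own spectral direction.
* Temperature - CH-stretch heights change by `temp_slope_lipid = 0.004`
  per degree C away from 18 degrees C (about +-5% over the design range),
  a magnitude chosen once as a realistic membrane-lipid response.
* Strains jitter every band height lognormally
  (`strain_sigma = 0.01`) - small against genus effects, so strains
  cluster within their genus.
* Growth - a per-(genus, medium, temperature) band table; combinations
  below band 3-4 produce no spectra (growth-dependent missingness). The
  default design grows everywhere, best at 18 degrees C.

Everything planted (gains, baselines, clean spectra, the design) is stored
in a truth record keyed by a run id, and `truth_check()` compares pipeline
outputs against it. Fitted EMSC gains are compared after normalizing to
the replicate-group mean, because a gain is only defined relative to the
reference and clean spectra differ across conditions.

What the generator does not emulate: Lorentzian/Voigt line shapes and band
asymmetry, Mie scattering and other physical baseline artifacts, water
vapour lines, wavenumber miscalibration, correlated (pink) noise, and
biological covariance between band heights. Passing the pipeline's
recovery checks on this generator therefore demonstrates the correctness
of the algorithms under controlled conditions, not performance on measured
spectra.

## Problem sizes and runtime

The default synthetic study is 4 genera x 5 strains x 5 media x 4
temperatures x 9 replicates = 3600 spectra on 1751 grid points, generated
and analysed in seconds; the test suite and the acceptance script use this
size for the phenotype-recovery and ester-shift checks, 50 random small
instances (<= 12 rows, <= 3 blocks, <= 6 columns) for the CPCA/SVD oracle,
10 random growth designs for fusion, and 20 seeds x 200 permutations for
the zero-effect null of the correlation analysis. For that null, the
observed max |cor(temperature dummy, peak)| is allowed to exceed its own
permutation 95th percentile in at most 3 of 20 seeds - the binomial(20,
0.05) calibration of a bound that a literal "never exceeds" reading would
fail by construction about two times in three.

## Known limitations

* QC thresholds are heuristics with defaults tuned to the generator's
  scale; measured data may need different windows and floors.
* The CPCA block scaling (unit Frobenius norm) and deflation variant
  (super-score) are declared package choices among several in use;
  alternative variants give different block scores and weights.
* Projection onto a block assumes the block's columns span the centred
  sample space; for blocks with fewer columns than samples the read-out is
  least-squares, not exact.
* The correlation analysis reads peaks at single grid points; band
  integration or fitted band areas would be more robust to peak-position
  shifts between groups.
* Four region models are built (lipid, protein, mixed, polysaccharide);
  the wide correlation region is preprocessed separately and is not one of
  the multiblock regions.
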