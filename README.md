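# chisep — error propagation from R2 mapping into susceptibility source separation

Brain magnetic susceptibility mixes paramagnetic iron and diamagnetic
myelin inside each voxel. Susceptibility source separation decomposes a
QSM-style measurement into non-negative paramagnetic and diamagnetic
component maps by combining two data channels: the reversible relaxation
rate **R2′ = R2\* − R2**, which responds to the *sum* of the sources,

    R2′ ≈ Dr · (χ_para + χ_dia),

and the dipole-induced frequency shift **Δf**, which responds to their
*difference* χ_total = χ_para − χ_dia through the unit dipole kernel
D(k) = 1/3 − (k·b̂)²/|k|². The relaxometric constant **Dr** (Hz/ppm) links
relaxation to susceptibility. Because R2′ inherits every error in the
measured R2 — and R2 mapping from reduced-flip-angle turbo spin echo
trains is notoriously biased by stimulated echoes — the separated
components can be strongly distorted by the R2 mapping method.

`chisep` is a self-contained R test bed for that error pathway. It
provides, as a pipeline over a synthetic ROI-labelled brain phantom with
exactly self-consistent ground truth:

* extended-phase-graph (EPG) simulation of the dual-echo TSE train
  (TR 2500 ms, TE 10/93 ms, turbo factor 8, 165° refocusing), verified
  against an isochromat Bloch oracle to machine precision;
* dictionary R2 fitting (T2 10–2000 ms in 0.1 ms steps × B1 0.4–1.6 in
  0.005 steps), the naive two-point exponential fit, ARLO R2\* fitting,
  and R2′ construction with zero-clipping;
* three R2 corruption schemes: global scaling from 75% to 125% in 1%
  steps (50 altered maps), exponential-fit substitution, and the
  R2 = 0.48·R2\* approximation;
* dipole forward model, closed-form and iteratively refined QSM, Dr
  regression over six deep-gray (structure, side) points, and a
  non-negative projected conjugate-gradient source-separation solver;
* an evaluation layer: per-ROI mean percentage error (MPE), CSF
  exclusion masks, paired t tests across replicate phantoms, and
  MPE-versus-R2-error sweep curves.

## Worked example

```r
library(chisep)

# one "subject": a 64 x 64 x 48 phantom with seeded texture and noise
truth <- generatePhantom(seed = 7)
dict  <- buildDictionary()                       # paper-resolution grid
cfg   <- defaultRunConfig(seed = 7)
base  <- fitBaselineMaps(truth, dict, cfg, seed = 8)

# corrupt R2 by -25 percent, rebuild R2', re-separate, compare
r2low  <- scaleR2Map(base$r2, 0.75)
r2pAlt <- computeR2Prime(base$r2star, r2low)
dr     <- drDefault()                            # 137 Hz/ppm
sep0   <- chiSeparate(base$r2prime, truth@deltaF, dr, truth@geometry,
                      base$brainMask, chiInit = base$qsm)
sepAlt <- chiSeparate(r2pAlt, truth@deltaF, dr, truth@geometry,
                      base$brainMask, chiInit = base$qsm)
round(roiMpe(sepAlt@chiPara, sep0@chiPara, truth@rois, base$exclMask,
             which = c("globus_pallidus_L", "caudate_L", "putamen_L",
                       "splenium")), 1)
```

```
globus_pallidus_L         caudate_L         putamen_L          splenium 
             13.1              26.6              29.6              53.0 
```

Underestimating R2 by 25% *overestimates* the paramagnetic component —
by only ~13% in the iron-rich pallidum (where R2′ is large) but by ~53%
in the splenium (where the paramagnetic baseline is small): the error is
inverted in sign and amplified where the map's own source is weak. The
total susceptibility map stays essentially unchanged (the same call on
`chiTotal` prints MPEs between -0.04% and 0.04% in these ROIs). The full sweep over factors, both Dr
modes, and replicate phantoms is `sweepCurves()`; `runExperiment()`
orchestrates everything and writes the report bundle.

A thin command-line wrapper with `phantom`, `fit-r2`, `fit-r2star`,
`inject-error`, `separate`, `evaluate`, `sweep` and `run-all`
subcommands is installed at `inst/cli/chisep-cli.R`.

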