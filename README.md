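# mpiphantom

Magnetic particle imaging (MPI) detects the nonlinear magnetization of
superparamagnetic iron-oxide tracers: a sinusoidal drive field sweeps the
field-free point (FFP) of a selection-field gradient across the field of
view, and the odd harmonics induced in receive coils encode the local tracer
concentration. Developing a tracer means characterizing its magnetic moment
distribution from quasi-static magnetometry, screening it by magnetic
particle spectroscopy (MPS), and evaluating it in phantom experiments:
reconstructing tube phantoms, optimizing the regularization of the
reconstruction by SNR, and quantifying the visualized volumes and iron
amounts.

`mpiphantom` implements that chain for R users — tracer physicists and
imaging methodologists — with a synthetic FFP scanner standing in for the
hardware, so every stage runs end to end on a desk.

## The models at the core

**Magnetometry.** A dispersion of non-interacting superparamagnetic moments
magnetizes as a Langevin ensemble. Multicore tracers follow a *bimodal
lognormal distribution of magnetic moments*:

    M(B) = M_S [ (1 − β) ∫ L(μB/k_BT) f₁(μ) dμ + β ∫ L(μB/k_BT) f₂(μ) dμ ]

with L(ξ) = coth ξ − 1/ξ, volume-weighted lognormal modes f₁ (elementary
~10 nm domains) and f₂ (large effective multicore moments, the
signal-generating fraction β). `fit_mh()` recovers (β, μ₁, μ₂, σ₁, σ₂, M_S)
by bounded least squares; moments map to equivalent-sphere diameters via
d = (6μ/(π M_vol))^(1/3).

**MPS.** `simulate_mps()` Fourier-analyzes the (optionally Debye-relaxed)
magnetization response to a 10 mT / 25 kHz drive and reports odd-harmonic
amplitudes per mole of iron.

**Imaging.** `build_system_matrix()` simulates the frequency-component ×
voxel system function of an FFP scanner (12 mT drive, (1.25/1.25/2.5) T/m
gradients, Lissajous trajectory); `acquire()` adds complex Gaussian noise
and a paired background measurement; `kaczmarz()` performs regularized
row-action reconstruction (five sweeps, relative regularization factor λ,
non-negativity projection); `segment()`, `snr()`, `lambda_sweep()`,
`volume_and_iron()`, `dual_tube_metrics()` and `mip_render()` implement the
evaluation protocol (30% cutoff + region-based active contours, SNR-optimal
λ selection, volume/iron quantification, shadowing metrics, maximum
intensity projections).

## Worked example

```r
library(mpiphantom)

tracer <- reference_tracer()                 # bundled multicore tracer
curve  <- mh_forward(tracer, mh_field_grid(50))   # synthetic M(H), 0–5 T
fit    <- fit_mh(curve)                      # six-parameter bounded fit
fit
#> Bimodal lognormal M(H) fit (converged)
#>   beta   = 0.7300
#>   mu1    = 0.1851 aAm^2, sigma1 = 0.300
#>   mu2    = 3.9 aAm^2, sigma2 = 0.130
#>   M_S    = 5.808 Am^2/mol(Fe)
#>   d_v2   = 27.6 nm, beta*mu2 = 2.85 aAm^2
#>   residual norm 1.27e-14 after 8 iterations
```

The fit recovers the generating distribution: 73% of the tracer volume sits
in mode B, whose mean moment of 3.9 aAm² corresponds to a 27.6 nm
equivalent sphere — close to the 25 nm optimum for 25 kHz excitation — with
saturation magnetization 5.81 Am²/mol(Fe) (104 Am²/kg(Fe), near bulk
maghemite).

```r
s <- simulate_mps(reference_tracer(temperature = 310), drive_protocol())
s
#> Harmonic spectrum (B0 = 0.01 T, f = 25000 Hz):
#>    k        M_k
#> 1  1 4.73179610
#> 2  3 1.02068616
#> 3  5 0.40173799
#> ...
```

M_k is the k-th harmonic moment amplitude in Am²/mol(Fe). The equilibrium
third harmonic (1.02) overestimates what a spectrometer measures for such a
tracer, since Brownian/Néel losses are not modelled; relaxation damping is
available through `simulate_mps(..., relaxation_time = )`.

A full imaging experiment — phantoms, acquisition, λ sweep, quantification:

```r
cfg <- default_experiment_config("dilution_series")
res <- run_experiment(cfg, out_dir = "out")   # writes CSV, NIfTI, manifest
head(res$report)   # per phantom × orientation × λ: SNR, volume (µL), iron (µmol)
```

A command-line wrapper with the same verbs is installed as
`exec/mpiphantom` (`mpiphantom dilution_series --seed 1 --out out/`).

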