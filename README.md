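# tracheadrs

Monte Carlo modelling and spectral inversion for tracheal diffuse
reflectance oximetry.

## What this package is for

After circular tracheal resection, the viability of the anastomosis
depends on local blood supply; an intraoperative, label-free readout of
tissue oxygen saturation (StO₂) helps catch ischemia before it becomes
necrosis. Contact diffuse reflectance spectroscopy (DRS) in the
500–600 nm band provides that readout, because hemoglobin dominates
absorption there and its oxygenated form (absorption peaks at 542 and
576 nm) differs in shape from the reduced form (single peak near
556 nm).

`tracheadrs` implements the full modelling chain for this measurement,
for researchers in biomedical optics who want to understand which layers
of the tracheal wall a fiber probe actually sees:

* a **layered Monte Carlo photon transport** kernel (compiled, Rcpp) for
  the four-/six-layer tracheal wall with packaged optical properties
  (μa, μs, g at 500/542/556/576/586 nm; n = 1.37), a contact fiber-probe
  geometry (0.25 mm cores, NA 0.37, 0.25 mm source–detector separation),
  Henyey–Greenstein scattering, implicit capture with roulette, and
  counter-based per-photon RNG streams (exact reproducibility and common
  random numbers across paired runs);
* the **DRS processing chain**: attenuation `A = ln(I₀/I)` (or
  `ln(1/Rd)` for simulated reflectance), nonnegative hemoglobin unmixing

  `A(λ) = c₀ + c₁λ + c₂λ² + a_Hb·μa_Hb(λ) + a_HbO2·μa_HbO2(λ)`,

  with `StO₂ = a_HbO2 / (a_HbO2 + a_Hb)`, returned as a classed fit
  object with `print`/`summary`/`coef`/`predict`/`residuals`/`plot`
  methods, plus the chord-subtended **blood-filling** area index;
* **scripted experiments** reproducing the simulation studies:
  perichondrium oxygenation contrast from either access side,
  layer-thickness sweeps, saturation sweeps, and the end-to-end StO₂
  recovery from simulated spectra;
* a **synthetic clinical-spectrum generator** (forward model against a
  reference spectrum with seeded multiplicative noise) and a small
  **command line interface** (`inst/cli/tracheadrs`) with YAML/JSON
  configs and CSV/JSON outputs.

## A worked example

Simulate the six-layer wall probed from the adventitial side, convert
to attenuation, unmix, and run the oxygenation-contrast experiment:

```r
library(tracheadrs)

st  <- build_stack("six", probe_side = "adventitial")
tal <- simulate_spectrum(st, config = sim_config(n_photons = 1e5, seed = 1))
tal
#> Monte Carlo detection tally
#>  wavelength_nm       Rd        Td Rd_total Td_total absorbed     Rd_se n_photons
#>            500 0.009126 3.396e-05   0.2481  0.02599   0.7259 0.0002529     1e+05
#>            542 0.006869 4.731e-05   0.1746  0.01864   0.8067 0.0002090     1e+05
#>            556 0.007064 2.218e-05   0.2107  0.02939   0.7599 0.0002205     1e+05
#>            576 0.005565 4.048e-05   0.1589  0.02406   0.8170 0.0001869     1e+05
#>            586 0.007643 6.547e-05   0.2134  0.03446   0.7521 0.0002296     1e+05
#> photon-count uncertainty: 0.3162% (1/sqrt(N))
```

`Rd` is the fraction of launched photon weight reaching the receiving
fibers (annular footprint + NA acceptance); `Rd_total` is everything
re-emerging from the illuminated face; rows sum to one with `absorbed`
and `Td_total`. Note the dips at 542 and 576 nm — the oxyhemoglobin
double peak imprinted on the detected signal.

```r
fit_attenuation(attenuation_from_reflectance(tal), poly_degree = 1)
#> Attenuation-model fit (polynomial baseline + Hb/HbO2 unmixing)
#>   5 wavelengths, baseline degree 1
#>       c0       c1       c2   amp_Hb amp_HbO2
#>   3.4400   0.0021   0.0000   0.0000   0.0016
#>   StO2 = 100.0%   residual norm = 0.1007

perichondrium_contrast("adventitial", n_photons = 1e5, seed = 1)
#> Perichondrium oxygenation contrast (adventitial side, relative metric)
#>  wavelength_nm diff_pct mc_se_pct
#>            500    0.396     3.913
#>            542    0.645     4.289
#>            556    2.083     4.457
#>            576    2.634     4.674
#>            586    1.261     4.281
#> mean over wavelengths: 1.40% (sd 0.95%, MC se 1.94%)
```

Flipping a fully oxygenated perichondrium to fully deoxygenated changes
the adventitial-side signal by a few percent (it sits 0.1 mm under the
probe); running the same experiment with `side = "mucosal"` gives a mean
difference far below 1%, because from the lumen the perichondrium lies
1 mm deep — the model's core clinical message about choosing the access
side. (The fully oxygenated bloodless baseline rows fit to StO₂ = 100%
here; see the vignette on baseline-shape degeneracy.)

The same machinery is scriptable from a shell:

```sh
inst/cli/tracheadrs simulate --out run1 --model six --side adventitial \
    --photons 100000 --seed 42
inst/cli/tracheadrs invert --sample spectrum.csv --reference baso4.csv \
    --out fit.json
inst/cli/tracheadrs experiment --name blood-filling-recovery --out rec \
    --photons 500000 --seed 7
```

See `vignettes/tracheal-drs-model.Rmd` for the model, its assumptions,
parameter choices and known limitations.

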