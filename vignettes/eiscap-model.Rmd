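---
title: "A two-region capacitive model for nanoparticle-decorated EISCAP sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-region capacitive model for nanoparticle-decorated EISCAP sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiscap)
```

## The device and the question

An electrolyte-insulator-semiconductor capacitor (EISCAP) is the simplest
capacitive field-effect sensor: a semiconductor substrate (here p-type Si),
a thin gate insulator (SiO~2~), an electrolyte in contact with the
insulator, and a reference electrode that applies the gate voltage
$V_G$. Any change of the potential at the insulator-electrolyte interface
re-biases the semiconductor surface underneath and moves the
capacitance-voltage (C-V) curve along the voltage axis — which is what
makes the structure a transducer for label-free charge detection.

When the surface is decorated with charged, ligand-stabilized
nanoparticles, the particles act as nanometer-sized local gates. Because
electrostatic inter-particle repulsion keeps the layer far from close
packing, only a fraction $n$ of the area is covered. This package models
the decorated device as **two non-interacting sub-regions in parallel**:

* a covered region of area $nA$ with interfacial potential
  $\varphi_{NP} = \varphi_0 + \Delta\varphi$, and
* a bare region of area $(1-n)A$ with interfacial potential $\varphi_0$,

where $\Delta\varphi$ is the potential change imposed by the particle
charge. Each region is a gate-insulator capacitance in series with the
depletion-approximation space-charge capacitance of the silicon beneath
it; fringing-field overlap between the local depletion regions is assumed
absent, and for the thin oxides, sub-kHz frequencies and >0.1 mM ionic
strengths typical of these measurements the electrolyte series elements
(solution resistance, double layer) are negligible compared with the
oxide and space-charge capacitances, so they are not part of the model.

## Model equations

With $C_{i0} = \varepsilon_i/d_i$ the insulator capacitance per unit
area, the per-area series capacitance of one sub-region at an effective
voltage $x = V_G - V_{fb}$ above its flat-band voltage is

$$ c(x) = \frac{1}{S(x)}, \qquad
   S(x) = \sqrt{\frac{1}{C_{i0}^2} + \frac{2x}{q\,\varepsilon_s N_a}}
        = \frac{1}{C_{i0}} + \frac{w(x)}{\varepsilon_s}, $$

where $w(x)$ is the depletion width (`depletion_width()`). The flat-band
voltages of the two regions differ only through the particle layer
(`flat_band_voltages()`):

$$ V_{fb} = V_{ip} - \varphi_0, \qquad
   V_{fbNP} = V_{ip} - (\varphi_0 \pm \Delta\varphi), $$

with $V_{ip}$ the lumped particle-independent potential (reference
electrode, solvent dipole, semiconductor work function, fixed oxide
charge; `lumped_interface_voltage()`). The device capacitance is the
area-weighted parallel sum (`ceq_depletion()`):

$$ C_{eq}(V_G) = A\,n\,c(V_G - V_{ip} + \varphi_0 + \Delta\varphi)
              + A\,(1-n)\,c(V_G - V_{ip} + \varphi_0). $$

Two closed-form limits bound every curve: the accumulation plateau
$C_{acc} = \varepsilon_i A/d_i$ (the semiconductor contributes nothing)
and the high-frequency strong-inversion plateau
$C_{inv} = \varepsilon_s A/w_m$ with the maximum depletion width

$$ w_m = \sqrt{\frac{4\varepsilon_s k T \ln(N_a/n_i)}{q^2 N_a}}. $$

### Regime stitching

The depletion expression alone is not total: below flat band its argument
turns negative, and at large bias the depletion width would grow beyond
$w_m$. The package therefore clamps each sub-region's **per-area
capacitance** to the physical band $[\varepsilon_s/w_m,\; C_{i0}]$:
accumulation is the ceiling, strong inversion the floor. This choice was
genuinely open — the alternative of capping the *width* at $w_m$ and then
switching to the $\varepsilon_s/w_m$ floor produces a curve that dips
below the inversion plateau and jumps back up at the switch. Clamping the
capacitance instead keeps $C_{eq}(V_G)$ continuous and non-increasing and
makes both plateaus exact, at the cost of placing the inversion onset
slightly earlier (at $w = w_m - \varepsilon_s/C_{i0}$ rather than
$w = w_m$). All readouts used in practice sit well inside depletion, away
from either boundary. The accumulation-depletion corner is a hard clamp;
real devices round it off, and a cosine taper is available in
`plot(..., smooth_mV = )` for display only — no numeric readout uses it.

### ConCap readout

In constant-capacitance (ConCap) mode a feedback loop holds the device at
a working capacitance $C_{work}$ chosen on the bare device's depletion
branch; the applied gate voltage is the signal. The package solves

$$ n\,c(V + \varphi_0 + \Delta\varphi - V_{ip})
 + (1-n)\,c(V + \varphi_0 - V_{ip}) = \frac{C_{work}}{A} $$

for $V = V_{G\text{-}NP}$ (`solve_concap_voltage()`) and reports
$\Delta V_{G\text{-}NP} = V_{G\text{-}NP} - V_G$ against the closed-form
baseline (`baseline_gate_voltage()`). Because only the fraction $n$ of
the area is re-gated, $|\Delta V_{G\text{-}NP}| < |\Delta\varphi|$
strictly for $n<1$, with equality exactly at full coverage — partial
coverage *attenuates* the signal, which is the central quantitative point
of the model. At the canonical parameter set (below) and
$C_{work} = 30$ nF the signal runs from $-7.3$ mV at $n=0.25$ to
$-33.2$ mV at $n=0.9$ for $\Delta\varphi = +40$ mV.

## Numerical choices

* **Root finding.** The capacitance balance is strictly monotone in $V$
  within depletion, so a bracketed method cannot fail; `stats::uniroot`
  (Brent) is used with an absolute voltage tolerance of $10^{-10}$ V,
  four orders below any quantity reported in mV. The initial bracket is
  $V_G \pm (2|\Delta\varphi| + 0.5\ \mathrm{V})$ with at most five
  geometric expansions.
* **Domain guard.** $S(x)$ turns complex for
  $x < -q\varepsilon_s N_a/(2C_{i0}^2)$; the lower bracket end is clamped
  just inside that boundary, where the residual diverges to $+\infty$, so
  a sign change is guaranteed whenever a solution exists.
* **Regime guard.** The printed balance assumes both sub-regions
  depleted. If the solution violates that (one region accumulated or
  inverted), the condition is re-solved with the clamped capacitance and
  the result flagged `clamped = TRUE`, with the per-region regimes
  attached. This is not a corner case to ignore: with the canonical
  working point only ~60 mV above flat band, a negative $\Delta\varphi$
  of $-100$ mV drives the covered region into accumulation at low
  coverage.
* **Identifiability.** Once the covered region saturates, its
  capacitance no longer depends on $\Delta\varphi$ and the forward map
  $\Delta\varphi \mapsto \Delta V_{G\text{-}NP}$ is flat.
  `estimate_delta_phi()` — the model-based inverse — detects this and
  raises a non-identifiability error rather than returning a number from
  the flat branch. Where the covered region stays depleted, the inverse
  recovers $\Delta\varphi$ to well under 0.1 mV (verified by round-trip
  through the forward solver).
* **Interpolated readouts.** Curve shifts at constant capacitance and
  capacitance changes at constant voltage interpolate linearly between
  grid points; the default grid spacing of 1 mV keeps interpolation error
  far below 1 mV.
* **Degenerate inputs.** $n=0$ reduces exactly to the bare device
  regardless of $\Delta\varphi$; $n=1$ is accepted as the analytic
  single-region limit (rigid $-\Delta\varphi$ shift); $\Delta\varphi = 0$
  is coverage-invariant.

## Canonical parameter set

`si_sio2_device()` bundles the Al/p-Si/SiO~2~ structure used in all
examples and tests:

| parameter | value | meaning |
|---|---|---|
| $\varepsilon_{ir}$ | 3.9 | SiO~2~ relative permittivity |
| $d_i$ | 35 nm | oxide thickness |
| $\varepsilon_{sr}$ | 11.7 | Si relative permittivity |
| $N_a$ | $2.76\times10^{15}$ cm$^{-3}$ | acceptor density (5 Ω·cm wafer) |
| $n_i$ | $1.5\times10^{10}$ cm$^{-3}$ | intrinsic density at 300 K |
| $T$ | 300 K | temperature |
| $A$ | 0.5 cm$^2$ | contact area |
| $V_{ip}$ | 0 V | lumped offset (relative-shift convention) |
| $\varphi_0$ | $-10$ mV | bare-surface potential |
| $\varphi_{NP}$ | $+30$ mV | covered-surface potential ($\Delta\varphi = +40$ mV) |

Derived anchors: $C_{i0} = 9.866\times10^{-4}$ F/m², $w_m = 542.5$ nm,
$C_{acc} = 49.33$ nF, $C_{inv} = 9.55$ nF; the 30 nF working capacitance
corresponds to a baseline gate voltage of $+50$ mV. Physical constants
default to the three-digit teaching values ($q = 1.6\times10^{-19}$ C,
$k = 1.38\times10^{-23}$ J/K, $\varepsilon_0 = 8.854\times10^{-12}$ F/m)
and are overridable via `physical_constants()`; switching to full CODATA
values moves the derived anchors by less than 0.2%.

```{r}
dev <- si_sio2_device()
concap_sweep(c(0.25, 0.5, 0.75, 0.9), 30e-9, dev, delta_phi_mV = 40)
```

## The particle layer

$\Delta\varphi$ is normally supplied directly, because the local
double-layer capacitance $C_d$ in the charge relation
$\Delta\varphi = N_{NP} Q_{NP}/C_d$ (`delta_phi_from_charge()`) is rarely
known; the relation is provided for forward what-if studies, with
$Q_{NP}$ understood as the *effective* (counterion-screened) charge.
Coverage and density interconvert through the projected hard-disk formula
$n = N_{NP}\,\pi d^2/4$ using the mean core diameter. Note that SEM
image analyses that measure per-particle areas can report slightly
different coverages than the mean-diameter formula for the same density
(a few percentage points for a ±3 nm size spread); the formula is the
package's contract, and it is exactly invertible
(`density_from_coverage()`).

### Synthetic particle fields

`rsa_place_particles()` generates hard-disk configurations by random
sequential adsorption (RSA): uniform center proposals, rejected on
overlap or edge clipping, until the target count
$\mathrm{round}(n\,A_{patch}/(\pi d^2/4))$ is placed. Defaults emulate
the SEM patches of the incubation study the model was built around:
28 nm cores on a 1 µm × 1 µm patch at coverages 0.12, 0.22 and 0.36 for
increasing immobilization time. The generator warns at the 2-D RSA
jamming limit (0.547) and refuses targets above 0.5, where placement
time diverges. What the synthetic fields share with real adsorbed
layers: hard-core exclusion, spatial randomness, exact coverage
bookkeeping. What they deliberately omit: electrostatic inter-particle
repulsion beyond the hard core (real layers are more ordered),
polydispersity, aggregation, and edge-clipped particles — so passing
field tests validates the geometry pipeline, not adsorption physics.

## Problem sizes used in the test suite

The suite runs entirely from code-generated inputs: C-V grids of
1001–8001 points, 50 random device/layer draws for the solver-vs-scan
oracle (a $10^5$-point dense scan each), $10^3$ random points for the
closed-form-vs-series-composition identity, a 5 × 6 recovery grid for the
inverse, and RSA fields up to ~585 disks. Everything completes in a few
seconds on one core.

## Known limitations

* Only p-type substrates are implemented and tested; the sign machinery
  would generalize but is not exercised.
* High-frequency inversion only — no low-frequency inversion
  capacitance, no interface-trap dispersion, no quantum corrections.
* The area-weighted 1-D treatment ignores the discrete 2-D/3-D
  electrostatics of individual particles; it is the appropriate limit
  when particles are dense enough to tile the surface statistically yet
  sparse enough that local depletion regions do not overlap.
* $n_i$ is a fixed input; its temperature dependence and the
  resistivity-to-doping conversion (mobility model) are out of scope.
* ConCap time series are ideal plateaus — no adsorption kinetics, drift,
  or feedback-controller dynamics.
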