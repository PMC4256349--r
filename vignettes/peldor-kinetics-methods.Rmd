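---
title: "Models and methods: dipolar EPR distances and homolysis kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: dipolar EPR distances and homolysis kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peldorkin)
```

# The scientific problem

Adenosylcobalamin (AdoCbl) radical enzymes such as ornithine
4,5-aminomutase are thought to couple a large domain motion to homolysis
of the Co--C bond: a "resting" open conformation holds the cobalamin far
from the substrate-PLP site, and a "closed" conformation brings them
into van der Waals contact, generating the Co(II)-radical pair. Three
kinds of measurement probe this model, and this package implements the
computation behind each:

1. **Four-pulse PELDOR (DEER)** between nitroxide spin labels (and
   between a label and the Co(II) centre) yields nanometre distances
   that can discriminate open from closed geometries.
2. **Steady-state coupled-assay kinetics** (Michaelis--Menten
   \eqn{k_{cat}}, \eqn{K_m}) and **stopped-flow homolysis transients**
   (single-exponential \eqn{k_{obs}} at 528 nm) quantify how interface
   mutations perturb the conformational equilibrium.
3. **Distance mapping on structural models** decides which site pairs a
   given PELDOR acquisition can see at all, and whether a set of
   measured distances is consistent with the open or the closed model.

# The dipolar model

Two unpaired electrons at distance $r$ with the inter-spin vector at
angle $\theta$ to the field couple at

$$\nu_{DD} = \frac{\mu_0}{4\pi h}\, g_1 g_2 \mu_B^2\,
  \frac{1-3\cos^2\theta}{r^3},$$

which evaluates to $52.04\ \mathrm{MHz}\, (r/\mathrm{nm})^{-3}$ for two
free-spin electrons ($g_1=g_2=2.0023$). The constant is hard-coded from
CODATA 2018 values ($\mu_0/4\pi = 10^{-7}$, $\mu_B =
9.2740100783\times10^{-24}$ J/T, $h = 6.62607015\times10^{-34}$ J s).
`perpendicular_frequency()` is the $\theta = 90^\circ$ turning point,
the most intense feature of the powder (Pake) spectrum and the
frequency read off dipolar spectra in practice;
`distance_from_frequency()` is its exact inverse. Distances are held in
nm internally and reported as integer-rounded Angstrom, matching the
significant figures such distances are quoted with. Nitroxide labels
and organic radicals sit at $g \approx 2.00$, so the free-spin default
is appropriate; for the mixed Co(II)--nitroxide measurement the cobalt
g is not known precisely, so the same default is used (overridable),
and distances from that configuration are treated as approximate rather
than exact anchors.

For an orientationally disordered frozen sample the echo modulation is
the orientation average

$$K(r,t) = \int_0^{\pi/2}\cos\{2\pi\nu_{DD}(\theta)(t-\tau)\}\,
  \sin\theta\,d\theta,$$

computed by `powder_kernel()` with Gauss--Legendre quadrature in
$\cos\theta$, doubling the order from 64 until successive estimates
agree to $10^{-6}$ absolute everywhere (hard failure past order 16384;
the integrand is smooth, so convergence is immediate at the problem's
frequencies). `simulate_peldor()` embeds either this kernel or, with
`collapse_theta = TRUE`, the single-orientation model
$V(t)=\cos\{2\pi\nu_\perp(t-\tau)\}$ -- the form in which the
refocused-echo modulation is usually written down -- inside

$$V(t) = B(t)\,[(1-\lambda) + \lambda\textstyle\sum_i w_i K(r_i,t)]
  + \varepsilon(t).$$

**Parameter defaults.** Modulation depth $\lambda = 0.3$ (a typical
X-band value; deep enough that a 25%-weight component clears the
peak-picking threshold), flat background $B \equiv 1$ (the background
dimension of real intermolecular decays is sample-dependent and out of
scope), Gaussian noise expressed as a fraction of the modulation
amplitude $\lambda$. The default acquisition timing is the study
condition throughout: $\tau = 200$ ns, $T = 1100$ ns, 148 points in
8-ns steps (a 1.184 us evolution window), zero-filled to 1024 points.

# The processing chain and its one sharp edge

`analyze_peldor()` applies, in fixed order: polynomial baseline
subtraction, Hamming apodization, zero-filling, cosine Fourier
transform, peak picking, distance conversion.

* **Baseline** is *subtracted*, not divided: the additive cosine model
  above is what the transform assumes. The fit region defaults to the
  full trace (`fit_start_fraction` moves it tailward).
* **Apodization** uses a descending Hamming half-window
  ($w_0 = 1$, $w_{N-1} = 0.08$): the acquired signal starts at its echo
  maximum and must be driven smoothly to zero to avoid truncation
  sidelobes. A symmetric full window is available by flag.
* **Transform** is a direct cosine sum on the grid $\nu_j = j/(N\,dt)$
  with phase referenced to $t=\tau$; at the default settings the
  resolution is $1/(1024 \times 8\,\mathrm{ns}) = 0.122$ MHz. The
  signed spectrum is kept (and picked on) by default; a magnitude mode
  exists because published dipolar spectra are sometimes moduli.
* **Peak picking** takes local maxima above 20% of the spectrum
  maximum, at or above twice the resolution (keeping the zero-frequency
  lobe out), refines each by three-point parabolic interpolation, and
  sorts by descending amplitude.

The sharp edge: **a quadratic baseline annihilates sub-cycle
oscillations**. Least-squares subtraction is a linear projection, and
over a 1.184-us window a 0.5-MHz cosine (0.59 cycles) is almost
entirely representable by a quadratic. Removing it leaves only the
cubic-and-above remainder, whose apparent frequency is higher: in a
noise-free experiment on this chain, true components at 0.5, 0.6 and
0.7 MHz all emerge near 0.8 MHz (about 40 Angstrom) after order-2
correction. This is a deterministic property of the stated processing,
not a numerical defect. Consequently:

* the order-2 default is retained for *real* traces, whose curved
  intermolecular background genuinely needs it and whose sub-cycle
  components must then be read with caution (`analyze_peldor()` flags
  them `sub_cycle`);
* validation round trips on simulated flat-background traces use the
  *matched* correction, `baseline_order = 0` (mean removal) -- with it,
  simulate-then-analyze at 2% noise recovers 29/42/44/47-Angstrom
  components within one resolution bin's distance equivalent (about
  0.6, 2.4, 2.9 and 3.8 Angstrom respectively; the bound widens as
  $r/3\nu$ because of the cubic distance law).

With two components sharing the short window (weights 0.75/0.25 at
4.703/2.916 nm), mutual spectral leakage shifts the picked peaks by
1--2 Angstrom even without noise; the tests assert exactly that
documented envelope, not perfection.

# Kinetic fitting

`rate_from_slope()` performs the Beer--Lambert conversion
$v = (dA/dt)/(\epsilon\,\ell)$ (defaults $\epsilon = 6220$
M$^{-1}$cm$^{-1}$ at 340 nm, $\ell = 1$ cm) and normalises by the
catalytic-site concentration (default 100 nM) to turnover units.

`fit_mm()` fits $v = k_{cat} s/(K_m + s)$ by Levenberg--Marquardt with
deterministic starts ($k_{cat,0} = \max v$; $K_{m,0}$ at half-maximum
by interpolation), so identical data yield bit-identical parameters.
Efficiency $k_{cat}/K_m$ carries a first-order propagated error
including the parameter covariance -- the propagation method is a
package choice; it is standard and slightly conservative. With the
default single-measurement 10-point design (10--2250 uM) at 5%
multiplicative noise, the median absolute error of the fitted
$k_{cat}$ is about 2.2% -- a design limit, not a fitting flaw; the
standard duplicate-measurement design (each concentration twice) brings
it under 2% and $K_m$ under 8%, and that is the design the recovery
property test uses.

`fit_exponential()` fits $A(t) = a_0 + \Delta A\,e^{-k_{obs}t}$ after
discarding a 1-ms dead-time prefix (instrument mixing artefacts;
configurable). Initialisation is log-linear on the contiguous early
decay above 5% of the amplitude -- points below that are baseline noise
whose logarithm would corrupt the slope. Fits implying less than one
half-life inside the window are flagged low-confidence rather than
refused. Constant traces and non-monotone time axes are errors.

# Structure mapping

`read_sites()` takes label positions from PDB coordinates; the
cysteine SG atom is the default proxy for a nitroxide label position,
with an optional outward offset along CA-to-SG since the nitroxide
midpoint sits several Angstrom beyond the thiol. `is_measurable()`
deems a pair measurable when its perpendicular frequency completes at
least 0.4 of a cycle in the evolution window and stays below Nyquist;
0.4 is calibrated so that 49 and 29 Angstrom pairs are measurable at
the 148-by-8-ns acquisition while the > 60 Angstrom cross-dimer pairs
are not. `reconcile()` performs greedy one-to-one nearest-distance
matching within a 5-Angstrom default tolerance, ties broken by smaller
gap then lexical site names (stable under reordering) -- and it is
*kind-aware*: an assignment measured between a cobalt centre and a
nitroxide can only be explained by a prediction connecting sites of
those kinds. This matters: a 31-Angstrom cobalt--label distance falls
numerically within tolerance of a 29-Angstrom label--label pair, yet is
physically incommensurable with it; kind-aware matching is what lets
the open model reject the cobalt-distance set wholesale while the
closed model explains all three of its members.

The packaged dimer fixtures are *synthetic embeddings* of the model
distances (49/29 and > 60 open; 19/17/31 closed, the 17/19 pair kept as
two cobalt positions reflecting reported heterogeneity), written at PDB
precision (0.001 Angstrom) so files round-trip bit-identically. They
are not crystallographic coordinates, and nothing in the tests requires
downloading any structure.

# What the generators do and do not emulate

The simulators reproduce: acquisition timing and zero-fill geometry,
multi-component powder or single-orientation modulation, modulation
depth, smooth exponential background, additive white Gaussian noise,
multiplicative rate noise, and exponential transients with offsets.
They do **not** emulate orientation selection by finite pulse
bandwidth, exchange coupling, g-anisotropy, electron-spin relaxation,
heteroscedastic detector noise, or multi-step homolysis kinetics.
Passing round trips therefore validate the processing chain under its
own signal model; they do not certify accuracy on real traces whose
physics includes the excluded effects.

# Problem sizes

The test-suite and acceptance computations use: 20 seeded replicates
per distance for PELDOR round trips (148-point traces, 1024-point
transforms); 100 datasets for Michaelis--Menten recovery; 50 traces of
5000 points for stopped-flow recovery; brute-force kernel oracles on
2e5-point orientation grids. These sizes give stable medians while
keeping the whole suite in the tens of seconds on a single CPU.

# Known limitations

* Sub-cycle dipolar components (longer than about 45 Angstrom at this
  window) are resolution- and baseline-limited; serious work at such
  distances needs longer evolution windows or model-based inversion
  (Tikhonov distance distributions are deliberately out of scope).
* The point-dipole model ignores spin delocalisation; at the 6--7
  Angstrom contact distances of the coupled regime it is qualitative
  only, which is why `classify_regime()` reports a category, not a
  distance refinement.
* The cobalt partner's g-value is taken as free-spin unless overridden;
  cobalt--label distances converted under that default inherit its
  bias.
* Greedy reconciliation is not globally optimal assignment; with the
  small prediction sets of a labelled dimer this cannot matter, but a
  dense prediction set would warrant Hungarian matching.
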