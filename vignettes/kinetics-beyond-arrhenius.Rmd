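---
title: "Methods: rate-constant phenomenology beyond the Arrhenius law"
author: "ratekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rate-constant phenomenology beyond the Arrhenius law}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratekin)
```

## The problem

Many thermally activated processes — combustion steps, atmospheric and
astrochemical reactions, enzymatic catalysis, relaxation in supercooled
liquids — show curved Arrhenius plots: the local slope

$$E_a(\beta) \;=\; -\frac{d\,\ln k}{d\beta}, \qquad \beta = \frac{1}{RT},$$

is temperature dependent. Concave curvature (*sub*-Arrhenius) is the
signature of quantum tunneling through the barrier; convex curvature
(*super*-Arrhenius) of transport- or collectivity-limited kinetics; a
negative $E_a$ (*anti*-Arrhenius) of stereodynamic constraints. The
reciprocal of the apparent activation energy,

$$\gamma(\beta) = \frac{1}{E_a(\beta)},$$

is the *transitivity* function. Plotted against $\beta$, it approximately
linearizes deformed-Arrhenius behaviour, which makes it a useful scaling
plane both for diagnosing curvature and for fitting. This package
implements that toolbox end to end: closed-form rate laws and their
transitivity representations, numerical transitivity plots from tabulated
data, stochastic fitting, gas-phase transition-state-theory (TST)
prediction with tunneling corrections, and solvent-corrected rates.

### Unit conventions

All molar energies are in cal/mol and $\beta = 1/(RT)$ with
$R = 1.98720\ \mathrm{cal\,mol^{-1}K^{-1}}$, so published parameter tables
quoted in cal/mol work verbatim; `kin_constants()` is the single source of
constants (CODATA), including conversions for J/mol, hartree and
wavenumbers. Pre-exponential factors are carried opaquely in whatever
units the source data use.

## The five rate laws

| law | $k(T)$ | parameters |
|---|---|---|
| `arrhenius` | $A e^{-E_a \beta}$ | $A$, $E_a$ |
| `am` (Aquilanti–Mundim) | $A(1 - d\,\varepsilon^{\ddagger}\beta)^{1/d}$ | $A$, $\varepsilon^{\ddagger}$, $d$ |
| `ascc` | $A\bigl(1 - d\,\varepsilon^{\ddagger}/(RT + E_\nu)\bigr)^{1/d}$, $d = -\tfrac13 (E_\nu/2\varepsilon^{\ddagger})^2$ | $A$, $\varepsilon^{\ddagger}$, $E_\nu$ |
| `nts` | $A \exp\bigl(-E_0 / (R\sqrt{T^2+T_0^2})\bigr)$ | $A$, $E_0$, $T_0$ |
| `vft` | $A \exp\bigl(B/(T-T_0)\bigr)$ | $A$, $B$, $T_0$ |

The deformed exponential $(1-dx)^{1/d}$ is the common kernel: it reduces
to $e^{-x}$ as $d \to 0$ (implemented with a continuous switch at
$|d| < 10^{-12}$), bends the Arrhenius plot concave for $d<0$ and convex
for $d>0$, and makes $\gamma(\beta) = 1/\varepsilon^{\ddagger} - d\beta$
exactly affine for the AM law. The ASCC deformation is never a free
parameter — it is always derived from $(\varepsilon^{\ddagger}, E_\nu)$,
so ASCC is a three-parameter law. The VFT coefficient $B$ may be negative
(then $E_a = -BRT^2/(T-T_0)^2 > 0$, the super-Arrhenius case).
`apparent_ea()` implements the analytic $-d\ln k/d\beta$ for every law and
is cross-checked in the test suite against a centered finite difference.

Outside a law's support (deformed-exponential base $\le 0$, or $T \le T_0$
for VFT) evaluation raises a domain error rather than returning 0 or NaN:
silent zeros would corrupt fits, whereas an infinite objective is handled
cleanly by the optimizer.

## Numerical transitivity

`numerical_transitivity()` differentiates $\ln k$ with respect to $\beta$
(not $T$ — the apparent activation energy is defined as a
$\beta$-derivative) on the exact point set, using the three-point
unequal-spacing Lagrange stencil at interior points and one-sided
three-point stencils at the two ends. Endpoint estimates are first-order
accurate only and are flagged in the output (`endpoint`), and downstream
fitting in the transitivity plane ignores them. Duplicate temperatures are
averaged in $\ln k$ first (derivative stencils need distinct abscissae);
points where $E_a = 0$ yield `NA` transitivity and a `singular` flag
rather than an error.

Optional Savitzky–Golay smoothing (delegated to `signal::sgolayfilt`,
which reproduces polynomials up to the filter order exactly, ends
included) is applied to $\ln k$ *before* differencing, because
differentiating raw noisy $k$ amplifies noise multiplicatively. The
default window 7 / order 2 is a deliberate mild setting for 20–60-point
kinetic tables; both are user-settable, and the window must stay odd,
larger than the order and no longer than the series.

On exact data the stencil error scales with the square of the
$\beta$-spacing; a 30-point grid spanning a factor-5 temperature range
reproduces the closed-form AM transitivity to about 0.2% at interior
points, comfortably inside the 0.5% envelope the self-tests enforce.

## Chi-square and the fitting planes

The fit objective is the mean squared residual in a chosen space;
the default is $\log_{10}$:

$$\chi^2 = \frac{1}{n}\sum_i \bigl(\log_{10} k_i^{\mathrm{obs}} -
\log_{10} k_i^{\mathrm{model}}\bigr)^2 .$$

Rate constants in one data set routinely span many decades, so a
logarithmic (or relative) space is the only scale-honest choice; `ln`,
`linear` and `relative` are available as options. Published $\chi^2$
values from other programs are generally not comparable across
conventions, and this package makes no attempt to reproduce any particular
one.

Two fitting planes are provided. In the **Arrhenius plane** all five laws
are fit to $k(T)$ directly. In the **transitivity plane** the numerical
$\gamma(\beta)$ series (interior points only) is fit against the law's
closed-form $\gamma$; because $\gamma$ is independent of $A$, the
pre-exponential factor is recovered afterwards by zeroing the mean
$\ln k$ residual. Only laws with tractable closed-form transitivity whose
curvature the plane actually linearizes — `arrhenius`, `am`, `vft` — are
allowed there.

## The annealer

`gsa_minimize()` is a Tsallis-statistics generalized simulated annealer
over a bounded box:

* **Schedule.** $T_{q_v}(t) = T_{q_v}(1)\,
  \dfrac{2^{q_v-1}-1}{(1+t)^{q_v-1}-1}$, with default visiting index
  $q_v = 2.62$ and initial temperature $100\times$ the starting objective
  (the objective sets the energy scale of the acceptance rule).
* **Visiting moves.** Per-coordinate draws from the one-dimensional
  Tsallis visiting distribution — a $q$-Gaussian, sampled exactly as a
  scaled Student-$t$ with $\nu = (3-q_v)/(q_v-1)$ degrees of freedom, so
  the step law is reproduced without approximation. The step width is the
  box width cooled by $(T_{q_v}(t)/T_{q_v}(1))^{1/(q_v-1)}$; the heavy
  $t$-tail keeps rare long jumps alive at low temperature. Proposals are
  folded back into the box by triangle-wave reflection, which is exact for
  arbitrarily long jumps.
* **Acceptance.** Generalized Metropolis with index $q_a = -5$:
  uphill moves pass with probability
  $[1 + (q_a-1)\Delta E/T_a(t)]^{1/(1-q_a)}$ (zero when the bracket is
  non-positive), $T_a(t) = T_{q_v}(t)/t$.
* **Determinism.** One integer seed drives the whole run; the session RNG
  state is saved and restored. Ties keep the earlier point, so the
  best-so-far trace is non-increasing and a repeated seed is
  bitwise-reproducible.

`fit_rate_data()` follows the annealer with a bounded Nelder–Mead polish
(two restarts, accepted only if it improves): the annealer locates the
basin, the simplex sharpens the optimum to well below the 1% recovery
tolerance the self-tests demand. Non-finite objective values — support
violations during the search included — are treated as $+\infty$.

Search bounds default to generous windows around an Arrhenius line fit
through the data ($\log_{10} A \pm 8$, energy scales several times the
local slope, $|d| \le 3$, $T_0$ capped below the data range for VFT).
Laws with more than two free parameters can have multiple $\chi^2$ minima
on noise-free data of limited span; for those (`ascc`, `nts`, `vft`) the
supported workflow is to pass a `guess`, which recentres the box — the
package then reports the best-$\chi^2$ solution and the seed, nothing
more.

## Gas-phase TST

`partition_functions()` uses the rigid-rotor / harmonic-oscillator /
ideal-gas factorization: $q_{\mathrm{trans}}/V = (2\pi m k_B T/h^2)^{3/2}$
(in m$^{-3}$), $q_{\mathrm{rot}} = T/(\sigma\theta_r)$ for linear rotors
and $(\sqrt{\pi}/\sigma)\sqrt{T^3/\theta_A\theta_B\theta_C}$ for
nonlinear tops, and the ZPE-referenced
$q_{\mathrm{vib}} = \prod_i (1-e^{-\theta_i/T})^{-1} \ge 1$, so zero-point
energy lives in the barrier, not in $q_{\mathrm{vib}}$. Symmetry numbers
and electronic degeneracies are explicit `species()` fields defaulting to
1 and are never inferred from geometry — silent symmetry inference is a
classic source of factor-of-two errors.

`tst_rate()` evaluates
$k = (k_BT/h)\,(Q^{\ddagger}/\prod Q_i)\,e^{-\varepsilon^{\ddagger}/k_BT}$
with the barrier defined as the TS electronic energy minus reactant
energies, ZPE-corrected by default (a flag disables it); higher-level
single-point energies can be substituted per species via
`energy_override`, replacing electronic energies only. Unimolecular rates
are s$^{-1}$; bimolecular rates are computed per molecule
(cm$^3$ molecule$^{-1}$ s$^{-1}$) with a molar option ($\times N_A$).

`dtst_rate()` replaces the barrier exponential by the deformed
exponential with
$d = -\tfrac13\bigl(h\nu^{\ddagger}/2\varepsilon^{\ddagger}\bigr)^2$,
which folds moderate tunneling into the rate expression itself; it
collapses onto TST as $\nu^{\ddagger} \to 0$ and produces concave
(sub-Arrhenius) plots for $d < 0$, both asserted in the tests.

## Tunneling corrections and their poles

Where the parabolic-barrier literature mixes $\hbar\nu^{\ddagger}$ and
$h\nu^{\ddagger}$, this package takes $\hbar\nu^{\ddagger} =
h\nu^{\ddagger}/2\pi$ literally everywhere, which reproduces the standard
Skodje–Truhlar $\alpha = 2\pi/h\nu^{\ddagger}$ convention. With
$b = 1/RT$, $a = 1/\hbar\nu^{\ddagger}$ (molar energies):

* **Bell 1935**: $\kappa = \bigl(a - b\,e^{\varepsilon^{\ddagger}(b-a)}\bigr)/(a-b)$,
  with the removable point $b=a$ evaluated by its limit
  $1 + a\varepsilon^{\ddagger}$. Its high-temperature tail decays only
  like $h\nu^{\ddagger}/(2\pi k_BT)$ — slower than the Bell-1958 family.
* **Bell 1958, leading term**: $\kappa = \frac{u/2}{\sin(u/2)}$ with
  $u = h\nu^{\ddagger}/k_BT$. The quotient has its pole at $u/2 = \pi$,
  i.e. at **half** the crossover temperature
  $T_c = h\nu^{\ddagger}/\pi k_B$; the module documents and guards the
  pole it actually computes, refusing evaluation within
  $|u/2 - \pi| < 10^{-3}$ and anywhere beyond it (where the sinc is
  negative), naming $T_c$ in the error.
* **Bell 1958, two terms**: the same sinc plus
  $-e^{\varepsilon^{\ddagger}(b-a)}\, b/(a-b)$, smooth enough to bridge
  negligible-to-moderate tunneling.
* **Skodje–Truhlar**: piecewise at $\beta = \mathbb{c} = \pi/h\nu^{\ddagger}
  = 1/k_BT_c$. The high-temperature branch is the two-term form with
  $\varepsilon^{\ddagger}$ replaced by $\varepsilon^{\ddagger}-\Delta H$
  (its sinc argument never exceeds $\pi/2$ there, so it is pole-free);
  the deep branch is the standard
  $\kappa = \frac{\beta}{\beta-\alpha}\bigl(e^{(\beta-\alpha)
  (\varepsilon^{\ddagger}-\Delta H)}-1\bigr)$, positive on its whole
  range and continuous through $\beta = \alpha$ (evaluated by `expm1`
  with a series guard). The two branches do not meet exactly at
  $\beta = \mathbb{c}$; the finite mismatch there is a property of the
  piecewise construction and is measured, not hidden, by the test suite.
  $\Delta H$ is required (0 is allowed) and may come from the declared
  system enthalpy or from the species energies.

The crossover temperature $T_c = c_2\tilde\nu^{\ddagger}/\pi$ also drives
the regime classifier: negligible ($T > 2T_c$), small
($T_c < T \le 2T_c$), moderate ($T_c/2 < T \le T_c$), deep
($T \le T_c/2$) — the four windows partition the axis exactly, with deep
read as $T \le T_c/2$ (the only reading consistent with the ordering).

## Solution kinetics

The solvent viscosity follows a deformed-exponential law; the built-in
water default is
$\eta(T) = 2.7024\times10^{-4}\,\mathrm{Poise}\,(1-213.0543/T)^{-2.75634}$,
giving $8.56\times10^{-3}$ Poise at 298.15 K against the handbook
$\approx 8.9\times10^{-3}$. Below $T^* = 213$ K the law is undefined and a
domain error is raised. Other solvents are supplied as
$\eta_0(1 - d\,\varepsilon/R T)^{1/d}$ with $\varepsilon$ in J/mol.

**Collins–Kimball** (`collins_kimball_rate`, bimolecular): cage radii from
molar volumes, $r_i = (3V_i/4\pi N_A)^{1/3}$; Stokes–Einstein diffusion in
cgs, $D_i = k_BT/6\pi\eta r_i$; Smoluchowski limit
$k_{\rightarrow D} = 4\pi r_{AB} D_{AB} N_A$ with $r_{AB} = r_A + r_B$ and
$D_{AB} = D_A + D_B$; and the harmonic combination
$1/k_{\mathrm{obs}} = 1/k_{\mathrm{TST}} + 1/k_{\rightarrow D}$, which
guarantees $k_{\mathrm{obs}} \le \min(k_{\mathrm{TST}},
k_{\rightarrow D})$. The reverse-diffusion step drops out in the
infinite-reaction-rate limit, so only the harmonic form is implemented.
The activated rate may come from TST, d-TST or any $\kappa$-corrected
rate — caller's choice.

**Kramers** (`kramers_rate`, unimolecular or pseudo-unimolecular):
$\kappa_{\mathrm{Kr}} = \bigl(\sqrt{\mu^2/4+\omega^{\ddagger 2}} -
\mu/2\bigr)/\omega^{\ddagger}$ with
$\omega^{\ddagger} = 2\pi c\tilde\nu^{\ddagger}$. The friction constant is
dimensionally the Stokes drag over the per-molecule mass,
$\mu = 6\pi r_{AB}\eta/(M/N_A)$ in s$^{-1}$ (cgs throughout) — the only
reading that gives $\mu$ the units the transmission factor requires; the
cage radius here is the transition state's own Stokes radius, whereas
Collins–Kimball uses the sum of the two reactant radii, since the two
formulations give the radius different physical roles.
$\kappa_{\mathrm{Kr}}$ is strictly decreasing in friction, lives in
$(0,1]$, equals 1 at $\mu = 0$ and decays as
$\omega^{\ddagger}/\mu$ at high friction.

## What the synthetic data do and do not show

`synth_rate_series()` generates exact law evaluations, optionally with
multiplicative lognormal noise (positive rates; consistent with the
log-space objective) from a seeded generator that leaves the session RNG
untouched. `benchmark_params()` bundles published fitted parameters for
four prototype processes — keto–enol tautomerization (sub-Arrhenius, deep
tunneling; 100–300 K), OH + H$_2$ (sub-Arrhenius, moderate tunneling;
200–1000 K), an enzymatic hydride transfer (super-Arrhenius; 278–338 K,
the 5–65 °C assay window), and OH + HBr (anti-Arrhenius; 120–360 K) — with
temperature windows fixed once to the ranges in which those processes were
characterized. `synth_reaction_system()` fabricates small
(2–4 atom) gas-phase systems whose partition functions can be audited by
hand, including a deep-tunneling template whose crossover temperature
exceeds 600 K; `synth_qc_log()` fabricates the minimal frequency-log
dialect the extractor reads, and is labelled synthetic throughout.

Passing the self-tests therefore demonstrates that the algebra, the
differentiation, the optimizer and the unit plumbing are right — that
noise-free data generated by a law are mapped back onto that law's
parameters to better than 1%, at 30 points per series and $10^4$ annealing
iterations per fit (sizes chosen to keep a full self-check run in tens of
seconds). It does **not** demonstrate anything about real measurements:
experimental error is rarely lognormal-independent, temperature coverage
is rarely dense or balanced, and multi-parameter laws genuinely admit
multiple solutions on narrow windows, where prior knowledge must pick the
physical one. The quantum-chemistry-log extractor is a fixture-tested
convenience; the YAML species spec is the supported input path.

## Known limitations

* No Eckart or variational-TST corrections; no hindered-rotor or
  anharmonic treatments; no pressure dependence.
* No uncertainty quantification on fitted parameters — the fit reports the
  optimum, its $\chi^2$, and the seed.
* The Bell-1958 leading term is refused at and beyond its pole rather than
  analytically continued; use the two-term, Skodje–Truhlar or d-TST
  routes near and below $T_c/2$.
* Electrostatic (Debye) corrections to diffusion-limited rates and
  time-dependent friction are out of scope.
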