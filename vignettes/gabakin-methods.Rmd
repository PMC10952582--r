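---
title: "Kinetic modelling of neurosteroid inhibition of GABA-A receptors: methods and design"
author: "gabakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic modelling of neurosteroid inhibition of GABA-A receptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabakin)
```

## The model

`gabakin` treats a GABA-A receptor population as a continuous-time Markov
chain over a small set of conformational states. The agonist-only scheme has
a resting state R, a GABA-bound closed composite RA (standing in for one or
more closed/preactivated conformations), the open state RA\* — the only
conducting state — and a desensitised state RD entered from the open state.
Sulfated-neurosteroid inhibition is modelled by analogue-bound states grafted
onto this backbone: binding to the GABA-bound closed state (RAP) with an
optional deep blocked state (RAPd), binding to the desensitised state (RDP),
or binding to an explicit preactivated (flip) state (RfAP). Four such
topologies ship with the package (`paperModelIds()`), each with the
rate-constant set obtained by waveform fitting of experimental currents;
`listPaperRates()` tabulates them.

Macroscopic currents are deterministic: with occupancy row vector $p(t)$ and
generator $Q(A, P)$ (off-diagonal $q_{ij}$ = rate constant of edge $i \to j$,
association edges multiplied by the GABA concentration $A$ or analogue
concentration $P$; diagonal = minus row sums), the master equation is
$\dot p = p\,Q$, and the current is the summed occupancy of the conducting
states, reported as a positive magnitude. No conductance or driving-force
model is applied: every downstream readout is a ratio of currents, so the
absolute scale cancels (the holding potential is metadata only).

Two deliberate simplifications are carried over from the published schemes
rather than "fixed": GABA binding is a single first-order step (real
receptors bind two GABA molecules cooperatively), and microscopic
reversibility is not enforced — the printed rate sets are used exactly as
given, even where loops are absent so balance cannot be checked.

### Numerical propagation

The rate constants span ten orders of magnitude (9.0e-2 to 9.2e5 s^-1, with
association terms around 1e4 s^-1 at 30 uM), which makes the master equation
stiff. Because protocols are piecewise-constant in concentration, the
propagator over one output step is the matrix exponential
$e^{Q\,\Delta t}$, computed once per epoch (`Matrix::expm`, scaling and
squaring) and applied repeatedly. This is exact for the linear system — no
step-size tuning, no stability constraint. A classical explicit RK4
integrator exists only in the test suite as an independent oracle; the two
agree to better than 1e-6 absolute occupancy on fine-step segments, and
trajectories conserve probability to 1e-9 at every sample.

Stationary distributions solve $pQ = 0$, $\sum p = 1$ by a bordered linear
solve with an SVD null-space fallback. At zero analogue the analogue-bound
states are unreachable and the chain is reducible; `steadyState()` then
restricts the solve to the component reachable from the resting state,
assigns the excluded states zero occupancy and warns. Residuals
$\lVert pQ \rVert_\infty$ are below 1e-10.

Occupancies emerging from finite-precision exponentials are clamped at zero
(tolerance 1e-9, anything more negative is an error) and renormalised each
step.

## The virtual rig

The default application protocol reproduces the recording design: 2 s
baseline, 10 s analogue pre-application (the experiments used 10-12 s), 20 s
GABA + analogue co-application at 30 uM GABA (approximately EC90 for this
receptor isoform), 5 s washout. Solution exchange is treated as
instantaneous: Y-tube exchange takes tens of milliseconds while the decay
phenomena of interest run over seconds. An optional exponential exchange
time constant is available (`concentrationProtocol(exchangeTau = )`,
implemented as a concentration staircase at the output resolution) and
defaults to 0.

Measurements follow the experimental conventions: the peak is the maximum
current over the co-application window; the steady state is the mean over
the final 200 ms of co-application — the published readout is a point sample
"after 20 s", and a short settled-trace average is identical to it while
being robust to sampling noise; percent desensitisation is
$100\,(1 - \mathrm{steady}/\mathrm{peak})$. A zero peak makes the quantity
undefined and is flagged, never silently returned. Inhibition readouts
compare a test trace against an analogue-free control simulated under an
identical protocol, separately at the peak and steady state; for the
packaged closed-state-block scheme the steady-state inhibition strictly
exceeds peak inhibition across 0.1-100 uM analogue, the defining signature
of this pharmacology.

The default output grid is 1 ms. The experimental digitisation (50 kHz) is
irrelevant at the 2-7 s decay scale; activation equilibrates within a few
samples even at 1 ms and every readout is insensitive to the grid well below
this value. Analysis-heavy tests and the dose-response pipeline use 10-20 ms
grids for speed; results agree with the 1 ms grid to the tolerances tested.

## Curve analysis

Decay fits use $A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + C$ over a window
from the co-application peak to the end of co-application. The plateau term
$C$ is included because these currents do not decay to zero, but the
weighted time constant deliberately excludes it:
$\tau_w = (A_1\tau_1 + A_2\tau_2)/(A_1 + A_2)$. Optimisation is
Levenberg-Marquardt (`minpack.lm::nls.lm`) with time constants in log space
and non-negative amplitudes; the low-level optimiser is used directly
because the high-level `nls`-object wrapper fails on the (near-)perfect fits
that arise with noise-free synthetic inputs. Single-exponential inputs
collapse the two components; the fit then falls back to a single exponential
and reports $\tau_1 = \tau_2 = \tau_w$. Non-decaying traces are flagged
degenerate rather than fitted.

Concentration-inhibition fits use
$I/I_{max} = 1 - B^n/(IC_{50}^n + B^n)$, fitted in log-concentration space
with $pIC_{50}$ and the slope $n$ free. $n$ is bounded to $[0.3, 5]$ —
no per-compound slope is published, and the bound keeps noise-free
single-site data identifiable without constraining any plausible estimate.
Standard errors come from the Gauss-Newton covariance at the optimum.

The decay-effect dose-response uses the fractional tau-w remaining,
$\tau_w(P)/\tau_w(0)$, as the response variable. The transform behind the
published "decay inhibition" potencies is not defined in the source, so the
package fixes this convention explicitly and uses it consistently in both
the generator and the fitter; decay potencies are therefore comparable
within the package but only qualitatively against the published column.

The proxy regression (desensitisation extent vs decay speed) is ordinary
least squares with $R^2$ equal to the squared Pearson correlation.

## Waveform fitting

Rate constants are estimated by simulating the full protocol for each
candidate rate set and minimising the sum of squared residuals between the
simulated and target currents over the co-application window. The published
workflow names neither objective nor algorithm ("waveform fitting", 50
iterations), so the package adopts: free parameters in log10 space, box
bounds (default 1e-4 to 1e10 in natural units), L-BFGS-B with a default
budget of 50 iterations honoured as a budget, not a convergence claim.
The simulated current is peak-normalized and the target matched with its
least-squares-optimal scale factor; this removes absolute scale as a
nuisance parameter without the upward bias that peak-normalizing a noisy
target by its sample maximum would introduce (with 2 %-of-peak noise that
bias alone can push recovered rates tens of percent off). Candidates whose
simulation fails are penalised rather than fatal; fixed rates are returned
bit-identical; the reported objective never exceeds the seed objective.
`compareHypotheses()` fits competing scheme/binding-site specifications to
one target and ranks them by final objective — on self-generated targets the
generating topology wins.

One structural identifiability caveat is inherited from the schemes
themselves: binding to the composite closed state and binding to an explicit
preactivated state produce currents too similar to distinguish, so the
packaged "c" and "d" topologies are alternatives, not competitors, and the
legend-order ambiguity of the k2/k4 association pairs in those models is
exposed as an explicit `assignment` argument (`"standard"` mirrors the
deep-block model: k2/k-2 on the closed/preactivated site; `"swapped"`
exchanges the pairs) recorded in the rate-set provenance.

## Synthetic data

The generators stand in for the original recordings, which are not publicly
deposited. `genTrace()` adds seeded additive Gaussian noise (SD as a
fraction of peak) to the deterministic current; `genDoseResponse()` draws
mean-one lognormal multiplicative noise around the Hill curve. Both are pure
functions of their arguments and the seed. What is *not* emulated: the 5 kHz
Bessel filter, digitisation artefacts, series-resistance error, rundown and
seal drift. Passing tests therefore demonstrate correctness of the
machinery on idealised currents with stationary Gaussian noise, not
robustness to every artefact of real recordings.

`calibratePhenotype()` produces rate sets whose simulated currents match the
published wild-type and desensitisation-mutant phenotypes (68/39/89 %
desensitisation; tau-w 3.7/7.4/2.3 s) under the conditions those values were
measured: 1 mM GABA for 20 s. Only the desensitisation-gate rates delta1 and
delta-1 are adjusted, echoing the structural interpretation of the mutants
as gate variants; the presets are phenomenological targets, not mechanistic
claims about the mutants' true rate changes. Because extent and speed are
two targets, a single scale factor cannot hit both (scaling delta1 alone
hits 39 % with tau-w near 6.6 s, not 7.4 s); calibration therefore
alternates two log-space bisections — the delta1/delta-1 ratio controls the
desensitisation extent, their common magnitude the decay speed — which
converges in a few rounds because the two effects are nearly separable. The
brackets stay below the regime where desensitisation outruns activation (no
peak forms and the readout collapses). The three calibrated phenotypes,
pushed back through `measure()`, `fitDecay()` and `linReg()`, reproduce the
strongly negative desensitisation/decay-speed relationship ($R^2 > 0.9$).

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `dtOut` | 1e-3 (simulate), 1e-2 (analysis pipelines) | s | far below every readout's sensitivity scale |
| co-application GABA | 30e-6 | M | approximately EC90 for the isoform |
| pre-application | 10 | s | experimental 10-12 s |
| steady window | 0.2 | s | settled-trace average of the "after 20 s" point readout |
| Hill slope bounds | [0.3, 5] | — | no published per-compound slope |
| waveform-fit bounds | [1e-4, 1e10] | s^-1 or M^-1 s^-1 | generous box around all published values |
| iteration budget | 50 | — | published fitting budget, honoured as a budget |
| calibration protocol | 1 mM GABA, 20 s | — | the conditions of the phenotype measurements |

## Degenerate inputs and tie-breaks

Non-decaying traces: flagged, not fitted. Zero peak: desensitisation
undefined, flagged. Collapsed biexponentials: single-exponential fallback
with $\tau_w = \tau$, preferred when its residual is no worse. Flat
dose-response curves (e.g. an analogue-free scheme): Hill fit rejected with
a warning, table still returned. Reducible chains: solve restricted to the
reachable component, excluded states reported. Decay-fit components are
reported fast-first ($\tau_1 \le \tau_2$).

## Problem sizes used in the shipped tests

Simulations in the test-suite and acceptance workflows use 10-20 ms output
grids over the 37 s default protocol, 6-7 point concentration grids, 10
noise seeds for the stochastic waveform-recovery property and 50 seeds for
the dose-response unbiasedness check. These sizes were chosen as the
smallest at which every tested tolerance is comfortably met on idealised
data; all are arguments, not constants, so larger studies only cost time.

## Known limitations

* Binding is first-order per ligand; agonist cooperativity, voltage
  dependence and single-channel (stochastic) behaviour are out of scope.
* The published experimental potencies (IC50 tables) and mutant results are
  summaries of recordings that are not deposited; they enter the package as
  generator parameters and fixtures, and only their round-trip recovery is
  testable from first principles.
* Decay-potency values depend on the package's explicit fractional-tau-w
  convention (above).
* Waveform-fit equivalence to the original fitting software is functional,
  not numerical: that program's objective and weighting are undocumented.
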