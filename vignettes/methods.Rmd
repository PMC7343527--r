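---
title: "Coupled neural mass models and spectral model inversion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled neural mass models and spectral model inversion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdcm)
```

# The generative model

## Population dynamics

Every source in a `gdcm` network is a neural mass model in second-order
convolution form. A population's mean membrane potential $v$ responds to
presynaptic firing through the synaptic kernel
$h(t) = (t/T)\,e^{-t/T}$, equivalently

$$\ddot v_j \;=\; \Big(\textstyle\sum_l \gamma_l\,S(v_l) \;+\; A\,S(v_m)
\;+\; I(t) \;-\; 2\dot v_j \;-\; v_j/T_j\Big)\big/\,T_j ,$$

where $T_j$ (ms) is the population's membrane time constant, $\gamma_l$
are signed intrinsic coupling strengths (positive glutamatergic, negative
GABAergic), $A$ are excitatory extrinsic strengths, and $I(t)$ is
endogenous input. The firing-rate function is the baseline-subtracted
sigmoid $S(v) = 1/(1+e^{-Rv}) - 1/2$ with one slope $R$ per source.
Subtracting the baseline rate makes $v = 0$ an exact fixed point of the
assembled network, so the linearization point needs no numerical search
(a constant exogenous drive is supported and then triggers a Newton solve
for the shifted fixed point; the shipped analyses leave it at zero, where
it only relocates the operating point).

Two models ship with the package:

* **MMC** — a four-population motor-cortex microcircuit (middle-layer,
  superficial and deep pyramidal cells, and one inhibitory interneuron
  pool) with 14 intrinsic connections, including self-inhibition of all
  four populations.
* **BGT** — a five-structure basal-ganglia/thalamus model (striatum, GPe,
  STN, GPi, thalamus) with 9 intrinsic connections covering the direct
  (Str–GPi–Tha) and indirect (Str–GPe–STN–GPi–Tha) pathways, the
  STN→GPe feedback, and inhibitory self-connections of striatum and both
  pallidal segments.

**Index convention.** Figures that depict such circuits number their
arrows, but no prose enumeration exists, so the mapping from connection
indices to arrows is frozen here as a documented *convention* (see
`model_spec("MMC")$connections`). The convention is anchored to known
anatomy: the two strongest cortical priors land on the dominant layer
4→2/3 and layer 2/3→5 pathways, and index 6 is the deep-pyramidal →
interneuron connection. The same applies to the four extrinsic
connections, ordered thalamus→MP, thalamus→DP, corticostriatal,
hyperdirect — an ordering under which the corticostriatal prior (672)
exceeds the hyperdirect one (127), as expected.

## Coupling, delays, and observation

Extrinsic input uses the *presynaptic* source's own sigmoid slope —
firing-rate semantics stay local to the emitting source — and enters the
postsynaptic acceleration exactly like intrinsic drive (divided by the
target's $T$). Conduction delays are specified per source pair: priors of
1 ms within cortex, 4 ms within the basal ganglia, 8 ms between the two.
They are absorbed into the Jacobian by the first-order Taylor embedding

$$J_d = (I + D \circ J)^{-1} J, \qquad x(t-d) \approx x(t) - d\,\dot x(t).$$

Two deliberate choices here:

* $D$ assigns the source-pair delay to state pairs of *different*
  populations only. A population's own $(v, \dot v)$ pair belongs to one
  synaptic kernel, not to an axonal projection; delaying it is unphysical
  and, empirically, destabilizes the embedded Jacobian at the shipped
  priors while the undelayed system is stable.
* The embedding is first order. At 8 ms and 45 Hz the product $\omega d$
  is not small, so the embedding is an approximation of true
  delay-differential dynamics, traded for a linear state-space form. The
  time-domain simulator therefore integrates the *same* embedded system
  ($\dot x = Q f(x) + U u$, $Q = (I + D\circ J)^{-1}$), keeping
  simulation and spectral prediction two views of one generative model
  rather than two different models.

Channels observe mixtures of membrane potentials scaled by a lead-field
gain $L$ per channel: the cortical channel reads
$0.2\,\mathrm{SP} + 0.2\,\mathrm{MP} + 0.6\,\mathrm{DP}$, the subcortical
channel reads the STN. `population_spectra()` swaps in a unit "virtual
electrode" on any population.

## Spectral prediction

With transfer functions $H(\omega) = L\,(i\omega I - J_d)^{-1} U$, the
predicted cross-spectral density is

$$G(\omega) = H\,\mathrm{diag}(g_u)\,H^* \;+\;
\alpha_c\,(f/f_0)^{-\beta_c}\mathbf{1} \;+\;
\mathrm{diag}\big(\alpha_s (f/f_0)^{-\beta_s}\big),$$

with innovations density $g_u = 512\,\alpha_u (f/f_0)^{-\beta_u}$
entering at middle-layer pyramidal cells and striatum. All power laws are
normalized at $f_0 = 1$ Hz, which makes the amplitudes $\alpha$
dimensionally interpretable; the constant 512 is the fixed innovations
gain. Common observation noise $\alpha_c$ couples every channel pair with
unit weight (it models noise shared by both recordings); channel-specific
noise is diagonal. The two innovation sites are treated as independent —
the model carries a single $(\alpha_u, \beta_u)$ pair and no
cross-correlation parameter. Predictions are Hermitian positive
semidefinite by construction at every frequency; an unstable embedded
Jacobian flags the prediction instead of producing one, and the inversion
treats that as a rejected step.

Internally the resolvent is evaluated through the eigendecomposition of
$J_d$ (one decomposition, all frequencies); if the eigenvector matrix is
defective — e.g. the critically damped isolated population — the code
falls back to direct per-frequency solves. The closed-form benchmark
$|H| = T/|1+i\omega T|^2$ for an isolated population is reproduced to
better than $10^{-8}$ relative error (see the test suite), and a
finite-difference linearization (`linearize()`, central differences,
relative step $10^{-6}$) pins down the analytic fast path.

# Priors and parameterization

All nonnegative parameters are lognormal: $\vartheta_i = \pi_i
e^{\theta_i}$ with $\theta_i \sim \mathcal N(0, \sigma_i^2)$, so
$\theta = 0$ *is* the prior mean. `dcm_priors()` assembles the full block
table (76 parameters for the shipped two-source network): coupling
strengths and time constants per source, extrinsic strengths, condition
effects, sigmoid slopes, delays, three power-law noise pairs, and the
lead-field gains. Dispersion defaults are deliberately wider for the
basal-ganglia blocks (e.g. $\sigma^2 = 1/2$ vs $1/4$ for coupling
strengths) reflecting greater uncertainty, and the lead-field gains get
$\sigma^2 = 4$ because recording scale is essentially unknown a priori.
The data log-precision $\lambda$ has a Gaussian hyperprior with mean 16
and variance 4 — a high expected precision that makes the inversion lean
on accuracy rather than on prior expectations.

Condition effects $B$ are *additive in log space* on the modulable
coupling parameters: the baseline condition uses $\pi e^{\theta}$, the
modulated condition $\pi e^{\theta + B}$, i.e. $e^B$ is the
multiplicative change in synaptic efficacy between conditions. Their
prior means are zero with the dispersion of the block they modulate.
Effects on connections not declared modulable are an error, not a silent
no-op.

# Inversion

`dcm_csd()` fits one or two conditions jointly: shared baseline
parameters, free $B$ for the second condition. The engine (`vl_fit()`) is
Variational Laplace under a Gaussian posterior:

$$F = -\tfrac{e^{\lambda}}{2}\lVert y - g(\theta)\rVert^2
+ \tfrac{n}{2}\lambda
- \tfrac12\,\theta^\top \Pi_\theta\, \theta
- \tfrac{(\lambda - h_E)^2}{2 h_C},$$

maximized by Gauss–Newton ascent with Levenberg–Marquardt damping. The
numerical conventions, all tunable through `control`:

* prediction Jacobian by central finite differences, step $10^{-3}$ in
  log-parameter space (balances the curvature of the exponential map
  against forward-model truncation error);
* a step is accepted only if $F$ increases; the damping factor doubles on
  rejection and halves on acceptance, starting at 1 (the data scale is
  initially mismatched by the free lead-field gains, so early steps need
  strong damping);
* $\lambda$ is updated by its own Newton iteration after every candidate
  step; convergence requires both the quadratic-model gain *and* the
  realized gain (which includes the $\lambda$ update) to fall below
  $10^{-2}$ on three consecutive iterations, with a cap of 64 iterations
  and an eight-rejection bailout that returns the best visited point
  flagged `converged = FALSE`;
* the posterior covariance is the inverse Gauss–Newton curvature at the
  optimum; parameters with zero prior variance are excluded from the
  free set.

The free-energy landscape of this model family has local optima —
especially the trade-off surface between lead-field gains, noise
amplitudes and coupling strengths. The package's remedy is the one used
in practice for these models: `multistart_invert()` chains inversions,
re-initializing each at the previous posterior mean (fresh damping and
precision), and returns the highest-$F$ result. On a linear-Gaussian toy
model the engine reproduces the conjugate posterior mean and covariance
to $10^{-6}$, which exercises every part of the updates except the
nonlinearity of $g$.

# The synthetic study

No recordings ship with the package; `generate_study()` creates the
study conditions instead, and its defaults *are* those conditions:

* 20 hemispheres, two conditions (OFF = baseline, ON = modulated),
  cross-spectra on a 5–45 Hz grid;
* per hemisphere, $\theta$ drawn from the prior tightened to a quarter of
  its standard deviation (keeping draws in the stable regime while
  providing between-hemisphere heterogeneity);
* ground-truth lead-field gains $\log L = (4.33, 5.16)$, fixed so each
  channel's spectral peak sits about a decade above the observation-noise
  floor — this is the convention that produces a visible 15–35 Hz STN
  beta peak in the OFF condition (the innovations amplitude alone does
  not determine peak visibility; the gain does);
* true condition effects of $-0.5$ (a $\approx 40\%$ reduction, a strong
  but realistic medication effect) on the pallido-subthalamic (GPe→STN),
  corticostriatal and hyperdirect connections, plus between-hemisphere
  jitter of 0.1 — the pattern of synaptic reductions this model family
  is used to detect, and one that demonstrably suppresses STN beta power
  in the forward model;
* sampling noise from an averaged complex-Wishart construction with 46
  degrees of freedom, matching a typical per-condition trial count.

The default, fast path produces observed spectra analytically
(prediction + sampling noise). The slow validation path integrates the
stochastic dynamics (Euler–Maruyama, step 0.05 ms, 2 s burn-in, output
decimated to 1 kHz) and estimates spectra by ridge-regularized
least-squares MVAR of order 12 — "Bayesian" MVAR is deliberately
simplified to ridge regression ($10^{-6}$ relative) because the
estimator's role here is feature extraction and its hyperparameters are
not part of the model. Innovations are generated by spectral
factorization (`colored_noise()`), calibrated so a Welch estimate
returns the requested one-sided density.

**What the generator does and does not emulate.** It reproduces the
second-order statistics the inversion consumes: power-law innovations
filtered by the circuit, channel mixing, observation noise, finite-trial
sampling variability, and between-subject parameter spread. It does not
emulate MEG sensor physics, beamforming residue, artifacts,
non-stationarity, or model mismatch — every dataset is generated by the
same model family that is fitted. Passing recovery tests therefore
demonstrates that the estimation machinery is consistent and informative
at realistic noise levels, not that the model is correct for real
recordings.

**Simulation–prediction consistency.** Welch spectra (0.5 s Hann
segments, 50% overlap) of a 100 s simulation at the prior means match
the predicted spectral shapes within 20% relative error over 5–45 Hz
after per-channel normalization. The comparison uses the Welch
estimator's expectation — the prediction convolved with the squared
window kernel, $(1, 4, 1)/6$ at neighbouring bins — since the raw
estimator is biased exactly where the spectrum is curved; with 0.5 s
segments the residual error is statistical.

# Group inference

Per-hemisphere posterior means of the 26 condition effects (14 cortical,
9 subcortical, 3 extrinsic) enter two-tailed one-sample t-tests against
zero across hemispheres ($df = n - 1$), followed by Benjamini–Hochberg
FDR control at $q = 0.05$ over the full 26-effect family. The family
size is exposed (`m_total`) because one could argue for correcting only
over a nominated subset; the default is the full family. The worked
check: six uncorrected p-values of .005–.026 from 20 hemispheres yield
zero FDR survivors at $q = .05$ over $m = 26$.

# Problem sizes and reproducibility

The shipped test and acceptance workloads use the full 41-point 1-Hz
frequency grid (prediction cost is dominated by the linear algebra per
parameter set, not by grid length, and the denser grid roughly doubles
the information available to the inversion), 20 hemispheres, two chained
restarts per inversion, three study replicates, 100 s of simulated time
for the consistency check, 200 prior draws for the Hermitian-PSD sweep,
and 200 null replicates for the type-I check of the group pipeline (which
draws hemisphere-level effect estimates directly — inverting 4 000
synthetic hemispheres would add nothing to a check of the *group* stage).
Every stochastic step is seeded; `generate_study()` and
`simulate_time_series()` return identical output for identical
(configuration, seed) pairs.

# Known limitations

* The delay treatment is first-order; true delay-differential dynamics
  would shift high-frequency phase relations. Both the simulator and the
  predictor share the approximation, so the package is internally
  consistent but not a test of the approximation itself.
* A single scalar log-precision weights all spectral features equally;
  heteroscedastic or frequency-weighted residual models are not
  implemented.
* Local optima are real: single inversions can converge early, and even
  chained restarts occasionally misattribute an effect in one
  hemisphere. Group-level inference over hemispheres is the intended
  consumer of these posteriors.
* Only convolution-based sources can currently be registered;
  conductance-based and field models would need a different state
  interface.
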