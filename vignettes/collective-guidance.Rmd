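---
title: "Collective guidance: model, methods, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective guidance: model, methods, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coguide)
library(ggplot2)
```

## The problem

Clusters of cells — neural crest explants are the motivating system — can
chemotax up gradients that their individual cells cannot sense. In the
*collective guidance* picture each cell reads only the local
chemoattractant level $S(\mathbf r)$; directionality emerges because the
signal regulates a cell–cell interaction, contact inhibition of
locomotion (CIL). Edge cells polarize outward; when cells at higher $S$
are more susceptible to CIL, the outward polarization is stronger at the
cluster front than at the back, and the tug-of-war resolves into net
drift up the gradient.

`coguide` implements this mechanism as a two-dimensional stochastic
particle model, together with the analysis layer used to characterize it:
a rigid-cluster steady-state predictor, cluster-level observables, a
reduced model of spontaneous cluster rotation with a pitchfork fitter,
and a deterministic pair-scattering analysis.

## The model

Each cell $i$ carries a position $\mathbf r^i$ and a polarity
$\mathbf p^i$ (its self-propulsion velocity in the absence of forces):

$$\partial_t \mathbf r^i = \mathbf p^i + \sum_{j \ne i} \mathbf F^{ij},$$

$$\partial_t \mathbf p^i = -\frac{\mathbf p^i}{\tau} + \sigma \boldsymbol\xi^i(t)
  + \beta^i \mathbf q^i
  + \chi \,\frac{\nabla c(\mathbf r^i)}{|\nabla c|}\,\Theta(|\nabla c| - g_0).$$

The four polarity terms are:

* **Ornstein–Uhlenbeck relaxation and noise.** Memory time $\tau$, noise
  strength $\sigma$ with correlator
  $\langle \xi_\mu \xi_\nu \rangle = 2\delta_{\mu\nu}\delta_{ij}\delta(t-t')$.
  An isolated cell performs a persistent random walk with RMS speed
  $\sqrt{2}\,\sigma\sqrt{\tau}$ and is entirely blind to $S$.
* **CIL.** $\mathbf q^i = \sum_{j \sim i} \hat r_{ij}$ sums unit vectors
  away from every neighbour within the contact range $D_0$; the
  susceptibility $\beta^i$ is where the signal enters (below).
* **Co-attraction.** Cells secrete a fast-diffusing, degrading chemical
  $c$; in the fast-field limit its gradient at cell $i$ is the screened
  kernel sum $\nabla c(\mathbf r^i) = -\sum_{j\ne i} K_1(d_{ij}/\ell)\,\hat r_{ij}$
  with decay length $\ell$. The response is a *hard step*: magnitude
  exactly $\chi$ whenever $|\nabla c| > g_0$, so cells respond equally
  strongly to weak and strong gradients. $g_0 = 10^{-5}$ exists only to
  guard the normalization.
* **Forces** $\mathbf F^{ij}$ are radial springs: repulsive
  $v_r(1-d)$ below the equilibrium separation $d = 1$, adhesive
  $-v_a(d-1)/(D_0-1)$ out to $D_0$, zero beyond. Forces move cells but
  never touch $\mathbf p^i$ — this asymmetry is why co-attraction (a
  polarity effect) can drive rotation while adhesion cannot.

Units: one length unit = one cell diameter = 20 µm; one time unit =
$\tau$ = 20 min; so one velocity unit is 1 µm/min.

### Signal processing: from S to beta

Three response modes set $\beta^i$:

* `minimal`: $\beta^i = \bar\beta\, S(\mathbf r^i)$ — direct
  transduction, no internal processing.
* `legi_linear`: $\beta^i = \bar\beta\, R^i / R_0$ with $R$ the output of
  a local-excitation global-inhibition (LEGI) network.
* `legi_switch`: $\beta^i = \bar\beta\, g(R^i/R_0)$ with
  $g(x) = \tfrac12[1 + \tanh((x-1)/\lambda)]$ — switchlike amplification
  that makes the front/back distinction nearly binary for
  $\lambda \ll 1$ (default $10^{-2}$).

The LEGI network produces, in each cell, an activator $A$
($\dot A^i = k_A S_i - k_{-A} A^i$) and an inhibitor $I$ that hops
between contacting cells at rate $k_D$ (a graph-Laplacian
reaction–diffusion system), and a response
$\dot R^i = k_R A^i (1 - R^i) - k_{-R} I^i R^i$. Because $A$ is local
and $I$ is shared, $R$ reports the local signal relative to the cluster
average: the network adapts perfectly to uniform signals (the uniform
steady state $R_0$ is independent of $S_0$), and in the fast-diffusion
limit $R^i \to R_0\, S_i/\bar S$. The communication quality is
$\alpha = k_{-I}/k_D$; $\alpha N \ll 1$ is needed for cluster-wide
sensing, and at the physiological $\alpha = 0.25$ large clusters sense
the gradient imperfectly — the origin of the optimal cluster size.

### Rate defaults and why

`legi_rates()` defaults: $k_I = k_{-I} = 1$ and $k_D = 4$
($\alpha = 0.25$, gap-junction-like transfer over a few minutes), in
units of $1/\tau$. The remaining rates are constrained only by ordering
assumptions (excitation and readout fast, readout weakly produced), and
we chose: $k_A = k_{-A} = 5$ — excitation five-fold faster than
inhibition. Only the ratio $k_A/k_{-A}$ enters steady states, but the
*speed* of the local branch is what produces the transient overshoot
after a signal step: if $A$ and $I$ relaxed at identical rates, a
uniform step would produce no pulse at all, contradicting the defining
phenomenology of adaptation. $k_R = 0.05$, $k_{-R} = 50$ keeps
$k_R/k_{-R} = 10^{-3}$, so the exact steady state
$R = k_R A/(k_R A + k_{-R} I)$ is within 0.1% of the ratio form while
$R$ itself relaxes fast, as the quasi-static treatment assumes.

We use the *exact* uniform steady state
$R_0 = \rho/(1+\rho)$, $\rho = (k_R/k_{-R})(k_A/k_{-A})(k_{-I}/k_I)$,
as the normalization (the ratio approximation $\rho$ is available via
`legi_r0(exact = FALSE)`). The distinction is 0.1% here but matters for
tight quantitative checks of the fast-diffusion limit, and it keeps
$g(R/R_0)$ centred exactly on the uniform state.

## Numerics

**Integration** is explicit Euler–Maruyama with the noise increment
$\sigma\sqrt{2\,\Delta t}\,\eta$ per component ($\eta$ standard normal).
The factor 2 comes from the stated noise correlator and is a classic
place to go wrong by $\sqrt 2$; the suite pins the stationary polarity
variance $\sigma^2\tau$ per component. All rates are evaluated at the
pre-step state; the contact graph is rebuilt every step (brute force
$O(N^2)$ — at the relevant scales ($N \le 127$) cell lists are not worth their complexity).
Time steps: $10^{-3}$ for co-attraction runs, $10^{-4}$ for rigid
high-adhesion runs (spring stiffness $\sim v\,\Delta t$ must stay well
below 1). Coincident cells are an error, never a regularization: the
repulsive spring makes coincidence dynamically inaccessible at these
steps.

The inner loop (in C++) evaluates the co-attraction kernel with a
rational-polynomial $K_1$ (absolute error $<\!2.5\times 10^{-7}$),
cross-checked in the tests against R's `besselK`, which the R-level
`coattract_gradient()` uses directly. In the default LEGI simulation
mode (`quasi_static`) only $I$ is integrated; $A$ and $R$ are enslaved
to their steady states. The `full` mode integrates all three, which is
the right tool for step-response transients and for amplified clusters,
where response fluctuations interact with the switch nonlinearity.

**Initial conditions**: hexagonal-lattice clusters (closed shells at
$N \in \{1,7,19,37,61,91,127\}$) at a uniform random orientation per
trajectory, zero polarities, inhibitor at the uniform steady state for
the initial mean signal. Burn-in is absorbed by the measurement window,
default the last three quarters of the trajectory (the bundled
co-attraction scenarios measure over $12.5\tau$–$50\tau$ of $50\tau$).

**Degenerate inputs**: linear signal fields error (not clamp) if any
cell samples $S \le 0$; `fit_pitchfork` raises a classed error when all
angular velocities vanish ($\chi_c$ unidentifiable); cells at the exact
centroid are excluded from the angular-velocity cell average.

## The analysis layer

**Rigid predictor.** For rigid clusters with the network at steady
state, the orientation-conditioned mean velocity is
$\langle \mathbf V \rangle_c = \frac1N \sum_i \beta_i \mathbf q_i$.
`rigid_steady_prediction()` averages $V_x$ over 64 equally spaced
orientations (doubling changes results by $<10^{-3}$ relative — asserted
in the tests) and computes the chemotactic index
$\mathrm{CI} = \langle V_x\rangle / \langle |\mathbf V|\rangle$ from the
orientation mixture of isotropic Gaussians with per-component variance
$\sigma^2\tau/N$, evaluating $E|\mathbf V|$ by quadrature over the Rice
density (closed forms exist; quadrature is oracle-checkable). This
reproduces the optimal cluster size $N = 19$ at $\alpha = 0.25$ under
the linear LEGI response in the standard shallow exponential gradient
($S_0 = 1$, $S_1 = 0.025$), the $N^{-1/2}$ velocity decay of amplified
clusters, and the saturation of the minimal model.

**Observables.** Cluster velocity is centroid displacement over the
window (robust to snapshot cadence, identical in the mean to averaged
instantaneous velocity). Angular velocity uses central finite
differences at the snapshot cadence (keep it $\le 0.1\tau$ for rotation
studies; the estimator carries an $O((\omega\,\Delta t)^2)$ chord bias),
averages over cells about the instantaneous centroid, then over time —
exact for rigid rotation up to that bias, exactly Galilean invariant,
and odd under mirror reflection.

**Rotation.** Strong co-attraction polarizes cells inward; with a
finite polarity memory $\tau$, a rigid circular cluster admits a
two-variable reduction in the total radial and tangential polarity
moments $(W, \Omega)$:
$\dot W = \Omega^2 - W/\tau + W_0/\tau$,
$\dot\Omega = -(1/\tau + W)\,\Omega$. The quiescent state loses
stability at $W_0\tau = -1$ in a supercritical pitchfork to mirror
rotating states $\Omega = \pm\tau^{-1}\sqrt{-1 - W_0\tau}$. (The
tangential equation is re-derived here from the component equations; the
sign convention is fixed by requiring it to reproduce the known steady
states and stability boundary.) In the full model the inward bias is
$-\chi$, so $|\Omega|(\chi) = \Omega_0\sqrt{\chi - \chi_c}$ above a
critical co-attraction $\chi_c$. `fit_pitchfork()` fits both parameters
jointly: for fixed $\chi_c$ the amplitude is a closed-form least-squares
solution, so the fit is a deterministic 1-D grid-plus-refinement search
over $\chi_c$ (ties toward smaller residual, then smaller $\chi_c$) —
the objective is non-smooth at the data points, so a naive local
optimizer is not trustworthy. Branch handling follows the handedness
convention: trajectories are split by the sign of their mean angular
velocity and branch means are fitted as magnitudes. Sweeps warn above
$\chi = 100$, where tightly wound clusters are numerically fragile at
the default step.

**Pair scattering.** Two cells colliding under strong CIL exchange
polarity in a nearly elastic way: with $\Delta = \mathbf p^i - \mathbf p^j$,
$\Sigma = \mathbf p^i + \mathbf p^j$ projected on the contact axis,
$\Delta \to -\Delta(0)$ and
$\Sigma \to \Sigma(0) - 2\Delta(0)\,(\beta_i-\beta_j)/(\beta_i+\beta_j)$.
The separation time scales as $1/(\beta_i+\beta_j)$ while the
repolarization contrast scales as $\beta_i - \beta_j$, so the transfer
depends only on the *relative* signal difference — adaptation without
any internal network, and the mechanism behind signal-level-independent
velocities of loosely bound clusters. `pair_scattering_numeric()`
realizes this as a noiseless two-cell simulation. Two numerical choices
matter and are easy to get wrong: the pair must start just *outside*
the contact range (starting inside injects an artificial exit impulse
that grows as $\sqrt\beta$ across the residual gap), and the time step
must resolve the repolarization time (default
$\Delta t = \min(10^{-4}, 2\times10^{-3}/\bar\beta)$). The theory is
asymptotic with $1/\beta$ corrections: at $\bar\beta = 50$ the residual
signal-level dependence of the transfer is a real few-percent model
property; demonstrating the asymptotic insensitivity ($<2\%$ over a
four-fold level change) needs $\bar\beta$ of order a few hundred.

## What the simulations do and do not emulate

The generator's default conditions are the study conditions: shallow
exponential gradients ($S_1 = 0.025$ per cell diameter, so the signal
changes by ~2.5% per cell), $\sigma = \tau = 1$, co-attraction range
$\ell = 5$, contact range $D_0 = 1.2$ (the interaction range is not
fixed by the main-text parameter set; it is config-overridable and all
derived results are reported with the value used). Cells are point
particles: no shapes, no torques on individual cells (polarities are
fixed in the lab frame — the collective rotation depends on this), no
receptor saturation, no reaction noise in the network, strictly 2-D
fields and motion, open boundaries, no division or death. Passing tests
therefore validate the mechanism and its quantitative signatures within
this idealization, not cell-shape- or adhesion-remodelling-dependent
features of real explants. The handedness-dependent drift of rotating
clusters is reported by `chirality_drift()` but its sign and magnitude
are sensitive to the hard-threshold co-attraction response, so it is
treated as emergent and not asserted quantitatively.

## Problem sizes

The packaged analyses use ensembles scaled to desk hardware: the
rotation sweep runs 10 trajectories of $25\tau$ per $\chi$ over seven
$\chi$ values (larger ensembles — say 100 trajectories of $50\tau$ —
sharpen the branch means but are not needed for few-percent
reproducibility of the fit); the
single-cell statistics use one $10^4\tau$ trajectory; predictor curves
are deterministic and cost seconds. At these sizes the pitchfork
parameters are reproducible to a few percent across seeds.

## A worked sweep

```{r sweep, eval = FALSE}
p <- model_params(beta_bar = 35, v_r = 100, v_a = 0, dt = 1e-3)
sw <- sweep_rotation(chi_values = c(5, 20, 35, 50, 65, 80, 95),
                     params = p, N = 37, T = 25, n_traj = 10, seed = 1)
fit <- fit_rotation_sweep(sw, n_boot = 200)
glance(fit)
autoplot(fit)
```

```{r predictor, eval = FALSE}
f <- signal_field("exponential", S0 = 1, S1 = 0.025)
p <- model_params(beta_bar = 20, v_r = 500, v_a = 500,
                  response_mode = "legi_linear", dt = 1e-4)
purrr::map_dfr(c(1, 7, 19, 37, 61), function(n)
  rigid_steady_prediction(init_hexagonal_cluster(n, angle = 0), p, f))
```

## Known limitations

* The explicit integrator is first order; halving $\Delta t$ should be
  (and is, in the tests) a first-order convergence check, but stiff
  high-adhesion runs need the smaller step and there is no adaptive
  stepping.
* The co-attraction field is a point-source superposition: no excluded
  volume, no finite secretion/diffusion timescale.
* `fit_pitchfork` assumes a single supercritical transition in the data
  range; sweeps that fragment at high $\chi$ violate the model and
  should be truncated first.
* The LEGI inhibitor exchange is defined on the instantaneous contact
  graph; for loosely bound clusters with transient contacts, sensing
  degrades — a model statement, not an artifact, but it means
  co-attraction + LEGI ensembles are slower and noisier than their
  rigid counterparts.
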