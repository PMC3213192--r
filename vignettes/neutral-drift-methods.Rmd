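---
title: "The neutral-drift polarity circuit: model, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The neutral-drift polarity circuit: model, methods, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutraldrift)
```

## The circuit

A single molecular species — think of Cdc42 or another Rho-family GTPase —
cycles between an **inactive, cytosolic** form and an **active,
membrane-bound** form. Three mass-action mechanisms connect the two states:

* **Spontaneous inactivation.** Each membrane molecule returns to the cytosol
  at rate $k_{\mathrm{off}}$ (per minute).
* **Spontaneous activation.** Inactive molecules within a shell of volume
  $V_{\mathrm{on}}$ near the membrane activate at rate $k_{\mathrm{on}}$.
* **Recruitment (positive feedback).** An active molecule converts inactive
  molecules within its feedback volume $V_{\mathrm{fb}}$ at rate
  $k_{\mathrm{fb}}$, placing the recruit at its own membrane position; both
  then diffuse independently.

The total number of molecules $N_T$ is conserved, the cytosol is well mixed
(inactive diffusion is far faster than membrane diffusion), and membrane
molecules perform Brownian motion with diffusivity $D_m$.

Writing $\rho_c$ for the cytosolic density and rescaling time by
$k_{\mathrm{off}}$, the mean-field dynamics are

$$\frac{d\rho_c}{d\tau} = (\rho_T - \rho_c)\Bigl(1 - \frac{\rho_c}{\rho^*}\Bigr) - \alpha\,\rho_c,$$

with three constants: the total density $\rho_T = N_T/V$, the **critical
density** $\rho^* = k_{\mathrm{off}}/(k_{\mathrm{fb}} V_{\mathrm{fb}})$
(a property of the circuit, independent of cell size and molecule number),
and the dimensionless on-to-off ratio
$\alpha = k_{\mathrm{on}} V_{\mathrm{on}} / (k_{\mathrm{off}} V)$. The ratio
$R_0 = \rho_T/\rho^*$ plays exactly the role of the basic reproductive ratio
in SIS epidemic models: cytosolic molecules are the susceptibles, membrane
molecules the infectives, recruitment the contact process.

For $\alpha = 0$ the right-hand side is a clean quadratic with equilibria
$\{\rho_T, \rho^*\}$; the smaller is stable, and stability is exchanged at
$\rho_T = \rho^*$ (a transcritical bifurcation). Below the threshold
*every* molecule ends up cytosolic — the off state is buffered against
noise by the deterministic flow itself, not by any accessory mechanism.
Above it, $(\rho_T - \rho^*)V$ molecules occupy the membrane. A small
$\alpha > 0$ breaks the crossing into an imperfect transcritical
bifurcation with a unique stable physical root; `steady_states()` computes
the roots from the cancellation-safe quadratic formula
(`2c/(-b + sqrt(b^2-4ac))` for the small root), because the naive form
loses precision precisely in the interesting region $\rho_T \approx \rho^*$.
Roots closer than $10^{-9}\rho^*$ are reported as the degenerate double
root.

## Count statistics: the one-step process

With finitely many molecules the cytosolic count $n$ is a one-step
birth–death chain on $\{0,\dots,N_T\}$: births (off-events) at rate
$k_{\mathrm{off}}(N_T - n)$, deaths at rate
$k_{\mathrm{on}}(V_{\mathrm{on}}/V)\,n + k_{\mathrm{fb}}(V_{\mathrm{fb}}/V)\,n(N_T-n)$.
The stationary law follows from the detailed-balance product recursion,
evaluated in log space with one normalization pass (stable to $N_T \sim
10^5$). Far below the critical number $N^* = \rho^* V$ the mass sits at
$n = N_T$; far above it the distribution is essentially Poisson with mean
$N^*$; near the transition it is **bimodal** even though the deterministic
equation is monostable — the hallmark of the stochastic switch. With
$k_{\mathrm{on}} = 0$ the empty membrane is absorbing and the chain's
stationary law degenerates to the point mass at $N_T$; the package signals
this case rather than erroring, since the no-spontaneous-activation limit
is analytically meaningful.

Mode detection merges plateaus (ties are common in discrete laws) and
requires each mode to carry at least `1e-4` peak probability, so that
floating-point ripples do not masquerade as modes.

## Space: neutral drift of clans

Above threshold the membrane population turns over with per-capita death
rate $k_{\mathrm{off}}$ and per-capita birth (recruitment) rate
$k_{\mathrm{fb}}(V_{\mathrm{fb}}/V) N_c$. At the quasi-stationary cytosol
level $N_c \approx N^*$ these balance exactly: every membrane molecule is a
member of a *critical* branching population. Group the initial membrane
molecules into $K$ clans by arc; recruits inherit their recruiter's clan,
dissociation erases identity, and extinct clans never return. Clan sizes
then perform neutral drift, exactly analogous to neutral alleles in a
finite population, and one clan eventually owns the whole membrane — at a
random location: this is how a spatially featureless circuit polarizes.

For the clan-time formulas the package treats clans as independent linear
birth–death processes with per-capita birth
$\lambda = k_{\mathrm{fb}}(V_{\mathrm{fb}}/V)(N_T - N_m)$ and death
$\mu = k_{\mathrm{off}}$ (critical when $N_m$ sits at its equilibrium).
A clan of $n_0 = N_m/K$ founders is extinct by time $t$ with probability
$P(t)^{n_0}$, where $P(t) = \lambda t/(1+\lambda t)$ in the critical case,
so the surviving count is approximately $\mathrm{Binomial}(K, 1 - P^{n_0})$.
Because the count is non-increasing, its first-passage time below a level
$c$ is $\le t$ exactly when $S(t) \le c$, so the *median* crossing time
solves $P(S(t) \le c \mid S \ge 1) = 1/2$; `clan_half_life()` uses
$c = \lceil K/2 \rceil$ (the same parity convention as the empirical
estimator) and `single_clan_time()` uses $c = 1$. The two coincide exactly
at $K = 2$. Asymptotically the half-life scales as
$N_m/(K k_{\mathrm{off}} \ln 2)$ and the single-clan time as
$N_m/k_{\mathrm{off}}$, independent of $K$. These are approximations —
clans are coupled through the conserved total — and the package's tests
gate them at 25% (half-life) and a factor of two (single-clan time)
against simulation medians, which is the honest scale of validity of the
independence assumption.

Two closed-form bounds delimit the polarized regime (`regime_bounds()`):

* **On-event rarity.** Over the consolidation time
  $T_{\mathrm{single}} \sim N_m/k_{\mathrm{off}}$, spontaneous on-events
  inject an expected $k_{\mathrm{on}}(V_{\mathrm{on}}/V) N^*
  T_{\mathrm{single}}$ membrane molecules (each on-founded lineage is
  critical, with expected size one). The injected fraction is exactly the
  on-to-feedback ratio $\beta = k_{\mathrm{on}}V_{\mathrm{on}} /
  (k_{\mathrm{fb}}V_{\mathrm{fb}})$, so all but a fraction $\delta$ of the
  membrane belongs to one clan when $\beta \le \delta$ (default
  $\delta = 0.1$; the default rates give $\beta = 0.05$).
* **Locality.** The winner spreads diffusively by
  $\sqrt{2 D_m T_{\mathrm{single}}}$ with $T_{\mathrm{single}} \le
  N_T/k_{\mathrm{off}}$; requiring this to stay below a fraction of the
  membrane size gives $N_T \le C\,k_{\mathrm{off}} L^2 / D_m$. The
  order-unity constant $C$ absorbs the initial-region size and geometry;
  it is an exposed parameter with default $0.5$, chosen as the midpoint of
  the order-unity range the spread argument allows, and the package treats
  the bound as a scaling statement, not a sharp line.

## The particle simulator

`simulate()` advances positions on the unit circle with a fixed-step
operator split per $\Delta t$: (a) dissociation sampled on the pre-step
membrane set, (b) recruitment with probability
$k_{\mathrm{fb}}(V_{\mathrm{fb}}/V)N_c\Delta t$ per surviving membrane
molecule — the recruit placed *exactly* at the recruiter's position, no
jitter, (c) a Poisson number of on-events at uniform positions, each
founding a fresh clan, (d) a wrapped Gaussian step of variance
$2 D_m \Delta t$. A fixed-step scheme was chosen over an event-driven SSA
because the recruitment propensity changes with every event (an exact SSA
would re-draw constantly) while the fixed step vectorizes; the default
$\Delta t$ keeps every per-molecule event probability below $0.1/\,$step
(hard error otherwise), and a convergence test checks that halving
$\Delta t$ leaves time-averaged occupancies unchanged within noise. The
sub-step ordering (dissociation before recruitment) is one fixed
convention among several that agree as $\Delta t \to 0$; it is documented
and pinned by tests. Mass conservation is exact by construction at every
step, and identical seeds give identical trajectories (the compiled core
draws from R's RNG stream). Replicate runs derive per-replicate sub-seeds
from the master seed by one `sample.int()` draw each, so streams are
reproducible and uncorrelated.

Perturbation protocols are first-class: `evt_reseed()` moves a fraction of
the cytosol into one randomly placed membrane window (fresh clan ids —
the window position is random because regime outcomes must be
rotation-invariant), and `evt_add_cytosol()` / `evt_remove_cytosol()`
change $N_T$ with explicit bookkeeping; removal beyond the current
cytosolic pool errors before mutating anything.

### Units and the diffusion anchor

The default composite rates are defined on a unit reaction domain, so the
defaults set $V = V_{\mathrm{on}} = V_{\mathrm{fb}} = 1$, making
$k_{\mathrm{on}}$ and $k_{\mathrm{fb}}$ per-molecule propensity
coefficients and $N^* = k_{\mathrm{off}}/k_{\mathrm{fb}} = 900$. Membrane
diffusion is physical ($D_m = 1.2\,\mu m^2/\mathrm{min}$, a Cdc42-scale
value), and only $D_m/L^2$ enters the dynamics. The package anchors the
default circumference to a 10-µm-diameter yeast mother cell,
$L = 2\pi \cdot 5\,\mu m$, giving $D_m/L^2 \approx 1.2\times10^{-3}$ per
minute. The anchor matters: the winner-clan spread
$\sqrt{2 (D_m/L^2) T_{\mathrm{single}}}$ must sit near the 15–25% window
scale at polarized molecule numbers for clusters to be visible at all,
which holds for cells of roughly this size and fails for much smaller
ones. Users modeling other systems should set `L` (or `D_m`) accordingly.

## Polarization calls and regimes

A state is **polarized** when more than 20 molecules are membrane-bound and
at least 50% of them lie in one contiguous arc covering 15–25% of the
membrane; `detect_cluster()` scans 360 equally spaced windows (1°
discretization, far below the window widths). `classify_regime()` then
labels a replicate set **OFF** (mean membrane fraction $< 0.02$),
**POLARIZED** (polarization frequency $\ge 0.3$ of post-burn-in samples),
**MULTI_CLAN**, or **HOMOGENEOUS_ON**. The multi-clan label requires both
more than 1.5 surviving clans *and* spatial enrichment (the best 15%
window holding at least twice its uniform share): at high molecule
numbers many clan labels coexist on a spatially uniform membrane for a
long transient (consolidation takes $\sim N_m/k_{\mathrm{off}}$, hundreds
of minutes at eight times the critical number), and a uniform membrane is
the homogeneous on state regardless of how many labels it carries — the
multi-clan regime of the phase diagram means multiple spatially distinct
clusters. All four thresholds are artifact choices, exposed as arguments.
Whether "polarization probability" means a per-time-sample or per-run
quantity is genuinely ambiguous; the package uses the per-time-sample
fraction after burn-in, which is the ergodic reading, and exposes
`burn_in`.

`phase_scan()` classifies a grid over molecule number and compartment size
(the size factor scales $V$ and $L$ together, as for a growing cell), and
overlays the analytic expectation ($R_0 \le 1$ off; $R_0 > 1$ plus both
regime bounds polarized; otherwise near a boundary).

## Finite-diffusion geometries

`simulate_geometry()` drops the well-mixed assumption: inactive molecules
diffuse at finite $D_c$ in the same compartment as (or interior to) the
active set, and recruitment becomes a proximity reaction — each
(active, inactive) pair within a reaction radius reacts with probability
`p_react` per step, at most one conversion per inactive molecule per step
with the recruiter drawn uniformly among neighbors. Three geometries are
supported: sphere surface/interior (polarity), periodic plane (membrane
microdomains), periodic box (nuclear/cytosolic puncta). Sphere-surface
diffusion uses a tangent-plane Gaussian step with radial re-projection
(error $O(\Delta t)$, controlled by the step-size tests); interior
molecules reflect radially at the surface. Neighbor queries use uniform
spatial binning with cell size equal to the reaction radius.

`effective_rate_map()` places such runs on the analytic phase plane: in
the fast-diffusion limit the composite mass-action constant is
$k_{\mathrm{fb}}V_{\mathrm{fb}} = p_{\mathrm{react}} \cdot
\mathrm{kernel}/\Delta t$ with kernel $\pi r^2$ (plane),
$\tfrac{4}{3}\pi r^3$ (box), or $\tfrac{2}{3}\pi r^3$ (half-ball for a
surface-bound recruiter). The map neglects local depletion
(diffusion-limited corrections), so it is exact only as $D_c$ grows or
$p_{\mathrm{react}}$ shrinks — which is precisely the regime the
well-mixed consistency tests probe. This module approximates
Brownian-dynamics reaction schemes generically; it does not reproduce any
particular third-party simulator step-for-step.

## What the tests do and do not show

The test suite checks: the analytic switch exhaustively over random
parameters; exact agreement of the stationary recursion with a dense
3-state generator oracle and global balance to $10^{-10}$; total-variation
agreement (at the default rates, $N_T = 100$) between long-run simulated
occupancies and the master equation for both the 1-D simulator (< 0.05)
and the finite-diffusion plane (< 0.1); off-state buffering below
threshold including after restimulation; the off → polarized → homogeneous
progression at $\{0.3, 1.5, 8\} \times N^*$ with 10 replicates each;
the Poisson limit at $4N^*$ (TV < 0.05 against Poisson($N^*$)); bimodality
within ±20% of $N^*$; clan fairness (each of 5 exchangeable clans wins
with probability consistent with 1/5 over 500 runs) and clan-time
concordance on a three-point sweep; and exact conservation plus seed
determinism everywhere. Simulation-based checks use scaled-down systems
(tens to thousands of molecules, tens of simulated minutes) chosen so each
statistic resolves well above its Monte-Carlo noise floor.

What they do *not* show: anything about real Cdc42 data (no rates are fit
here); behavior when reaction volumes overlap at high density (mass action
is assumed never to saturate — the known limitation of the model class);
multi-component feedback loops (GEFs, scaffolds) beyond the effective
two-state reduction; or membrane curvature and crowding effects in the
geometry module.

## Numerical choices, edge cases

* Quadratic roots via the cancellation-safe small-root form; degenerate
  double roots flagged at $10^{-9}\rho^*$ relative separation.
* Stationary recursion in log space; $k_{\mathrm{on}} = 0$ returns the
  absorbing point mass with a warning rather than an error.
* `integrate_density()` reports solver failures; it never clips silently.
* Step-probability guards error out loudly naming the violated bound.
* Clan extinction is irreversible by construction: ids are never reused,
  each on-event founds a fresh clan.
* The half-life estimator uses the first crossing of $\lceil K/2 \rceil$
  surviving clans (parity convention, matched by the formula).
* `winner_locality()` refuses to answer when more than one clan survives.

## Package shape

The package follows the classic R modelling idiom: `polarity_model()` is
the single constructor returning a classed object, with `print`,
`summary`, `coef`, `simulate` and `plot` methods; analysis functions take
the model object. `predict` and `residuals` methods are deliberately
absent — the object is a mechanistic forward model, not a fit to data, so
there is nothing for them to act on.

```{r example, eval = FALSE}
m <- polarity_model(N_T = 1350)          # 1.5 x the critical number
summary(m)
ss <- steady_states(derive_constants(m))
tr <- simulate(m, seed = 42, t_end = 45, record_every = 0.5)
plot(tr)                                  # kymograph
classify_regime(m, simulate(m, nsim = 10, seed = 1, t_end = 45,
                            record_every = 0.5))
```
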