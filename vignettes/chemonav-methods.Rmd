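---
title: "chemonav: model, training procedure and attribution methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chemonav: model, training procedure and attribution methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(chemonav)
```

## The scientific problem

Microorganisms performing chemotaxis estimate a chemical gradient from
molecule counts that are fundamentally noisy.  Two classical strategies
exist: *spatial* sensing (compare simultaneous counts across the cell
body — effective for large cells) and *temporal* sensing (compare counts
over time while moving — the only option for small cells, whose
body-scale concentration differences drown in shot noise).  `chemonav`
implements a minimal stochastic model of a chemotactic cell and a set of
trainable neural navigation policies designed to probe the regime in
between, where an optimal strategy may mix both information sources, and
provides attribution tools to quantify *how much* a trained policy
relies on memory versus instantaneous measurements.

## The simulation model

**Concentration field.** A static, radially symmetric chemoattractant
profile peaks at the origin.  The default is exponential,
$C(\mathbf{x}) = C_0 e^{-\lambda|\mathbf{x}|}$, with
$\lambda = \sqrt{\kappa/D}$ when derived from a diffusion–decay source
($D$: particle diffusion coefficient, $\kappa$: decay rate).  The
defaults $\lambda = 0.032\,\mu m^{-1}$ (from $D = 100\,\mu m^2/s$,
$\kappa = 0.1\,s^{-1}$) and $C_q = 16\,\mu m^{-2}$ place the cell in the
fundamental-limit-of-sensing regime.  Two alternative shapes are
provided: the steady-state solution of the 2D diffusion–decay source
equation, which is a modified Bessel function $K_0(\lambda r)$, and an
algebraic profile $C_0/(1+\lambda r)^2$.  Because the $K_0$ amplitude
involves the release rate rather than a peak value (it diverges
logarithmically at the origin), the Bessel profile is pinned to the
exponential profile's value at a reference radius `r_match` (default
2 um, the cell scale), which makes profiles comparable where the cell
actually measures; the far-field log-slope then approaches $-\lambda$
for both.

**The cell.** A disk of radius $R$ carries $K$ sensors uniformly spaced
on its perimeter, each a *perfect instrument* counting every particle
inside its detection disk of radius $r_s = R\sin(\pi/K)$ (this choice
tiles the cell surface).  Counts are independent Poisson draws per
sensor and per step with mean
$E(M_i) = C(d_i)\,\pi r_s^2$ — the locally flat approximation, accurate
to well under a percent at the default geometry (the test suite checks
it against 2D quadrature).  Receptor binding/unbinding kinetics,
receptor saturation and count correlations are deliberately out of
scope.  Measurements are compressed by the Weber–Fechner transform
$m_i = \log(M_i + 1)$, which maps shot noise into an input range
friendly to small networks.

**Motion.** The cell never stops: it moves at constant speed $v$
(default $5\,\mu m/s$) along its heading $\theta$, which evolves as
$d\theta = a_t\,dt + \sqrt{2 D_R}\,dW$ with policy action $a_t$ (rad/s,
positive = counterclockwise/left) and rotational diffusion $D_R$
(default $0.025\,s^{-1}$).  Integration is Euler–Maruyama with
$\Delta t = 0.1\,s$ by default: heading first, then translation along
the *new* heading.  The alternative order differs at $O(\Delta t)$; one
order had to be fixed and this one makes a zero-noise, perfect-aim
policy reach the source in exactly the straight-line time.

**Episodes.** Each episode samples an initial distance $d_0$ (uniform),
a random bearing and heading, and a per-episode concentration scale
$C_0$ log-uniform over $[C_q, 10\,C_q]$.  (The source strength and peak
concentration are a single physical dial; the field is parameterised by
$C_0$ directly.)  The episode ends on arrival within $\delta$ (default
10 um) of the source or at the horizon $t_{max}$.  The terminal reward
is
$$R = \frac{t_{max}-\tau}{t_{max}} +
  \max\left(-1, \frac{\delta-d}{d_0-\delta}\right),$$
with exactly one term nonzero: arrivals earn the normalised time term,
timeouts the (negative) distance term, so the reward lies in $[-1,1]$.
The distance term is reward shaping — it supplies a learning signal
early in training when the source is never reached.

The full-scale defaults $d_0 \in [100, 500]$ um and
$t_{max} = 2000$ s are declared assumptions (a straight path takes at
most 98 s, far less than the horizon, and a blind agent almost never
arrives); both are configuration-exposed and echoed in all outputs.
There is no spatial boundary; the horizon handles divergence.

## The policy variants

All policies share one interface: measurements in, angular velocity
out.  Three neural variants differ only in what they may see:

* **spatial** — a feedforward tanh MLP on the instantaneous per-sensor
  measurements $\{m_i\}$; stateless by construction.
* **temporal** — receives only the sensor average $\langle m\rangle$
  (and its own previous action), routed through a gated recurrent unit
  (GRU) whose hidden state is the model's stand-in for biochemical
  memory; spatial information is unavailable by design.
* **combined** — all $K$ measurements plus the previous action through
  a GRU; can realise either pure strategy or any mixture.

Heads on the top layer emit the mean $\mu_t$ (tanh-squashed to
$[-a_{max}, a_{max}]$, default $a_{max} = \pi$ rad/s — bounding the
action keeps the clipped-surrogate optimisation stable), a
state-dependent standard deviation $\sigma_t$ (softplus-positive,
initialised at half the action scale), and a value estimate $V_t$ of
the terminal reward used only during training.  Actions are sampled
from $\mathcal{N}(\mu_t, \sigma_t)$ during training and set to $\mu_t$
at evaluation (exploration noise anneals toward zero as training
converges).  The previous action is fed back only to the recurrent
variants, where it lets the policy separate its own exploration noise
from environmental change; the spatial variant stays memoryless.

Defaults: hidden size 32, MLP widths 64/64, tanh activations, Gaussian
fan-in initialisation with small output heads.  Network layers (dense,
GRU) are implemented in vectorised base R with analytic forward and
backward passes; all gradients are verified against finite differences
in the test suite.

**Analytic baselines.** A *blind* agent (zero action always), a
*memory-kernel* comparator (turn rate proportional to a lag-weighted
left-minus-right contrast, sensors weighted by $\sin\phi_k$ so the
front sensor is neutral; a delta kernel reduces it to an instantaneous
spatial comparator), and a *switching* strategy that runs a temporal
policy until the mean measurement first crosses a threshold and then
latches irreversibly onto a spatial policy.  The kernel weights are
exposed rather than fixed, since no canonical shape is prescribed —
the bi-lobed impulse-response kernel known from bacterial chemotaxis is
one natural choice.

## Training

Policies are trained by proximal policy optimisation (PPO): batches of
independent stochastic episodes are collected (vectorised across
episodes; results are independent of batching), advantages are computed
by generalised advantage estimation with terminal bootstrap 0 and
normalised per update, and the clipped-surrogate policy loss plus value
regression and a small entropy bonus is minimised by Adam over several
passes, with global gradient-norm clipping.  Recurrent variants replay
*full sequences in order* from their initial (zero) hidden states — no
truncated backpropagation windows, since desk-scale episodes are short.
Rewards are purely terminal; every transition carries zero reward
except the last.  All randomness flows from a single seed, so training
runs are exactly reproducible.

Defaults follow common PPO practice (clip 0.2, $\gamma = 0.99$,
$\lambda_{GAE} = 0.95$, 4 epochs, learning rate $3\cdot10^{-4}$ with
linear decay, entropy coefficient $10^{-3}$, 256 episodes per update).
$\gamma = 1$ is fully supported and is the natural choice for the
purely terminal reward.

### The desk-scale study configuration

`scaled_study_config()` freezes the conditions of the package's own
directional experiments, which the acceptance tests run end to end:
a 2 um cell in the high-concentration regime ($C_0 = 10\,C_q$ fixed),
$d_0 \in [60, 100]$ um, $\delta = 10$ um, $t_{max} = 60$ s,
$\Delta t = 0.2$ s, hidden size 16, MLP 32/32, initial $\sigma = 0.8$
rad/s, and a matched budget of 256 episodes x 100 updates per variant
with $\gamma = 1$, $\lambda_{GAE} = 1$ (whole-episode credit assignment
— with a terminal-only reward and short episodes this converges far
faster than bootstrapped credit) and learning rate $10^{-3}$, linearly
decayed.  The choices scale the published experimental design down by
orders of magnitude (the original study trains millions of episodes);
they are sized so that a straight path takes well under the horizon,
the blind agent almost never arrives, and the whole three-variant
experiment runs in minutes on one CPU core.  The recurrent variants use
larger optimisation minibatches than the spatial one to bound the cost
of backpropagation through time; the environment-interaction budget is
identical across variants, which is what the cross-variant efficiency
comparison requires.  Verified at this scale: the trained spatial
policy exceeds the blind baseline's efficiency several-fold, mean
$\sigma_t$ decreases over training for every variant, and the combined
variant at least matches the better constrained variant.  What this
scale does *not* show: converged efficiencies, the full cell-size
transition curve, or quantitative agreement with the published
full-scale values.

## Evaluation

Chemotactic efficiency compares realised arrival times to the ballistic
optimum:
$$\eta = \left\langle \frac{d_0-\delta}{v\,\tau} \right\rangle .$$
Policies are evaluated deterministically ($a_t = \mu_t$) over a horizon
decoupled from training (default $4\,t_{max}$).  Whether the average
conditions on arrival is ambiguous in the source description; the
package's default is conservative — failed runs enter the mean with
$\tau$ set to the horizon — and the alternative (condition on arrival)
is a flag, with the failure fraction always reported.  Efficiency runs
are simulated in fixed-size seeded chunks, so estimates are invariant
to how a run count is split across calls.  Standard errors are
bootstrapped over runs.

One empirical subtlety found while validating the harness: blind-agent
efficiency is *not* monotone in $D_R$.  At weak-to-intermediate
rotational noise, occasional reorientation rescues wrongly-aimed
ballistic cells, so $\eta$ peaks at intermediate $D_R$ before the
strong-noise decline; the test suite asserts monotonicity only in the
strong-noise regime where it actually holds.

## Attribution

**Integrated gradients.** The importance of input $x_i$ for the
deterministic steering output $\mu$ is
$$I_i = (x_i - x_i')\int_0^1
  \frac{\partial \pi(x' + \alpha(x-x'))}{\partial x_i}\, d\alpha,$$
with zero baseline $x' = 0$ for measurements *and* hidden state
(configurable).  The path integral uses a midpoint Riemann sum,
`n_steps = 512` by default; completeness
($\sum_i I_i = \pi(x)-\pi(x')$) is monitored with a $10^{-3}$ relative
tolerance and a warning suggests refining the grid when exceeded.  The
$\sigma$ and value heads are not attribution targets.

**Memory usage.** $U_h$ is the fraction of total absolute attribution
carried by the hidden-state inputs versus hidden plus measurements,
with previous-action attributions excluded from both sums.  It is
scale-invariant, lies in $[0,1]$, equals 0 identically for the spatial
variant (no hidden inputs) and 1 for a policy whose measurement path is
severed; it is reported as missing (flagged) in the degenerate case
where both sums vanish.  `memory_usage_map()` aggregates $U_h$ over
evaluation trajectories by cell size and concentration scale and as a
distance-to-source-resolved profile, using a coarser integration grid
per step (default 64) since $U_h$ is a ratio of aggregates and is far
less sensitive to quadrature error than completeness.

**Through-time attribution.** Because
$a_t = \pi(m_t, h_{t-1}) = \pi(m_t, m_{t-1}, \dots)$, the recurrence
can be unrolled `T_back` steps (default 300, i.e. 30 s at the default
step) from a stored hidden state and integrated gradients applied
jointly over all lagged measurement inputs plus the unroll-initial
hidden state.  Recorded actions along the unroll are held fixed on the
integration path (identically in input and baseline), so completeness
holds over the attributed inputs; the reported relative completeness
defect is normalised by the largest output change across the averaged
positions, since a per-position ratio is meaningless wherever the
action barely responds.  For the spatial variant all positive lags are
exactly zero.  For the temporal variant the network's
measurement input is the scalar mean, and the per-lag attribution is
split equally across the $K$ sensors — this preserves completeness and
realises the variant's designed sensor symmetry exactly, rather than
inheriting spurious asymmetry from whichever measurements happened to
be recorded.  Trajectories shorter than the horizon are attributed over
their available prefix and flagged.

## Numerical choices and degenerate inputs

* Sensor frame co-rotates with the body (sensor 0 on the heading);
  front/left/right semantics of attribution curves depend on it.
* Sign convention: positive action and positive attribution = left
  turn.
* $K_0$ divergence at the origin is cut off at $r = 10^{-9}$ um;
  concentration profiles are monotone decreasing everywhere.
* A Gaussian action head with $\sigma$ floored at $10^{-12}$ inside
  log-densities; zero-$\sigma$ outputs sample deterministically.
* Checkpoints serialise parameters at 17 significant digits, which
  round-trips IEEE doubles bit-exactly; version fields are checked on
  load and mismatches fail with an explicit migration error.
* Non-finite actions or losses abort with diagnostics rather than
  propagating.

## What the generator emulates — and what it does not

The synthetic world captures the physics the navigation problem turns
on: Poisson shot noise tied to absolute concentration, body-scale
gradient differences shrinking with cell size, rotational decorrelation
of the heading, and randomised episode conditions that prevent
overfitting to a particular molecule count.  It does not emulate
receptor kinetics or adaptation, correlated sensing noise,
hydrodynamics, three-dimensional motion, moving or fluctuating sources,
or heterogeneous environments.  Conclusions drawn from passing tests
therefore concern the idealised sensing-limited navigation problem, not
any particular organism.

## Known limitations

* Desk-scale training demonstrates direction, not convergence; the
  temporal variant in particular is far from its attainable efficiency
  within the scaled budget.
* Pure-R training is practical up to roughly $10^5$ episodes; the
  full-scale study design (millions of episodes, $2^{16}$-run
  evaluations) requires accelerator hardware and is out of scope.
* The kernel baseline fixes one reasonable contrast functional; fitting
  kernel shapes to measured impulse responses is left to the user via
  `kernel_weights`.
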