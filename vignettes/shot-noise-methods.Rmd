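---
title: "Exact firing statistics under inhibitory shot noise: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact firing statistics under inhibitory shot noise: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotspike)
```

## The model

A leaky integrate-and-fire (LIF) neuron evolves as

$$\dot v = -\frac{v - \mu_0}{\tau} + \sum_{\{t_e\}} a_e\,\delta(t - t_e)
          + \sum_{\{t_i\}} a_i\,\delta(t - t_i),$$

fires when $v$ reaches $v_{th}$ and resets to $v_{re}$.  Defaults are
$\tau = 20$ ms, $v_{th} = 10$ mV, $v_{re} = 5$ mV; all internal units are
mV and ms, with rates in Hz at every interface.  Arrival times are Poisson
with rates $R_e$, $R_i$; inhibitory amplitudes $a_i < 0$ are i.i.d. draws
from one of four laws — a point mass (DD), a one-sided exponential (ED), a
uniform law (UD), or a Gaussian truncated to $(-\infty, 0]$ (TGD).  The
excitatory input is either a DC current $\mu_0$ or exponentially
distributed kicks (the two cases with a closed integration limit, see
below).

Because inhibitory kicks can never carry the voltage *across* the
threshold from above, the first-passage problem remains solvable for an
arbitrary inhibitory amplitude law: the overshoot difficulty that blocks
general excitatory shot noise does not arise.

## The Laplace-space engine

All statistics rest on the bilateral Laplace transform of the free
(threshold-at-infinity) stationary voltage density, the generating function
$Z_0(s)$.  Writing the transformed synaptic flux as
$\tilde J = \tilde P\, Q(s)$ with
$Q(s) = R\,\bigl(\mathbb E[e^{s a}] - 1\bigr)/s$,

$$\log Z_0(s) = \log H_e(s) + \mu_0 s + \tau \int_0^s Q_i(u)\, du, \qquad
  H_e = (1 - s a_e)^{-\tau R_e} \text{ (kicks) or } 1 \text{ (DC)} .$$

Closed forms of the kernel integral exist for DD, ED and UD in terms of the
entire function $\mathrm{Ein}(z) = \gamma + \log z + E_1(z)$; the TGD
kernel (an erfc expression, evaluated through the scaled complementary
error function so that no overflowing exponential is ever formed) is
integrated numerically on an adaptively grown panel grid and cached in a
spline.  The engine works exclusively with $\log Z_0$ — never $Z_0$, which
grows like $e^{\mu_0 s}$ — and every integrand is assembled as
$\exp(s v - \log Z_0)$.

The stationary rate is

$$\frac{1}{\tau r_0} = \int_0^{\bar x} \frac{F(c)}{c\, Z_0(c)}\, dc,
\qquad F(s) = e^{s v_{th}} D_e(s) - e^{s v_{re}},$$

with $D_e = (1-s a_e)^{-1}$ for excitatory kicks and $1$ for DC, and
$\bar x = 1/a_e$ or $\infty$ the point where $1/Z_0$ vanishes.  Note the
sign convention: this $F$ makes the integrand positive
($F/(cZ_0) \to v_{th} - v_{re}$ as $c \to 0$) and reproduces the known
exponential-shot-noise rate, the diffusion limit, and event-driven
simulation; the package derives the full set of expansion coefficients from
scratch in the angular convention
$\hat q(\omega) = \int e^{-i\omega t} q(t)\, dt$, under which

$$\langle t\rangle = 1/r_0, \qquad
  \langle t^2\rangle = 2\Bigl(\tfrac{1}{r_0^2} - \tfrac{\tilde n_1}{r_0}
  - d_2\Bigr), \qquad
  \tilde n_1 = \tau\!\int_0^{\bar x}\!\log s\, A'(s)\, ds,\;
  d_2 = \tau^2\!\int_0^{\bar x}\!\tfrac{\log s}{s} B(s)\, ds,$$

with $A = e^{s v_{re}}/Z_0$ and $B = F/Z_0$.  The logarithmic endpoint
singularities are integrable and handled by adaptive quadrature; for
excitatory kicks the algebraic endpoint factor $(1 - s a_e)^{\tau R_e - 1}$
at $\bar x$ is flattened exactly by the substitution
$c = \bar x\,(1 - u^{1/\tau R_e})$.

```{r rate-cv}
m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
summary(m)
```

## Effective input and noise intensity

Configurations with different amplitude laws are compared at matched
effective input $\mu_T = \mu_e + \tau R_i \langle a_i\rangle$ and total
noise intensity
$\sigma^2 = \sum_x R_x \tau (\langle a_x\rangle^2 + \mathrm{var}[a_x])$.
`solve_drive()` inverts these relations: under DC drive the solution is
unique, and when it lands at $\mu_0 \le v_{th}$ the neuron can never fire
(the configuration is flagged *silent*, not rejected — the firing onset in
$\sigma^2$ depends on the amplitude law, and sits rightmost for the
longest-tailed exponential law).  For excitatory kicks the balanced
convention $R_e = R_i$, $\langle a_e\rangle = |\langle a_i\rangle|$,
$\mu_0 = \mu_T$ is used.

## Spectra and the ISI density

The spike-triggered rate in the Fourier domain is a ratio of oscillatory
integrals of $s^{i\omega\tau}$ against $dA/ds$ and $dB/ds$; then
$\hat q = \hat\rho/(1 + \hat\rho)$ and
$\hat C = r_0 (1 - |\hat q|^2)/|1 - \hat q|^2$ (with a symbolic
$\delta$-spike at $\omega = 0$ excluded from grids).  Numerically the two
integrals are evaluated on shared Gauss–Legendre panels in $u = \log s$,
with panel length tied to $\pi/\omega\tau$.  Standard renewal theory — and
the package's numerics — place the plateaus as
$\hat C \to r_0\,\mathrm{CV}^2$ at low frequency and $\hat C \to r_0$ at
high frequency; the implementation asserts the pair as a set.

Two numerical regimes require care:

* **Large $\omega\tau$ on the real axis.**  Both integrals decay like
  $e^{-\omega\tau\pi/2}$ while their ratio decays only algebraically, so
  beyond $\omega\tau \approx 20$ the real-axis quadrature returns noise.
  For DC drive with the closed-form kernels the integrand is entire and
  the contour is rotated to the ray $s = r e^{i 75^\circ}$, on which the
  envelope decays like $e^{-(\mu_0 - v_{th}) r \cos\theta}$ and no
  cancellation occurs.  The rotation becomes ill-conditioned for large
  $\tau R_i$ (the $\mu_0 s$ / $\log Z_0$ balance breaks on the ray), but in
  exactly that regime $\hat q$ decays fast and the real axis suffices:
  the hybrid rule uses the real axis for $\omega\tau \le 15$ and the
  rotated contour above.

* **The deterministic atom.**  With DC drive and $\mu_0 > v_{th}$ the ISI
  law contains an atom $p_0\,\delta(t - t^*)$ at the tonic crossing time
  $t^* = \tau\log[(\mu_0 - v_{re})/(\mu_0 - v_{th})]$, of mass
  $p_0 = e^{-R_i t^*}$ (no kick before the crossing).  The atom makes
  $\hat q$ non-decaying; it is subtracted analytically before inversion
  and reported separately.  The continuous part is reconstructed by
  inverse FFT on a 0.25 ms grid over a 2048 ms period, windowed by the
  spectral factor of a 1 ms bin and a 1 ms Gaussian taper that suppresses
  ringing from the onset discontinuities of the kick-delayed branches.

```{r isi}
isi_peak(m)
```

`isi_peak()` reports **two** characterizations of where the ISI
distribution concentrates.  For large kicks the continuous density has a
broad plateau (flat to well under 1% over tens of ms), so its literal
argmax (`mode_ms`) is a soft number; the period of the spike-train-spectrum
maximum (`spectral_period_ms`) is the sharper summary and is the quantity
quoted in the shot-noise literature for these configurations (40–41 ms at
$|a_i| = 0.1$ mV and 54 ms at $|a_i| = 1$ mV for $\mu_T = 9$ mV,
$\sigma^2 = 2$ mV$^2$).

## Diffusion approximation

The Gaussian baseline depends only on $(\mu_T, \sigma^2)$:

$$\frac{1}{r_0} = \tau\sqrt{\pi}\int_{y_r}^{y_\theta} e^{x^2}(1 +
\mathrm{erf}\,x)\,dx, \qquad
\mathrm{CV}^2 = 2\pi (r_0\tau)^2 \int_{y_r}^{y_\theta}\! dx\, e^{x^2}
\int_{-\infty}^{x}\! dy\, e^{y^2}(1 + \mathrm{erf}\,y)^2 .$$

(The $r_0^2$ belongs in the numerator — dimensional analysis and the
small-kick limit of the shot-noise engine both require it.)  Every
$e^{x^2}$ is folded into $\mathrm{erfcx}$, so the $\sigma^2 \to 0$ limits
are computable without overflow.  The shot-noise statistics converge to
these expressions as $|a_i| \to 0$ at fixed $(\mu_T, \sigma^2)$ — the
package's tests verify the convergence is monotone in the kick size.

## Event-driven simulation

The simulator integrates the model *exactly*: a single merged exponential
clock (rate $R_e + R_i$, type Bernoulli) generates events, the membrane
relaxes in closed form between them, and deterministic crossings are
resolved analytically — no time step exists anywhere.  Burn-in discards a
configurable number of initial spikes (200 by default; spike times are
referenced to the end of burn-in).  Empirical spectra are computed from
mean-removed 1 ms binned counts as $|X(f)|^2/T$ averaged over
realizations, so the high-frequency plateau estimates the rate in 1/s,
directly comparable with the analytic $\hat C$.

## Heterogeneous sparse networks

Each of $N$ neurons has an excitability $\mu(j)$, uniform on a range, and
exactly $K$ presynaptic partners; the kick sent by neuron $k$ has a fixed
amplitude $a_i(k)$ drawn once from the coupling law.  In the sparse
asynchronous regime the input to a neuron is approximately Poisson, which
closes the population description: the mean field solves

$$\bar r_0 = \frac{1}{\Delta}\int_{\{\mu_A\}} P(\mu)\,
  r_0\bigl(\mu;\, R_i = K n^* \bar r_0\bigr)\, d\mu$$

over the active set $\{\mu_A\}$ (the fraction $n^*$ of highest
excitabilities, with $\Delta$ its probability mass), by damped fixed-point
iteration (damping 0.5, tolerance $10^{-8}$ Hz) warm-started from the
diffusion solution; the excitability integral uses 24 Gauss–Legendre
nodes.  Two modelling choices deserve emphasis:

* the presynaptic rate is $K n^* \bar r_0$, not $K \bar r_0$: silent
  partners contribute no spikes, and the measured mean input rate in
  direct simulation matches $K n^* \bar r_0$ exactly.  With this closure
  the mean-field rate agrees with the $N = 400$, $K = 20$ simulation to
  within about 2% for point-mass couplings at
  $\langle|a_i|\rangle = 0.4$ mV;
* $n^*$ is an *input*, taken from simulation — the closure does not
  determine which neurons fall silent.

The mean-field CV is less faithful than the rate (population input trains
are superpositions of quasi-regular renewal processes, not Poisson, which
the closure ignores); the package documents this and the tests assert only
the rate-level agreement and the qualitative orderings.  The description
assumes asynchronous collective dynamics; no synchrony detector is built
in beyond inspecting the population spike-count variability.

## Numerical choices, in brief

* Quadratures: `stats::integrate` (QUADPACK) at `rel.tol` $10^{-9}$ to
  $10^{-10}$ for the rate/CV integrals; Gauss–Legendre panels for the
  oscillatory ones; kernel Taylor expansion below
  $|s|(|\langle a\rangle| + \mathrm{sd}) < 10^{-4}$ to avoid $0/0$.
* Special functions: real $E_1$/erfcx from pracma (with an asymptotic
  guard where pracma's erfcx overflows to NaN above $x \approx 26$);
  complex $\mathrm{Ein}$ via a power series below $|z| = 12$ and a Lentz
  continued fraction for $E_1$ beyond — needed only on the rotated
  contour.
* The Euler–Mascheroni constant enters the DD/UD normalization constants
  at full double precision; the kernel integrals are written directly in
  terms of $\mathrm{Ein}$, which makes $Z_0(0) = 1$ exact by
  construction.
* Degenerate inputs: $\sigma^2 = 0$ reduces to the tonic neuron;
  $\mu_0 \le v_{th}$ under DC drive is flagged silent with $r_0 = 0$;
  supra-threshold DC combined with excitatory kicks is refused by the
  analytic engine (no integration limit $\bar x$ exists — the known
  validity boundary of the method) and left to the simulator.

## Test problem sizes and what passing shows

The test suite validates theory against the event-driven simulator at
$10^5$ ISIs per configuration across the four amplitude laws and both
drive kinds (agreement within 3.5 standard errors, family-wise), compares
analytic and simulated spectra band-averaged over 200 realizations of 64 s
traces, and checks the network mean field against a direct $N = 400$,
$K = 20$ simulation of $2\times 10^5$ spikes.  These sizes resolve rates
and CVs to a few tenths of a percent.  The synthetic data are generated by
the package's own exact simulator — they share every modelling assumption
of the theory (instantaneous synapses, Poisson arrivals, no refractoriness),
so passing tests demonstrate the correctness of the analytics and the
implementation, not the biological adequacy of the model itself.

One reference quantity deliberately fails its quoted value: the location
of the CV minimum along the $|a_i|$ sweep at $\mu_T = 9$ mV,
$\sigma^2 = 2$ mV$^2$.  The exact curve is flat to $4\times10^{-4}$ over
$[0.65, 0.95]$ mV with argmin at $0.76$ mV (confirmed by simulation with
$2\times10^7$ ISIs per point); the commonly quoted $\simeq 0.9$ mV is not
reproducible as the argmin of this curve at these conditions.  The
existence of the interior minimum — the scientifically meaningful
statement — is asserted and holds.
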