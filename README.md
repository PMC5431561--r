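# shotspike

Exact firing-time statistics for leaky integrate-and-fire (LIF) neurons
driven by **inhibitory shot noise** — Poisson trains of instantaneous
inhibitory post-synaptic potentials with finite, distribution-drawn
amplitudes — together with the Gaussian diffusion-approximation baseline,
an exact event-driven simulator, and a self-consistent mean field for
heterogeneous sparse inhibitory networks.

The standard treatment of synaptic noise (the diffusion approximation)
assumes post-synaptic potentials are vanishingly small and arrive at high
rate, so only the mean input and noise intensity matter.  Real inhibitory
amplitudes are finite — unitary IPSPs of ~1 mV are measured routinely — and
at that scale the *shape* of the amplitude distribution changes the firing
rate, the regularity of spiking, and the spike-train spectrum in ways the
diffusion limit cannot capture.  Because downward kicks can never carry the
membrane potential across the threshold, the first-passage problem stays
exactly solvable for an **arbitrary** inhibitory amplitude law; this
package implements that solution for practitioners in computational
neuroscience who need exact single-neuron statistics, validated
simulations, or population-level closures beyond the diffusion limit.

## The method in brief

For a LIF neuron (time constant $\tau$, threshold $v_{th}$, reset
$v_{re}$) with DC drive $\mu_0$ or exponentially distributed excitatory
kicks, and inhibitory Poisson input of rate $R_i$ with amplitude density
$A_i(a)$ on $a \le 0$, the bilateral Laplace transform of the free
subthreshold voltage density is

$$Z_0(s) = H_e(s)\, \exp\Bigl(\mu_0 s + \tau\!\int_0^s Q_i(u)\,du\Bigr),
\qquad Q_i(s) = R_i\,\frac{\mathbb E[e^{s a_i}] - 1}{s},$$

and the stationary rate, the first two interspike-interval (ISI) moments
and CV, the spike-triggered rate $\hat\rho(\omega)$, the spike-train
spectrum $\hat C(\omega)$ and the ISI density all follow from quadratures
of $F(s) = e^{s v_{th}}D_e(s) - e^{s v_{re}}$ against $1/Z_0$ — evaluated
here with overflow-free log-space arithmetic, closed-form kernels for the
delta/exponential/uniform laws, a cached kernel for the truncated
Gaussian, and a rotated-contour scheme for the high-frequency oscillatory
integrals.  Supported amplitude laws: point mass (`amp_delta`), one-sided
exponential (`amp_exponential`), uniform (`amp_uniform`), upper-truncated
Gaussian (`amp_tgauss`).

## Worked example

A neuron receiving 1 mV inhibitory kicks at 100 Hz under a 11 mV DC drive
(effective input 9 mV, noise intensity 2 mV²):

```r
library(shotspike)

m <- shot_lif(amp_delta(-1), mu_T = 9, sigma2 = 2)
summary(m)
#> LIF neuron with shot-noise input
#> LIF neuron: tau = 20 ms, v_th = 10 mV, v_re = 5 mV
#> DC drive: mu0 = 11 mV
#> Inhibitory input: R_i = 100 Hz, delta amplitude (a = -1 mV)
#>   effective input mu_T = 9 mV, noise sigma2 = 2 mV^2
#>
#> Exact firing statistics:
#>   r0 = 8.9625 Hz, <t> = 111.576 ms, CV = 0.6330

st <- isi_stats(simulate_neuron(m, n_spikes = 50000, seed = 1))
#> r0 = 8.9739 +- 0.0255 Hz, CV = 0.6357 +- 0.0027   (exact event-driven sim)

c(da_rate(9, 2), da_cv(9, 2))
#> 12.0666  0.6395                                    (diffusion approximation)

isi_peak(m)
#> spectral period 53.85 ms, continuous mode 56.90 ms,
#> deterministic atom of mass 0.0278 at 35.84 ms
```

The exact rate (8.96 Hz) matches the simulation within one standard error,
while the diffusion approximation overestimates it by a third — the
signature of finite-amplitude inhibition.  The ISI distribution carries a
deterministic atom at the tonic crossing time (the no-kick trajectory), a
broad continuous plateau, and a dominant interspike period of ~54 ms read
off the spike-train-spectrum maximum.  `spike_spectrum()`, `isi_density()`
and `plot(m)` expose the full curves; `solve_drive()`/`effective_input()`
map between drive parameters and the $(\mu_T, \sigma^2)$
parameterization.

Network-level analysis follows the same pattern:

```r
cfg <- network_config(N = 400, K = 20, g_dist = amp_delta(-0.4))
sim <- simulate_network(build_network(cfg, seed = 11))
mf  <- mean_field_rate(cfg, n_star = sim$n_star)
c(sim$r_bar, mf$r_bar)    # 7.79 vs 7.91 Hz
```

A thin command-line wrapper over these functions is installed at
`inst/cli/shotspike.R` (subcommands `rate`, `cv`, `spectrum`, `isi`, `da`,
`simulate`, `network`, `fixtures`).

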