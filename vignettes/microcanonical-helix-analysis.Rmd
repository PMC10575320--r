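---
title: "Microcanonical analysis of a coarse-grained helical homopolymer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microcanonical analysis of a coarse-grained helical homopolymer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r load}
library(helixmc)
library(dplyr)
library(ggplot2)
```

This vignette walks through the full methodology implemented in `helixmc`:
the coarse-grained model, the two-dimensional replica-exchange sampler,
multiple-histogram reweighting to the density of states, microcanonical
inflection-point analysis of phase transitions, and the structural
prevalence field that separates single helices from two-helix bundles. The
chunks below use desk-scale settings so the whole document runs in minutes;
`study_grids()` provides the full-scale study presets.

## 1. The model

A homopolymer of $N$ monomers is a chain of points
$\mathbf{x}_1,\dots,\mathbf{x}_N$ in continuous space with the Hamiltonian

$$
E = S_\mathrm{FENE}\sum_{i} v_\mathrm{FENE}(r_{i,i+1})
  + S_\mathrm{LJ}\sum_{|i-j|\ge 2} v_\mathrm{LJ}(r_{ij})
  + S_\theta \sum_k \left[1-\cos(\theta_k - \theta_0)\right]
  + S_\tau \sum_l \left[1-\cos(\tau_l - \tau_0)\right]
$$

with four ingredients:

* **FENE bonds.** $v_\mathrm{FENE}(r) = \log\!\left[1 - \left(\frac{r -
  r_0}{R}\right)^2\right]$ with $r_0 = 1$ and maximum extension
  $R = 3/7$. The prefactor is fixed by matching the harmonic expansion to a
  spring constant of $98/5$, giving $S_\mathrm{FENE} = -\tfrac{98}{5}
  \cdot \tfrac{r_0^2 R^2}{2} = -1.8$ exactly.
* **Truncated and shifted Lennard-Jones** interactions between all monomer
  pairs with $|i-j| \ge 2$, with $\sigma = 2^{-1/6}$ (so the minimum sits at
  $r = 1$), cutoff $r_c = 2.5\,\sigma$, and a constant shift that makes the
  potential vanish continuously at the cutoff.
* **Bending stiffness** $S_\theta = 200$ about the reference angle
  $\theta_0 = 1.742$ (measured between successive bond vectors; a straight
  chain has $\theta = 0$).
* **Torsion stiffness** $S_\tau$ about the reference dihedral
  $\tau_0 = 0.873$, whose sign selects a right-handed helix. $S_\tau$ is
  the control parameter of the study: the sampler runs a whole ladder of
  torsion strengths side by side.

All quantities are in reduced units ($k_B = 1$).

```{r model}
p <- model_params(s_tau = 8)
p$s_fene            # exactly -1.8
helix <- ideal_helix(30, p)
energy_terms(helix, p)
```

The ideal helix zeroes the bending and torsion terms by construction; its
energy is pure Lennard-Jones attraction between monomers packed along the
helical turns.

### The bundling order parameter

Secondary structure (one helix) and tertiary structure (two packed helical
segments) are separated by the order parameter

$$
q = \frac{\sum_{|i-j| > 6} v_\mathrm{LJ}(r_{ij})}
         {\sum_{2 \le |i-j| \le 6} v_\mathrm{LJ}(r_{ij})},
$$

the ratio of long-range to short-range Lennard-Jones energy. A single helix
has almost no long-range contacts, so $q \approx 0.01$; two helical
segments folded back onto each other share a long contact interface and sit
in a band around $q \approx 0.35$–$0.45$.

```{r q}
order_q(helix, p)
```

## 2. Replica-exchange sampling

`run_grid()` runs a two-dimensional grid of Metropolis threads: one axis is
a geometric temperature ladder, the other the $S_\tau$ ladder, so
neighboring threads exchange configurations both between temperatures (at
fixed Hamiltonian) and between Hamiltonians (at fixed temperature). Each
thread performs sweeps of four move types — single-monomer displacements,
rigid tail displacements, bond-preserving bend rotations, and torsion
rotations about a bond — with acceptance by the Metropolis rule, and
proposals that stretch a bond beyond the FENE domain rejected outright.
Exchange acceptance uses the general two-Hamiltonian detailed-balance
factor, since threads can differ in both $\beta$ and $S_\tau$.

```{r simulate}
sched <- build_schedule(n = 30, t_range = c(0.2, 1.6), n_temp = 8,
                        s_tau = 8, sweeps = 4000, burn_in = 500,
                        e_bin = 0.25, q_bin = 0.02)
run <- run_grid(sched, p, seed = 7)
glance(run)
```

Runs are bitwise reproducible from `(schedule, seed)`. `tidy(run)` exposes
the per-sweep energy and order-parameter traces for all threads.

## 3. From histograms to the density of states

Each thread deposits one `(E, q)` observation per production sweep into
binned histograms. Multiple-histogram reweighting (WHAM) combines the
energy histograms of all temperatures into a single density of states
$g(E)$, iterating the coupled equations for $g$ and the per-thread
partition functions in log space until the partition-function estimates
stop moving:

```{r wham}
h <- energy_histograms(run)
dos <- wham(h)
glance(dos)
```

From $g(E)$, canonical expectations at any temperature follow by
back-reweighting — the mean energy and the specific heat both as a
fluctuation and as a temperature derivative:

```{r canonical}
can <- canonical_observables(dos, seq(0.2, 1.6, length.out = 120))
can[which.max(can$cv), ]
```

## 4. Microcanonical inflection-point analysis

The microcanonical entropy $S(E) = \log g(E)$ and its derivatives
$\beta(E) = S'(E)$, $\gamma(E) = S''(E)$, $\delta(E) = S'''(E)$ carry the
transition signals: a first-order transition shows as a backbending region
($\gamma > 0$), a second-order transition as a least-sensitive inflection
of $\beta$ (a peak of $\gamma$ below zero), and third/fourth-order
transitions as the analogous structures one and two derivative levels
higher. Because numerical derivatives of sampled curves are noisy, the
derivatives are estimated by Savitzky–Golay filtering — local polynomial
fits whose analytic derivatives are exact for polynomial signals up to the
fit order:

```{r analysis}
curves <- smooth_derivatives(entropy_from_dos(dos), window = 31)
detect_transitions(curves)
```

The detector's calibration is validated in the test suite against
synthetic entropy curves with planted transitions of known order and
location (`planted_entropy()`), where it attains $\ge 95\%$ recall and
order accuracy across orders 1–4.

A desk-scale run like the one above gives a coarse, but already structured,
transition report; converged locations need the longer presets. On
full-length runs of this model at $S_\tau = 8$ the analysis finds a strong
low-energy signal near $E \approx -43$ classified as first order (the
helix-pair collapses into a tightly packed bundle with compressed bonds, see
Section 6) and a high-energy coil transition near $E \approx 5.8$.

## 5. Structural prevalence

The two-dimensional density of states $g(E, q)$ — reweighted from the
joint histograms with the same per-thread partition functions — yields the
*prevalence field* $p(E, q) = g(E, q)/g(E)$: within each microcanonical
ensemble, the fraction of configurations whose order parameter falls in
each $q$ bin. Heat maps of $p$ show which structure type dominates at each
energy, and constant-$q$ cross-sections track single helices
($q \approx 0.01$), bundles ($q \gtrsim 0.3$), and the intermediate
structures that are progressively suppressed as the torsion stiffness
grows.

```{r prevalence}
d2 <- wham_2d(joint_histograms(run), dos)
prev <- prevalence_field(d2)
autoplot(prev)
```

## 6. The two-helix bundle and the compressed-bond ground state

`two_helix_template()` builds a deterministic bundle seed: two antiparallel
ideal-helix segments at Lennard-Jones contact, joined by a slightly bowed
turn (an exactly straight turn would make the turn dihedrals numerically
degenerate). The seed is intentionally strained; a short low-temperature
relaxation equilibrates it into the bundle band:

```{r template}
tmpl <- two_helix_template(30, p)
relax_sched <- build_schedule(n = 30, n_temp = 1, t_range = c(0.2, 0.2),
                              s_tau = 8, sweeps = 3000, burn_in = 0,
                              tune_steps = FALSE,
                              move_mix = c(local = 0.8, global = 0,
                                           bend = 0.1, torsion = 0.1),
                              local_step = 0.1, max_bend = 0.1,
                              max_torsion = 0.1)
relax <- run_thread_sweeps(tmpl, p, beta = 5, n_sweeps = 3000,
                           schedule = relax_sched)
mean(relax$trace$q[2001:3000])
```

A physical note on this model's low-energy states: the FENE bond is soft
(effective spring constant $98/5$) relative to the stiffness of the packed
Lennard-Jones interface, so equilibrated bundles compress their bonds to
roughly $0.7\,r_0$ to tighten the inter-segment packing. This compression
strengthens the short-range Lennard-Jones denominator of $q$ less than it
strengthens the long-range interface numerator, and relaxed bundles of this
Hamiltonian therefore equilibrate near $q \approx 0.42$–$0.45$ — at the
upper edge of, rather than centered in, the classic bundle band near
$0.35$. The package reports what the model produces; the fixture
documentation and the acceptance measurements both record this behavior.

Increasing $S_\tau$ stiffens the helices until the turn becomes too
expensive: by $S_\tau = 14$ the lowest-energy structures are single helices
with $q \approx 0$, while for $S_\tau$ between 5 and 12 they are bundles.

## 7. One-command pipeline

`pipeline_run()` chains every stage — simulate, reweight (1D and 2D),
entropy analysis, transition detection, prevalence, canonical tables — and
optionally persists all artifacts (TSV/JSON/XYZ plus a manifest) for a
configuration loaded from YAML. The same pipeline backs the `helixmc`
command-line tool in `inst/cli/`.

```{r pipeline, eval = FALSE}
cfg <- default_config()
cfg$n_monomers <- 10; cfg$n_temp <- 4; cfg$sweeps <- 500
cfg$burn_in <- 50; cfg$e_bin <- 0.5; cfg$window <- 21
pl <- pipeline_run(cfg, out_dir = "helixmc-out")
pl$results$s_tau_8$transitions
```
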