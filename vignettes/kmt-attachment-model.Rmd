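---
title: "A discrete-time Markov chain model of kinetochore-microtubule attachment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-time Markov chain model of kinetochore-microtubule attachment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biorient)
```

## The model

Faithful chromosome segregation requires *bi-orientation*: the two
kinetochores of a chromosome pair (sister chromatids in mitosis, a
bivalent in meiosis I) must end up attached exclusively to microtubules
from opposite spindle poles. The attachment process is highly dynamic,
with frequent binding and unbinding of kinetochore microtubules (kMTs),
and erroneous intermediate configurations are common.

`biorient` implements a discrete-time Markov chain over the joint
attachment state of a kinetochore pair. Each kinetochore can hold at most
$n$ kMTs; a state is the count 4-tuple $(i_1, j_1, i_2, j_2)$ of left-
and right-pole kMTs on kinetochore 1 and 2, with $i_m + j_m \le n$. The
state space therefore has $\left(\tfrac{(n+1)(n+2)}{2}\right)^2$ states
(4,356 at the headline $n = 10$). Every state belongs to exactly one of
five classes:

| class | name       | definition |
|-------|------------|------------|
| 1     | free       | no attachments at all |
| 2     | monotelic  | exactly one kinetochore attached, to a single pole |
| 3     | syntelic   | both kinetochores attached, to the same pole |
| 4     | merotelic  | some kinetochore attached to both poles |
| 5     | amphitelic | one kinetochore left-only, the other right-only (correct) |

Merotelic takes precedence: a state with any dual-pole kinetochore is
class 4 regardless of the other kinetochore.

Each time step performs at most one elementary event. The base
probabilities reflect attachment proportional to free kinetochore surface
and occupancy-independent detachment per kMT:

* attachment of one microtubule from either pole to kinetochore $m$:
  $\frac{n - i_m - j_m}{n}\, p$ per pole,
* detachment of one left-pole kMT from kinetochore $m$: $i_m q$
  (right-pole: $j_m q$).

Residual probability stays on the self-loop. The admissible ranges
$0 \le p \le 1/4$ and $0 \le q \le 1/(2n)$ make the total exit
probability of every state at most 1, so this single-event-per-step
reading is exactly conservative; the constructor `kmt_params()` enforces
the bounds.

Three dimensionless factors rescale particular class transitions
(applied multiplicatively on the base probability):

* $\alpha \in [0,1]$ — attachments that take an amphitelic state to a
  merotelic one, modelling the physical constraint on a bi-oriented pair.
  Correct-pole attachments within class 5 are *not* scaled. In mitosis
  $\alpha = 0$.
* $\beta \in [0,1]$ — every detachment event originating in class 5
  (whether the target is monotelic or still amphitelic), modelling kMT
  stabilisation by inter-kinetochore tension.
* $\gamma \in [0,1]$ — attachments that take a monotelic state to a
  syntelic or merotelic one, modelling the back-to-back geometry of
  sister kinetochores in mitosis. In meiosis I $\gamma = 1$; the
  conventional mitotic value is $0.1$. A monotelic-to-amphitelic
  attachment is never scaled.

With $\alpha = \beta = 0$, class 5 cannot be exited and the chain is
eventually absorbed in the two fully occupied amphitelic states
$(n,0,0,n)$ and $(0,n,n,0)$.

All times are in dimensionless chain steps; all probabilities are per
step.

## Exact analyses

`build_kernel()` assembles the sparse row-stochastic one-step matrix
(rows sum to 1 within $10^{-12}$; every off-diagonal transition changes
exactly one count by $\pm 1$). On top of it:

* `propagate()` computes the exact law at times $0..T$ by repeated
  sparse vector-matrix products.
* `mean_first_passage_time()` makes the target class absorbing and
  solves $(I - Q)\,t = \mathbf{1}$ on the transient block. Because
  $\alpha$ and $\beta$ only scale transitions *out of* class 5, the MFPT
  to class 5 is exactly independent of both.
* `stationary_distribution()` solves the balance equations
  $\pi K = \pi$, $\sum_i \pi_i = 1$. It refuses the $\beta = 0$ regime,
  where multiple closed classes exist, and directs the caller to
  `absorption_statistics()`.
* `absorption_statistics()` returns expected visit counts
  (a row of the fundamental matrix $N = (I-Q)^{-1}$) and absorbing-state
  hitting probabilities $N R$.
* `biorientation_attempts()` counts the expected number of entries into
  class 5 from class 2 or 4 before absorption (defined for $\beta = 0$):
  $\sum_{u, v} N[s_0, u]\, K[u, v]$ over transient $u$ in classes
  $\{2, 4\}$ and $v$ in class 5. At $\alpha = 0$ it is exactly 1, since
  class 5 is never exited.

### Numerical choices

The natural lexicographic state order produces heavy fill-in under
sparse LU, so every linear solve uses an AMD fill-reducing ordering on
$A + A^\top$ (`Matrix::lu(order = 1)`); this cut the $n = 10$
first-passage solve from roughly 3.5 s to 0.4 s. The stationary law is
computed by the reference-state formulation — fix $\pi$ at the empty
state, solve the reduced sparse system, renormalise — rather than by
replacing a balance row with an all-ones normalisation row, whose dense
row defeats the ordering. Solver residuals ($\max |\pi K - \pi|$, row
sums) are checked at $10^{-10}$ and $10^{-12}$ respectively. Stationary
entries negative by less than $10^{-12}$ (round-off) are clipped to zero
and the vector renormalised; at the exact parameter corner
$p = 1/4, q = 1/(2n)$ a self-loop of $-2\cdot10^{-16}$ is clamped to 0.
Absorbing states are identified structurally (rows with no off-diagonal
mass), which is exact because blocked events have probability exactly 0.

## Observables

`class_probabilities()` aggregates a trajectory into the five classes.
`kmt_density()` accumulates mass on the $(i_1+j_1) \times (i_2+j_2)$
occupancy grid, by default *unnormalised* within the selected class
subset so that the class-5 table plus the class-1..4 table reproduces the
full density cellwise (a normalised variant sits behind
`normalize = TRUE`). `mean_kmt()` returns the conditional mean and
standard deviation of the per-kinetochore count; the standard deviation
is computed exactly from the conditional distribution.

For $k$ chromosome pairs evolving as independent copies of the chain,
the probability of *synchrony* (all pairs simultaneously amphitelic) at
time $t$ is $\theta_t^k$ where $\theta_t$ is the single-pair class-5
probability (`synchrony_curve()`, default $\theta_t$ from the chain
started at the empty state). `steady_state_synchrony()` returns the
stationary class-5 probability to the $k$-th power, or 1 when
$\beta = 0$ (the absorbing amphitelic regime).

### Half-life of synchrony: a design decision

"Half-life of synchrony at steady state" admits more than one reading;
this package exposes the dwell-time one: start each of the $k$ pairs
from the stationary distribution conditioned on class 5, and find the
smallest duration $s$ (linearly interpolated between integer steps) at
which the probability that *all* pairs have remained continuously
amphitelic for $s$ steps falls to $1/2$. Per-pair persistence is the
survival function of the substochastic restriction of the kernel to
class-5 states. We chose this definition because it is the standard
dwell-time reading of "synchrony maintained for a sufficient time"; a
relaxation-time reading (spectral) would measure the approach to
equilibrium instead and is not exposed. In the geometric-decay regime
the joint half-life scales like $1/k$, and it is infinite when
$\alpha = \beta = 0$.

## Closed forms

In the fully unscaled regime $\alpha = \beta = \gamma = 1$ the two
kinetochores decouple and each follows a reversible occupancy process
whose stationary law is trinomial over (left, right, free) slots with
per-slot odds $p/(nq)$. The stationary mean kMT count per kinetochore is

$$\bar N = \frac{n\rho}{n + \rho}, \qquad \rho = \frac{2p}{q},$$

so $\bar N = 5/3$ at $p = q$, $n = 10$ (`steady_state_mean_kmt()`; the
test suite verifies the trinomial law against the exact stationary
marginal to total-variation $10^{-10}$). For the $\alpha = 0$ regime the
mean occupancy *conditional on the amphitelic class* has the analytical
approximation

$$\bar N_5 = \frac{\bar\rho\,(\bar\rho/n + 2)^{n-1}}
                 {(\bar\rho/n + 2)^{n} - 2^{n}},
  \qquad \bar\rho = \frac{2p}{\beta q},$$

implemented in `amphitelic_mean_kmt_approx()` with $2^n$ factored out
and a log-space branch for large $\bar\rho/n$ (capacities up to
$n = 40$ and small $\beta q$ are routine), so the $\beta \to 0^+$ limit
returns $n$ without overflow. It is an approximation: the suite
*characterises* its error against the exact class-5 conditional mean
(a few percent at moderate $n$) rather than asserting a universal bound.

## The Monte Carlo oracle

`simulate_paths()` draws sample paths without ever touching the
assembled matrix: each step recomputes the eight event probabilities
from the elementary rules and partitions a single uniform draw over the
documented event order (attach L/R on kinetochore 1, attach L/R on
kinetochore 2, the four detachments in the same order, self-loop).
Replicate $r$ consumes uniforms from its own Mersenne-Twister stream
seeded with `seed + r`, so any replicate is individually reproducible
regardless of batch size, while the time loop is vectorised across
replicates for speed. This makes the simulator an
implementation-independent cross-check of the exact analyses: the suite
verifies one-step frequencies against a kernel row by chi-square at
$10^5$ draws, class frequencies against exact propagation at $10^4$
replicates, and the empirical MFPT against the linear solve.

The simulator emulates the chain exactly as specified — it is an oracle
for the mathematics, not a biological data generator. Like the model
itself it omits spatial search-and-capture geometry, microtubule
dynamics within a step, inter-chromosome coupling, and explicit spindle
assembly checkpoint biochemistry; agreement between simulator and solver
validates the implementation, not the model's fidelity to any particular
cell type.

## Problem sizes and test design

The exact analyses at the headline $n = 10$ (4,356 states) take well
under a second per solve. The test suite audits the full kernel,
propagation, first-passage and stationary solvers against a dense
brute-force reference implementation at $n = 2$ (36 states) written
independently (pattern-string classification, explicit event loops,
dense `solve()`/`eigen()`), and runs the structural property checks at
$n \in \{2,\dots,6\}$ where dense linear algebra is instant. Monte Carlo
comparisons use $10^4$ replicates over 200 steps at $n = 10$ and $10^5$
single-step draws, sizes at which binomial standard errors are a few
times $10^{-3}$ — small enough to detect real discrepancies while
keeping the whole suite in tens of seconds.

## Limitations

* The chain is a single-step-per-tick approximation; simultaneous events
  within one step are excluded by construction (consistent with the
  parameter bounds, which make the exit mass at most 1).
* $k$ chromosome pairs are assumed independent; no checkpoint-mediated
  coupling.
* `amphitelic_mean_kmt_approx()` is only meaningful in the $\alpha = 0$
  regime and is an approximation even there.
* The half-life of synchrony is the dwell-time definition above;
  alternative readings would give different numbers.
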