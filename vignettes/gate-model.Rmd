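---
title: "A multiplicative threshold gate for replication initiation: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiplicative threshold gate for replication initiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repgate)
```

## The model

repgate treats the decision to begin DNA replication as a conjunctive,
threshold-governed event rather than a graded accumulation. Four normalized
control variables summarize the cell's readiness:

* **A** — origin-licensing architecture: ORC/MCM occupancy, pre-RC
  integrity, density of licensed origins;
* **D** — metabolic and kinase drive: CDK2/CDK4-6 activity, ATP and dNTP
  pools;
* **C** — chromatin context: accessibility and nuclear topology
  (euchromatin high, heterochromatin and lamina-associated domains low);
* **phi** — cell-cycle phase permissiveness: near 0 in G0 and mitosis,
  near 1 in late G1/S, transiently lowered by checkpoint signalling.

All four live on $[0,1]$ after min–max scaling of their raw assay
correlates. Initiation occurs when the product crosses a threshold:

$$\text{fire} \iff \phi \, A \, D \, C \;\ge\; T, \qquad T \in (0,1].$$

The multiplicative form makes every component a *necessary* condition: if
any factor is 0 the product is 0 and initiation is categorically blocked
($1 \times 1 \times 0 = 0$), no matter how large the others are. This is
the "zero-veto", and it is what distinguishes the gate from an additive
score, which always lets a strong component compensate for an absent one.
The same algebra produces synergy: two partial reductions that are each
individually tolerated (e.g. $0.6 \ge T = 0.5$) can jointly abolish
initiation ($0.6 \times 0.6 = 0.36 < 0.5$).

For stochastic settings the hard step is smoothed into a Hill response

$$h(s) = \frac{s^k}{s^k + T^k},$$

which is exactly $1/2$ at $s = T$, preserves $h(0)=0$ (the veto survives
smoothing), and converges pointwise to the hard gate as the sharpness $k$
grows. We compute it as $1/(1+(T/s)^k)$, which is stable for large $k$
where $s^k$ underflows.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `threshold` (T) | minimum combined readiness | 0.5 | center of the normalized range; no empirical calibration exists yet |
| `sharpness` (k) | Hill exponent of the graded response | 8 | a steep but smooth switch; the hard gate is the $k\to\infty$ limit |
| beta shapes | cell-to-cell spread of A, D, C | Beta(2, 2) | symmetric, mid-spread heterogeneity; components sampled independently |
| `k_act`, `gamma` | activation/decay gains of $dR/dt$ (1/h) | 1, 1 | order-one kinetics on the hour scale of a mammalian cycle |
| `dt` | Euler step (h) | 0.01 | divides all default phase durations; $\ll$ any dynamic time scale |
| phase levels | permissiveness per phase | G0/M 0.01, early G1 0.3, late G1/S 1.0, G2 0.3 | "essentially vetoed" in mitosis, maximal at the G1/S boundary |
| `noise_sd` | per-step (cycle) or per-cell (perturbation) component jitter | 0 / 0.05 | perturbation-experiment noise matches the discrimination study's stated spread |

The default cell cycle is G1 10 h, S 8 h, G2 4 h, M 1 h (a 23 h
mammalian-like cycle). G1 permissiveness ramps linearly from 0.3 to 1.0 by
default so that threshold-crossing times are non-degenerate: origins with
larger $A\,D\,C$ products cross earlier on the ramp, which is how
early/late replication-timing domains emerge from the same gate without a
dedicated timing program. A note on the step size: an earlier internal
default tied `dt` to 1% of the total cycle, but that cannot divide the
default segment durations (23/100 h does not divide 10 h), violating the
integrator's own precondition; `dt` is therefore a fixed 0.01 h, which is
finer and divides every default segment.

## Cell-cycle dynamics

The aggregate readiness variable $R$ follows

$$\frac{dR}{dt} = k_{act}\, h(s(t)) - \gamma R,$$

with $s(t) = \phi(t)\,A(t)\,D(t)\,C(t)$. The forms of activation and decay
are the simplest pair consistent with an activation-minus-feedback
formulation: a saturating drive through the graded gate response and linear
relaxation. With constant score the closed form $R_\infty = k_{act}
h(s)/\gamma$ is reached within $e^{-10}$ at $t = 10/\gamma$, which the test
suite checks against the integrator at 1% tolerance.

Per-origin gates use each origin's own $(A_i, D_i, C_i, T_i)$. Three rules
enforce once-per-cycle replication: an origin that fires is consumed
(removed from the licensed pool and never refired), the aggregate licensing
component declines in proportion to the remaining licensed fraction, and no
relicensing occurs inside the cycle. Mitotic firing is excluded not by a
special case but by the schedule itself: at the M-phase floor
($\phi = 0.01$) no sub-unit component product can reach a default-scale
threshold.

Checkpoint events multiply both permissiveness and drive by configurable
scales over a time window (ATR/ATM signalling inhibits CDK activity and
lowers permissiveness); overlapping events compose multiplicatively.
Recovery is a step back to the scheduled level when the window ends — the
source material does not resolve step versus gradual recovery, and the
step is the simpler choice; a gradual variant can be emulated by chaining
windows with increasing scales. Because arrest only rescales components,
it delays threshold crossings rather than abolishing them: the set of
origins that ever fire is unchanged whenever enough permissive time
remains after the window, which is the reversibility property the
acceptance suite asserts.

Per-step noise in the cycle simulator is one Gaussian draw per component
per step, *shared across origins*: the components are cell-level state
(kinase activity, global accessibility), so their fluctuations move all
origins of the nucleus together. Independent per-origin noise would be a
different biological claim (local chromatin fluctuation) and is not
implemented.

## Populations, bimodality, and the quadrature oracle

Sampling $A, D, C \sim$ Beta and evaluating the hard gate per cell splits a
population into two discrete classes — initiating and not — even though
every underlying component is continuous. Near the threshold this produces
the characteristic bimodal (bistable-looking) population structure:
ensemble averaging over cells then yields smooth "gradients of replication
probability" at the bulk level while every single cell remains binary.
Bimodality is quantified by Sarle's coefficient
$BC = (g_1^2+1)\big/\!\left(g_2 + \tfrac{3(n-1)^2}{(n-2)(n-3)}\right)$ on
the graded response, with the conventional 5/9 benchmark; a zero-variance
sample has undefined moments and is reported as `NA` rather than silently
coerced.

Monte-Carlo initiation fractions are audited against a deterministic
oracle: $P(\phi A D C \ge T)$ computed by midpoint tensor-grid quadrature
over the beta components, with the last beta dimension integrated exactly
through its survival function. The semi-analytic last dimension makes the
oracle accurate to well below one Monte-Carlo standard error at the default
resolution (400 cells per integrated axis), and halving/doubling the
resolution moves the value by less than $5\times10^{-4}$ in the tested
configurations. The oracle shares no code with the sampler.

Reproducibility: each population draw derives four child seeds from the
root seed in the fixed order A, D, C, phi, so editing one component's
distribution leaves the other streams untouched.

## The perturbation experiment and model discrimination

The factorial design crosses multiplicative scalings of A (partial ORC/MCM
depletion), D (CDK inhibition or nucleotide depletion) and C (chromatin
compaction) around a baseline state, defaulting to a
$3 \times 2 \times 2$ layout with scales $\{1, 0.7, 0.4\}$, $\{1, 0.5\}$,
$\{1, 0.5\}$. Readouts are binomial counts of initiating cells; the
generative truth is either the multiplicative gate or an additive
comparator that fires when $\phi\,(A+D+C)/3 \ge T$ (the division by 3 puts
both rules on the same $[0,1]$ scale; the source frames the additive model
as an unweighted sum, and weighted variants would only sharpen the
contrast).

Both candidate models are fitted by binomial maximum likelihood with the
Hill response as the link from the model's combined condition score to
firing probability, threshold and sharpness free, L-BFGS-B on a
transformed scale (logit threshold, log sharpness) from a fixed grid of
ten starts. Model choice is by
$\Delta AIC = AIC_{add} - AIC_{mult}$.

One numerical choice deserves a full account: **the fitted sharpness is
capped at 50**. The twelve condition scores are finitely spaced; once the
exponent is large enough that the Hill curve rises from ~0 to ~1 between
two adjacent condition scores, further increases change nothing the data
can see. The profile likelihood in $k$ therefore goes flat, and an
unconstrained ML estimate drifts to whatever box bound is supplied —
letting the *misspecified* combination rule fake a step function through
the observed pattern and neutralizing the AIC comparison (both "models"
degenerate into step functions with a movable edge). Capping the exponent
at 50 — about six-fold above the generative default of 8, and inside a
broad plateau (roughly 40–64) where the discrimination study is stable —
restores identifiability. Bounded slope parameters are standard practice
in dose–response fitting for exactly this reason. With the cap, the
correct generative model is preferred in at least 95% of replicates for
each truth at the default design, 1000 cells per condition and component
noise 0.05 (the acceptance suite runs this at 100 replicates per truth),
and the fitted threshold recovers the generative value within ±0.05
(median).

Supra-additive inhibition is scored against a Bliss-style expectation: for
a combination of $m$ single perturbations with observed fractions $f_j$
and baseline $f_0$, the expectation is $\prod_j f_j / f_0^{\,m-1}$
(clipped to $[0,1]$), and the index is expectation minus observation. For
a pair this is the familiar $f_1 f_2 / f_0$. Under the gate with baseline
all-1 and $T = 0.5$, single 0.6-scalings of D or C each leave the fraction
at 1 while the combination yields 0, so the index attains its maximal
value 1 — the clean signature separating multiplicative from additive
logic. Under additive truth the same design gives an index within sampling
error of 0.

## What the synthetic data does and does not establish

The fixture generator emulates pre-summarized assay tables (occupancy
counts, kinase activity units, accessibility scores, a checkpoint
reporter) for three qualitative regimes — stem-like (everything high,
checkpoints attenuated), quiescent (licensed but unpowered: A high, D and
phi low), stressed (phi suppressed, D partially suppressed) — as truncated
Gaussians on the normalized scale mapped onto plausible raw ranges. It
reproduces regime *means and spreads only*. Real single-cell data differ
in ways the generator deliberately omits: components are interdependent
in vivo (metabolism remodels chromatin; checkpoints touch licensing and
drive at once), distributions are not symmetric beta/Gaussian, origins
interact spatially, and measurement noise is assay-specific. A green test
against this generator therefore establishes internal consistency of the
gate machinery — not that any real cell type obeys a multiplicative gate.
Estimating $T$ from real experiments is explicitly out of scope.

## Numerical choices and degenerate inputs

* **Boundary inclusive**: firing at score exactly $T$ counts as fired.
* **Threshold surface**: $C^* = T/(\phi A D)$ is nudged upward by at most a
  few ulps so that the returned $C^*$ actually fires under floating-point
  evaluation of the product; "unreachable" ($\phi A D < T$) and
  "zero-veto" ($\phi A D = 0$) are distinct explicit outcomes.
* **Integration**: explicit fixed-step Euler; adequate for a monotone
  scalar ODE, transparent, and testable against the closed form. `dt`
  must divide every segment duration (checked with a $10^{-8}$ relative
  tolerance).
* **Ties and degenerate fits**: readouts whose fractions are identical in
  every condition (all-fire or all-quiescent) carry no threshold
  information and are flagged degenerate instead of fitted; an exact AIC
  tie is reported "inconclusive" rather than forced to a side.
* **Empty origin sets** simulate cleanly with no firings; an all-G0
  schedule decays $R$ to 0 and fires nothing.
* **Determinism**: noise-free runs are bit-reproducible; stochastic paths
  are reproducible given the seed; fits are deterministic given data (no
  random restarts).

## Known limitations

* Components are sampled independently; in-vivo interdependence is real
  but unmodeled (a correlation extension would need a stated joint model).
* The additive comparator is the unweighted mean; weighted sums are
  possible in principle but not exposed as defaults.
* Checkpoint recovery is a step, not a ramp.
* No replication-fork elongation, genome coordinates, or rereplication
  pathology beyond the licensing veto; no inference from real sequencing
  or imaging data.
* Stochastic per-step firing (Bernoulli at the graded response) is
  available behind a flag, but its effective rate depends on `dt`; the
  deterministic crossing rule is the supported default.
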