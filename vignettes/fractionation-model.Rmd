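---
title: "Modelling biased fractionation after whole genome duplication"
author: "fractorun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling biased fractionation after whole genome duplication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractorun)
```

## The process being modelled

Whole genome duplication (WGD) leaves a genome with two identical
homeologous copies of every chromosome. Over time most duplicate gene
pairs lose one member — *fractionation* — but almost never both, because
at least one functional copy must survive. The observable outcome, after
aligning the two homeologs, is a pair of binary presence/absence sequences
$G$ and $H$ with $g(i) + h(i) \ge 1$ at every gene position $i$:
alternating *runs* of duplicated positions and consolidated *runs* of
single-copy positions.

`fractorun` implements a null model for this process in which deletion
events excise a geometrically distributed number of contiguous genes:

* an event is *anchored* at a position where both copies survive, chosen
  uniformly among such positions;
* with probability $\phi$ it falls on chromosome 1 ($G$), with $1-\phi$ on
  chromosome 2 — $\phi$ is the *fractionation bias*;
* its drawn length $a$ follows $\gamma(a) = \frac{1}{\mu}\left(1 -
  \frac{1}{\mu}\right)^{a-1}$, $a \ge 1$, with mean $\mu$;
* scanning rightward, positions already deleted on the same chromosome
  are *skipped* without counting toward $a$ (excised DNA is invisible to
  later deletions), while the first position already deleted on the
  *other* chromosome *blocks* the event (deleting it would destroy the
  last copy of a gene).

Each single-copy run is therefore the product of some number $r \ge 1$ of
deletion events — the central unobservable of the model. The package
tracks $r$ exactly in simulation by logging the event identifier of every
deleted position, and computes the distribution $\pi(r)$ deterministically
by a recurrence. The state of the process is summarized by the duplicate
proportion $\theta$, the mean single-copy run length $\bar u$, the mean
duplicate run length $\bar v$ (linked by $\bar v = \frac{\theta}{1 -
\theta}\bar u$), and $\tau(r)$, the proportion of $r$-event runs carrying
deletions from both homeologs.

Time never appears: the event count (equivalently $\theta$) is the clock.
The simulator uses a discrete event loop for the same reason — a
continuous-time intensity would only serve to separate events.

## Event types and the recurrence

Between consecutive states, each deletion event acts in one of a small
number of ways, classified by how many pre-existing single-copy runs it
absorbs:

* **A** — falls strictly inside a duplicate run: a new run with $r = 1$;
* **B** — extends the run immediately left of its anchor ($r \to r + 1$);
* **C** — reaches the run to its right ($r \to r+1$), either skipping into
  it (same chromosome) or being blocked at it (other chromosome content);
* **D** — skips through the right-hand run entirely and also absorbs the
  run beyond it (merging two runs into one with $r + s + 1$ events);
* **E** — touches the left run *and* reaches the right run (again a
  merger);
* **other** — absorbs three or more runs; its probability is reported but
  deliberately not fed back into the recurrence, which bounds the model's
  validity at small $\theta$.

The probability of each type, with all chromosome sub-labels, follows from
three modelling assumptions: anchors are uniform on duplicate positions;
duplicate-run lengths are geometric with mean $\bar v$ (checked by
goodness-of-fit against simulation output — see `geometricGofTest`); and
successive duplicate runs are independent. `computeRates()` evaluates the
resulting expressions. Three evaluation paths are provided:

* `method = "separable"` (the default used by `runRecurrence`): the sums
  over anchor position and event length are collapsed analytically using
  the closed-form geometric tail $\sum_{a \ge x}\gamma(a) = (1 -
  1/\mu)^{x-1}$, after which the remaining run-length sums either factor
  completely or reduce to an $O(M^2)$ convolution, where $M$ is the range
  over which $\gamma$ has non-negligible mass. This is what makes the
  deep triple-run-length sums (type D) tractable at $\bar v$ in the
  thousands.
* `method = "collected"` and `method = "naive"`: the collected-term and
  fully nested (as-printed) forms of the formulas for the A, C-same and
  D-same families, on an explicitly truncated support. They exist purely
  as cross-checks; the test suite verifies all three agree to $10^{-12}$.

`deltaPi()` and `deltaTau()` turn the rates into per-event changes of the
run-count distribution and of the both-chromosome counts, and
`advanceState()` applies $\Lambda$ events per macro-step. The update is
constructed so two identities hold *exactly* at every step: total gene
count $R(\bar u + \bar v)$ is conserved, and $\bar v = \frac{\theta}{1 -
\theta}\bar u$.

### Choices that were genuinely open

**Merger bookkeeping (`conservationMode`).** The as-printed update system for
$\pi$ credits each two-run merger to the gain term with coefficient
$2(p_D + p_E)$, while removing two runs via the loss terms; summing the
system then yields a total run-count change of $p_A$, i.e. mergers would
not reduce the number of runs. Per-event bookkeeping says a merger
consumes two runs and creates one, so the net change should be $p_A -
(p_D + p_E)$. The default mode `"corrected"` therefore halves the merger
gain coefficient; `"as_printed"` implements the as-printed equations
literally. The validation harness (`compareRecurrenceToSimulation`)
selects the default: in corrected mode the recurrence's event-type
trajectories track 100-replicate simulation means within a few
hundredths, at all three parameter corners exercised.

**Misprint repairs (`typos`).** Two expressions in the as-printed
$\delta_\tau$ system are taken as misprints: a term reading
"$p_{B12} + p_{B12}$" (read as $p_{B12} + p_{B21}$, by symmetry with the
accompanying $p_{C12} + p_{C21}$) and a factor "$(1 - r(r-1))$" (read as
$(1 - \tau(r-1))$, the only dimensionally consistent reading and the
exact analogue of the $r = 2$ equation). The literal forms remain
available behind `typos = "as_printed"` for audit. Similarly, three
summation bounds in the mean-length contribution formulas contain obvious
slips (`1-j+1` for `l-j+1`, and so on); they are read in parallel with
their companion probability formulas.

**Scalar vs per-$r$ mixing proportion.** The rate formulas use an
argument-free $\tau$; the update system uses $\tau(r)$. The only
consistent reading, adopted here, is that the scalar entering the rates
is $\tau = \sum_r \tau(r)\pi(r)$.

**Initialization.** The recurrence cannot start at $\theta = 1$ (no runs
exist, $\bar v$ is undefined). It starts at `thetaStart = 0.99` with $\pi
= (1, 0, \dots)$, $\tau \equiv 0$, $\bar u = \mu$ and $\bar v$ from the
accounting identity: at $\theta \approx 1$ essentially every event is
type A and blocking is negligible, so new runs are single events with
mean length $\mu$. The carrier $R$ starts at 1 and cancels from every
reported proportion.

**Step size.** `lambda = "auto"` chooses each macro-step so that the run
count changes by at most 1% — a large fixed $\Lambda$ visibly lags the
simulation, which is also the main discrepancy mode reported for the
original implementation.

**Truncations.** The supports of $\gamma$ and $\rho$ are cut where their
tail mass falls below `tailEpsilon` ($10^{-10}$ by default) and $\rho$ is
renormalized; infinite $\gamma$ tails are always evaluated in closed form
rather than truncated. The $\pi$ support grows on demand whenever mass
approaches its bound.

## What the simulator emulates — and what it does not

`runSimulation` reproduces the study conditions: an interval of length
100,000 (large enough that boundary effects are negligible — runs touching
the ends are nevertheless included in statistics, and events clipped by
the right end keep their realized deletions), anchors uniform among
duplicate positions, and 100 replicates per parameter setting for the
validation comparisons. Checkpoints are expressed in $\theta$; event-type
tallies are accumulated per window between checkpoints, which is what the
comparison harness aligns against the recurrence (interpolated at window
midpoints on the $1 - \theta$ axis).

Real post-WGD genomes violate the model in known ways that are out of
scope here: chromosomal rearrangements interrupt runs (biasing observable
run lengths downward), gene-by-gene silencing may coexist with segmental
excision ($\mu = 1$ is the gene-by-gene limit inside the model, but no
mixture is fitted), and orthology/synteny calling noise has no
counterpart. Passing tests therefore validate the implementation against
its own stated process, not the process against real genomes.

## Inference

Only run lengths and $\theta$ are observable, plus — when homeolog
identity is known — which chromosome each single-copy gene survives on.

* `estimatePhiDirect` estimates $\phi$ as the larger per-homeolog share
  of deleted genes. Labels are conventions, so estimates are reported on
  $[0.5, 1]$ with the favoured side attached; relabelling the chromosomes
  maps the estimate to itself.
* `fitMuPhi` fits $\mu$ (and, without side information, $\phi$) against a
  simulated forward-model grid at matched $\theta$
  (`buildModelGrid`, default $\mu \in \{2,3,4,6,8,11\}$, $\phi \in
  \{0.5,\dots,1\}$). The simulator, not the recurrence, is the forward
  model because the observable is the run-length distribution $p(l)$,
  which the recurrence does not produce (it yields $\pi(r)$ and $\bar u$).
  Two objectives are offered: a chi-square distance between run-length
  histograms (bins pooled to keep expected counts above 5), minimized on
  the grid and refined by a parabola on the $\log\mu$ axis; and a
  mean-curve match, where the model mean run length — strictly increasing
  in $\mu$ at fixed $(\phi, \theta)$ — is inverted by monotone
  interpolation of $\log\mu$ against the model means. The inversion form
  is used wherever calibrated uncertainty matters: the histogram
  objective's minimum sits in a noisy, asymmetric valley and its refined
  argmin carries a small upward bias (a few percent at $\mu = 6$), which
  is harmless for point estimation but shifts percentile intervals.
* Bootstrap intervals resample runs with replacement, holding $\theta$
  fixed — the run is the sampling unit of the data — and re-fit against
  the cached grid; $\phi$ intervals use a parametric (binomial) resample
  of the per-homeolog split.

Since the (μ, 1−φ) labelling ambiguity is resolved by convention and the
data determine $\phi$ only up to it, the joint fit without side
information can sit on a flat ridge in $\phi$ near 0.5; the fit warns
when the objective surface is flat.

## Numerical and testing notes

Problem sizes in the test suite are chosen to exercise each claim at the
smallest scale at which it is statistically decisive: full study scale
(length $10^5$, 100 replicates) for the acceptance checks — the
accounting identity, the geometric duplicate-run fit, the
recurrence-vs-simulation deviation bound of 0.08, and (μ, φ) recovery at
$(6, 0.75)$ — and reduced intervals (20,000–50,000) for unit-level
properties, where the effects under test are orders of magnitude larger
than sampling noise. Bootstrap coverage is checked at nominal 90% over 30
synthetic datasets with the mean-curve fit.

Degenerate inputs are handled explicitly: $\mu = 1$ makes every deletion
a single gene (the geometric becomes a point mass and all type-D rates
vanish identically); $\bar v = 1$ collapses $\rho$ to a point mass;
saturation (no duplicate position left) stops the simulation with a
warning. Ties in the event-type classification cannot occur: an event
either absorbs a pre-existing run or it does not, and blocked events
always count the blocking run as touched.

## Limitations

The recurrence neglects mergers of three or more runs; their simulated
frequency is reported as `pOther` and flagged when it exceeds 5%, which
happens once roughly 70–80% of duplicates are gone (earlier under strong
bias with large deletions). Below that regime the recurrence is accurate
to a few hundredths in every event-type proportion; beyond it, its
trajectories should be treated as qualitative. No closed form for
$\pi(r)$ is attempted, and no hypothesis test of segmental-excision
versus gene-by-gene loss is provided — the package supplies the null
model such a test would be built on.
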