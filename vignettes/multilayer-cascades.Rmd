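---
title: "Cascading failures in coupled gene-regulatory, protein and metabolic networks"
author: "cascnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascading failures in coupled molecular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascnet)
```

# The model

Cellular function rests on three tightly coupled interaction networks: a
directed gene regulatory network (GRN) in which transcription factors
control target genes, an undirected protein-protein interaction (PPI)
network, and an undirected metabolic network whose metabolites are
sustained by enzyme support links from the PPI layer. `cascnet` models
this system as a `MultilayerNetwork`: three `Layer` objects, a partial
one-to-one gene/protein interdependency map (a protein-coding gene and
its product stand or fall together), and a many-to-many
protein-to-metabolite support map.

A perturbation knocks out a set of target genes. Failure then spreads by
four rules, iterated in rounds until a fixed point:

1. **Regulatory loss.** A newly failed gene drags down its regulatory
   targets (all of them, or each independently with probability *f* when
   the target-failure fraction *f* < 1). Genes left with no remaining
   regulatory links at all (isolates) also fail. Under the default
   `one_hop` rule only genes failed by perturbation or protein loss
   propagate to their targets; `recursive` mode iterates target failure
   to a fixed point within the round.
2. **Interdependency.** The partner protein of every gene that failed
   this round fails.
3. **Connectivity.** Proteins disconnected from the largest connected
   component (LCC) of the surviving PPI network fail — a protein must be
   part of the main interacting machinery to function.
4. **Feedback.** Genes paired to connectivity-failed proteins fail, and
   seed the next round's regulatory step.

After convergence the metabolic layer is resolved once (metabolites do
not feed back onto proteins): a metabolite with $k_s > 0$ supports fails
when at least $\lceil f_{\mathrm{P2M}}\, k_s \rceil$ of them have
failed, and surviving metabolites outside the metabolic LCC fail too.
Robustness is summarized by the final functional fractions
$f_S^G, f_S^P, f_S^M$ and by the integral
$R = \int_0^1 f_S \, \mathrm{d}p$ of a functional-fraction curve over
the gene survival probability $p$.

```{r toy, eval = FALSE}
t1 <- toyFixture("T1")
runCascade(t1, perturbationConfig(seeds = "g1"))
#> CascadeResult (coupled mode, 1 round)
#>   functional fractions: fsG = 0, fsP = 0.2, fsM = 0.3333
```

# The analytical theory

For networks whose layers are locally tree-like and whose interlayer
links are (approximately) random, the final sizes can be predicted from
degree distributions alone. The ingredients, all exposed as functions:

* `rS(p, joint)` — the fraction of genes neither perturbed nor the
  target of a perturbed regulator,
  $r_S = \sum_{k_\mathrm{in},k_\mathrm{out}} P(k_\mathrm{in},
  k_\mathrm{out})\, p^{k_\mathrm{in}+1}$.
* `remainingJoint`, `fsGene`, `hGene` — binomial thinning of the joint
  degree pmf and the isolate correction
  $f_S^G = r_S\,[1 - P^{(r_S)}(0,0)]$ (the thinning assumes independent
  in- and out-degrees; empirical joints are accepted so the
  approximation error can be quantified).
* `giantFraction(gf, p)` — configuration-model site percolation:
  the smallest root of $x_c = H(p x_c + 1 - p)$ by fixed-point
  iteration from 0 (tolerance $10^{-12}$, bisection fallback; below the
  threshold $p\,H'(1) \le 1$ the result is exactly 0), giving
  $h(p) = 1 - G(p x_c + 1 - p)$.
* `cascadeTheory(p, qG, qP, joint, ppiGf)` — the coupled recursion
  $\psi'_n = p\,(1 - q_G(1 - h_{\mathrm{PPI}}(\phi'_{n-1})))$,
  $\phi'_n = 1 - q_P(1 - h_{\mathrm{Gene}}(\psi'_n)\,p)$, iterated to
  $|\psi'_{n+1}-\psi'_n| < 10^{-9}$ (at most $10^4$ stages); the
  functional fixed points are $f_S^G = \psi'_m h_\mathrm{Gene}(\psi'_m)$
  and $f_S^P = \phi'_m h_\mathrm{PPI}(\phi'_m)$.
* `metabolicTheory(phiM, supportGf, metGf, fP2M)` — the probability a
  metabolite loses a super-threshold fraction of supports,
  $\omega = \sum_{k_s \ge 1} P_D(k_s) \sum_{l = \lceil f_{\mathrm{P2M}}
  k_s \rceil}^{k_s} \binom{k_s}{l} (1-\phi_m)^l \phi_m^{k_s - l}$,
  followed by percolation of the remaining fraction
  $r_\mathrm{Meta} = 1 - \omega$ on the metabolic layer. Metabolites
  with no supports never fail through support loss; their pmf mass is
  exactly what the coupling strength $q_\mathrm{Meta}$ removes from
  $\omega$, so passing the full support pmf (including $k_s = 0$) and
  passing the conditional pmf with an explicit `qMeta` are equivalent.

The coupling strengths $q_G, q_P$ (fractions of each layer depending on
the other) come from `couplingStrengths()`: the `"naive"` method reads
them off the interlayer maps; `"calibrated"` fits them by least squares
against a simulated curve (see *Accuracy*, below).

# Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `fP2M` | fraction of a metabolite's supports whose loss is fatal | 1 | the strictest, best-identified rule: a metabolite fails when all supports fail; the threshold form $\lceil f_{\mathrm{P2M}} k_s\rceil$ matches the theory's binomial tail |
| `grnPropagation` | whether target-failed genes drag down their own targets | `one_hop` | consistent with the theory, where only perturbation- and protein-loss-removed genes thin the network ($p^{k_\mathrm{in}+1}$) and target failure is applied once per stage |
| `targetFraction` (*f*) | fraction of a failing gene's targets that fail | 1 | redundancy sensitivity knob; each alive target is retained independently with probability $1-f$, redrawn per failing gene per run (a smooth Bernoulli version of "a fraction *f*") |
| `couplingRetention` | fraction of gene-protein pairs kept for propagation | 1 | interlayer-information dilution knob; a seed gene always takes its own protein down, so retention 0 reproduces the uncoupled control exactly |
| `replicates` | removal draws per grid point | 30 | standard averaging convention for the robustness curves |
| rewiring `nSteps` | attempted swaps | $10\,|E|$ | common mixing heuristic for degree-preserving edge shuffles |

# The synthetic benchmark

`generateERMultilayer(erBenchmarkSpec())` builds the canonical
three-layer Erdős–Rényi benchmark: 5000 genes (directed ER, mean in- and
out-degree 2, independent by construction, matching the theory's
independence assumption), 5000 proteins (mean degree 8), 1000
metabolites (mean degree 4), a uniform one-to-one gene/protein matching
covering $q_G = q_P = 0.8$ of each layer, and Poisson(3) support
degrees (zeros kept, exercising the $q_\mathrm{Meta}$ pathway). These
sizes and densities are the package's validation convention: large
enough for mean-field behaviour, small enough that a full
theory-vs-simulation sweep (20 grid points × 30 replicates) runs in
seconds.

What the generator emulates is the *structure* the method assumes —
partial bidirectional gene–protein interdependency and many-to-many
protein–metabolite supports on sparse random layers. What it does not
emulate: heavy-tailed degree distributions, in/out-degree correlations
within the GRN, degree-assortative interlayer wiring, clustering, and
edge confidence — all present in curated molecular networks. Passing
tests on ER inputs therefore validate the machinery and the theory's
internal consistency, not the biological conclusions one would draw on
real networks (the rewiring module exists precisely to probe the wiring
features the ER benchmark lacks).

Hand-traceable fixtures `toyFixture("T1")` / `"T2"` pin down every rule
of the cascade exactly (T2 adds a feedback chain that produces a
genuine second-round failure).

```{r bench, eval = FALSE}
net <- generateERMultilayer(erBenchmarkSpec(seed = 1))
pGrid <- seq(0.05, 1, by = 0.05)
sim <- robustnessCurve(net, pGrid, replicates = 30, fP2M = 1, seed = 7)
theo <- theoryCurve(net, pGrid, fP2M = 1)
theoryVsSim(sim@curve, theo)
#> [1] 0.9983443
```

# Accuracy of the mean-field theory, and a known limitation

On the ER benchmark the analytical curves track the simulation closely
(Pearson r ≈ 0.998 across all layers and grid points; the acceptance
script recomputes this). The agreement is not pointwise-exact: at
intermediate $p$ the recursion systematically overestimates the
gene-layer feedback damage (e.g. predicted $f_S^G = 0.055$ vs simulated
$0.070$ at $p = 0.5$ on the benchmark), a mean-field effect — the
recursion treats "partner outside the giant" as independent of the
gene's own neighbourhood state, while in the simulated cascade those
events are positively correlated.

This bias has a practical consequence for `couplingStrengths(method =
"calibrated")`: least-squares fitting absorbs the model error into the
fitted parameters, so on benchmark data generated with
$q_G = q_P = 0.8$ the calibration recovers $q_P$ accurately (~0.80)
but returns an *effective* $q_G \approx 0.6$ that compensates the
overestimated feedback. Calibrated strengths should be read as
effective curve-fitting parameters, not structural coverage fractions;
when the interlayer maps are available, the naive fractions are the
honest structural estimate (and are what the validation uses). In the
decoupled limit the protein curve pins $q_P$ near 0 while $q_G$ is
structurally unidentifiable (it only enters through the non-giant
protein fraction).

# Numerical choices and degenerate inputs

* **LCC ties.** When several components tie for the maximum size, all
  of them count as functional. An id-ordering tie-break would make
  results depend on node labels; the inclusive rule does not. The cost
  is that strict monotonicity in the seed set can fail in heavily
  damaged small networks (a rival component overtaking the shrunken
  giant resurrects nodes); `CascadeResult@lccTies` flags runs where a
  tie occurred. The `one_hop` rule adds a second, independent
  non-monotonicity: failure *cause* determines propagation, so an
  earlier non-propagating (target) failure can spare downstream genes.
  Both effects vanish in practice on the benchmark's dominant-giant
  regime; the test suite asserts monotonicity for the recursive rule on
  tie-free runs.
* **Threshold arithmetic.** $\lceil f_{\mathrm{P2M}} k_s\rceil$ is
  computed as `ceiling(f * k - 1e-9)` so that binary-float noise
  (0.7 × 10 = 7.000000000000001) cannot shift a threshold.
* **Fixed points.** The percolation root is found by monotone iteration
  from 0, which converges to the physically relevant smallest root;
  $x = 1$ is always a fixed point and must not be returned when a
  smaller one exists, hence the analytic subcriticality test
  $p\,H'(1) \le 1 \Rightarrow h = 0$ exactly.
* **Determinism.** Every stochastic entry point takes a seed; replicate
  streams are derived per (grid point, replicate), so extending a grid
  or adding replicates never perturbs earlier draws. The RNG state of
  the calling session is always restored.
* **Degenerate inputs.** Empty seed sets are valid (the baseline run
  fails only structural non-functionality); degenerate pmfs (all mass
  at degree 0) give $h = 0$; `hGene` is undefined at $p = 0$ and the
  recursion short-circuits that limit to 0.

# Validation problem sizes

The shipped tests run, by design, at these scales: the full benchmark
(5000/5000/1000, 30 replicates, 20 grid points) for theory-vs-simulation
agreement and for targeted-damage analysis (200 draws per arm);
2000/2000/500 with 15 replicates for calibration; 50 seeded instances of
200/200/50 for the coupled-vs-uncoupled prioritization comparison (20
planted positives each); 100 random 25-node instances for the
decoupling identity; and 10^5 swap attempts on a 500-node layer for the
rewiring invariants. Engine correctness is cross-checked against an
independent set-based reference implementation on random 40-node
instances, and the largest-component routine against brute-force
component enumeration on graphs of up to 12 nodes.

# Known limitations

* No feedback from metabolites to proteins or genes, and no
  within-layer metabolite failure other than the LCC rule.
* Unweighted edges; no confidence scores or weighted failure rules.
* The analytical framework inherits the configuration-model
  assumptions: tree-likeness, independent in/out degrees (the empirical
  joint is accepted as input, but the thinning step factorizes it) and
  random interlayer matching. In/out-degree correlations — which the
  GRN rewiring module can inject — are precisely the regime where the
  theory degrades.
* `"calibrated"` coupling strengths are effective parameters (see
  above).
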