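# cascnet

Robustness analysis of multilayer molecular networks: a cascading-failure
simulator for coupled gene-regulatory / protein–protein-interaction /
metabolic systems, influence-score analytics for essential-gene
prioritization, degree-preserving rewiring null models, and the
generating-function percolation theory that predicts final functional
layer sizes from degree distributions alone.

## Who it is for, and what it does

Systems biologists studying how genetic perturbations propagate across
molecular layers, and network scientists working on interdependent-network
percolation. The cell is modelled as three coupled graphs:

* a directed **gene regulatory network** (GRN), transcription factor →
  target edges;
* an undirected **PPI network**, coupled to the GRN by bidirectional
  gene↔protein interdependency links (a partial one-to-one matching);
* an undirected **metabolic network**, sustained by many-to-many
  protein → metabolite support links.

Perturbing a set of target genes triggers a cascade: failed genes drag
down their regulatory targets and their protein products; proteins
disconnected from the largest PPI component fail, taking their coding
genes with them; rounds repeat to a fixed point, after which a metabolite
fails when at least ⌈f_P2M · k_s⌉ of its k_s supports are gone (and when
it leaves the metabolic largest component). The final functional
fractions f_S^G, f_S^P, f_S^M and the robustness integral
R = ∫₀¹ f_S dp summarize the damage.

The analytical core predicts the same quantities from the joint GRN
degree pmf P(k_in, k_out), the layer degree generating functions
G(x), H(x) = G′(x)/G′(1) and coupling strengths q_G, q_P, q_Meta, via
the coupled recursion

    ψ′_n = p (1 − q_G (1 − h_PPI(ϕ′_{n−1})))
    ϕ′_n = 1 − q_P (1 − h_Gene(ψ′_n) p)

iterated to its fixed point, with r_S = Σ P(k_in,k_out) p^{k_in+1},
h_Gene the isolate correction, h_PPI the percolation giant-component
fraction, and a binomial-tail support-failure probability ω feeding the
metabolic percolation step.

## Worked example

```r
library(cascnet)

t1 <- toyFixture("T1")   # 4 genes, 5 proteins, 3 metabolites, hand-traceable
t1
#> MultilayerNetwork
#>   Layer 'grn' (directed): 4 nodes, 3 edges
#>   Layer 'ppi' (undirected): 5 nodes, 5 edges
#>   Layer 'met' (undirected): 3 nodes, 2 edges
#>   gene-protein pairs: 4
#>   protein-metabolite supports: 4

runCascade(t1, perturbationConfig(seeds = "g1"))
#> CascadeResult (coupled mode, 1 round)
#>   functional fractions: fsG = 0, fsP = 0.2, fsM = 0.3333

influenceScores(t1)
#>   gene influence uncoupledInfluence outDegree secondRound
#> 1   g1       0.8                0.2         2           0
#> 2   g2       0.8                0.4         0           4
#> 3   g3       0.6                0.2         0           0
#> 4   g4       0.6                0.4         1           0
```

Knocking out g1 kills its targets g2, g3 (and hence proteins p1–p3),
isolates g4 (killing p4), and leaves only p5 in the PPI layer — so g1's
influence score 1 − f_S^P = 0.8, against 0.2 for the uncoupled control
that deletes p1 alone. The metabolites m1, m2 lose all their supports
and fail; m3 survives on p5.

On the synthetic Erdős–Rényi benchmark (5000/5000/1000 nodes, mean
degrees 2/8/4, q_G = q_P = 0.8, Poisson(3) supports) the analytical
curves track a 30-replicate simulation with Pearson r ≈ 0.998:

```r
net  <- generateERMultilayer(erBenchmarkSpec(seed = 1))
pGrid <- seq(0.05, 1, by = 0.05)
sim  <- robustnessCurve(net, pGrid, replicates = 30, fP2M = 1, seed = 7)
theo <- theoryCurve(net, pGrid, fP2M = 1)
theoryVsSim(sim@curve, theo)
#> [1] 0.9983443
```

A command-line wrapper covering the same pipeline (synth / cascade /
theory / rewire / influence subcommands over TSV network bundles) is
installed at `system.file("scripts", "cascnet", package = "cascnet")`;
see `cascnetMain("--help")`.

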