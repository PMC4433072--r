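# pathreg

Which enzymes of a metabolic pathway should be under transcriptional
control?  `pathreg` answers this for small pathway models — linear,
converging and diverging chains of irreversible Michaelis–Menten
reactions — by dynamic optimization.  Given a time course of demand for
the pathway product, it finds the enzyme concentration programs
\(e_i(t)\) minimizing

```
J  =  σ · Σ_i e_i(0) · t_f   +   Σ_i ∫₀^{t_f} ( e_i(t) − e_i(0) )² dt
      └── protein cost ──┘       └──── regulatory effort reg_i ────┘
```

subject to the pathway mass balances, a tolerance band on the product
concentration, caps on intermediate accumulation, and optionally a
bound `m` on how fast enzyme levels can change (limited protein
biosynthesis).  Feedback inhibition of upstream enzymes by pathway
products enters as competitive inhibition (apparent `Km` inflated by
`1 + p/kr`).  Randomized-parameter ensembles then show where regulatory
effort concentrates: at the initial and terminal enzymes of a pathway,
how rate limits shift that balance, and how product feedback inhibition
removes the need to regulate the enzymes it targets.

A second component implements the genomic statistics used to confront
such predictions with prokaryotic annotations: promoter lengths from
intergenic gaps (operon-aware, shared between divergent genes),
relative normalization against non-metabolic genes, sparse/pervasive
pathway classification (60% rule), and positional/PTM rank-sum
comparisons — driven here by a synthetic annotation generator with
planted effects.

Audience: systems-biology researchers studying metabolic regulation,
and anyone needing a compact, fully scriptable dynamic-optimization
pipeline for enzyme expression programs.

## Worked example

```r
library(pathreg)

topo <- build_topology("linear", "initial")   # P inhibits e1
set.seed(6)
smp  <- sample_parameters(topo, kr = 1)       # kcat, km ~ U[1e-3, 2]
dil  <- dilution_profile(c(0, 15, 30), smp$dilution_values)
prob <- new_ocp(topo, smp$params, dil, sigma = 0.1)
sol  <- solve_ocp(prob, seed = 1)
sol
#> <ocp_solution> linear+initial
#>   J = 33.58 (sigma*J_cost = 33.505, J_reg = 0.074883)
#>   feasible: TRUE (max violation 6.43e-09)
#>   reg_i:  e1=0.00437, e2=4e-05, e3=1.27e-05, e4=6.92e-05, e5=0.0704
```

This run's demand rises from 0.59 to 0.75 at t = 15.  With the
feedback loop in place the product level dips, the inhibition of `e1`
releases and the entry flux follows automatically: the first enzyme
needs almost no transcriptional regulation (`reg_1 = 0.004`) and the
remaining effort sits at the terminal step.  Removing the inhibition
(`build_topology("linear", "none")`) forces the first enzyme to carry
the adjustment:

```r
prob0 <- new_ocp(build_topology("linear", "none"), smp$params, dil,
                 sigma = 0.1)
round(solve_ocp(prob0, seed = 1)$reg, 4)
#>     e1     e2     e3     e4     e5
#> 0.5316 0.0010 0.0004 0.0014 0.0952
```

Ensemble experiments wrap this per-run machinery:

```r
cfg <- scenario_config("demo", kind = "linear", inhibition = "initial",
                       sigma = 0.1, n_runs = 20, seed = 1)
rec <- run_scenario(cfg)                   # one row per randomized run
med <- ensemble_medians(rec)               # per-enzyme median reg_i
count_control_points(med)                  # tau = 0.05 share rule
```

For the genomic stage:

```r
anns <- generate_annotation(annotation_config(n_genomes = 30,
                                              delta = c(branch = 200),
                                              seed = 1))
prof <- do.call(rbind, lapply(anns, function(a) analyze_genome(a)$relative))
positional_comparison(prof, "pre_branch_vs_branch", sparse_only = FALSE)
#> <comparison> medians -0.6234 vs 0.6494 (n = 30, 60), p = 5.909e-13
```

A thin CLI over these functions is installed at
`inst/scripts/pathreg-cli.R` (subcommands `solve`, `ensemble`,
`m-scan`, `kr-scan`, `genome-analysis`, `synth`).

See `vignettes/pathway-regulation.Rmd` for the model, the formulation
choices (drain form, steady-state start, bounds) and the solver design.

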