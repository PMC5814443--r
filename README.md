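# ribopool

Host-aware simulation of bacterial gene expression with orthogonal
ribosome pools.

Synthetic circuits compete with their host — and with each other — for
shared cellular resources, above all ribosomes. This produces hidden
"couplings": inducing one circuit gene silently lowers the expression of
another, with no regulatory link between them. One engineering answer is
to partition translation itself: expressing a synthetic 16S rRNA whose
anti-Shine-Dalgarno sequence pairs only with matching orthogonal RBSs
creates a quasi-orthogonal ribosome pool that translates only chosen
circuit genes. `ribopool` is a deterministic whole-cell model for
studying and designing such partitions: which genes to allocate to which
pool, how pool size trades off against host burden, and how a feedback
controller can re-allocate ribosomes dynamically as circuit demand
changes.

The package is aimed at modellers and circuit designers in synthetic
biology who want a mechanistic, steady-state-solvable sandbox for
translational resource allocation.

## The model in brief

The host core follows the coarse-grained growth model of Weisse et al.
(2015): substrate import and catabolism yield an internal energy pool
*e*; mRNAs of four host gene classes are transcribed at
ω·*e*/(*o*+*e*); free ribosomes *R* bind mRNAs reversibly and elongate
at γ(*e*) = γ_max·*e*/(K_γ+*e*) amino acids per minute; growth dilutes
everything at

λ = γ(*e*)/M · Σ c,

the total translational flux over the proteome mass M, summed over every
translating complex. Ribosome biosynthesis is resolved into two
components: an "empty ribosome" protein p_R and an rRNA *r*, assembling
reversibly into functional ribosomes. An orthogonal pool adds a
synthetic 16S rRNA ρ that competes with the host rRNA for the same p_R
(p_R + ρ ⇌ P); the resulting o-ribosomes P translate only the circuit
genes allocated to that pool.

Coupling between two reporters is quantified by the **isocost line**:
the line of steady-state (induced, constitutive) expression pairs traced
as one gene is induced, fitted by least squares; its slope measures how
much constitutive expression is lost per unit induced expression gained.
The package's analyses are built on this measure: comparison of the four
host/orthogonal allocation patterns, a two-pool (one pool per gene)
decoupling optimisation, a five-enzyme violacein pathway study, and a
negative-feedback controller in which a constitutive o-pool-translated
repressor gates o-rRNA transcription by 1/(1+(p_F/k_D)^h), sensing
translational demand through its own competition for o-ribosomes.

## A worked example

```r
library(ribopool)

ss <- solve_steady_state(cell_model())
ss
#> <steady_state> converged: TRUE  residual: 1e-10  lambda: 0.02411 /min  phi_R: 0.241

m <- cell_model()
m <- add_o_pool(m, o_pool_spec("o1", omega_rho = 500))
m <- add_circuit_gene(m, circuit_gene("gfp", omega = 100, pool = "o1"))
m <- add_circuit_gene(m, circuit_gene("rfp", omega = 1, pool = "host"))
sw <- isocost_sweep(m, induced = "rfp", constitutive = "gfp",
                    omega_grid = logspace(0, 3, 8))
sw
#> <isocost_result> gfp vs rfp over 8 points
#>   slope (raw): -0.4554   slope (normalised): -0.2976
```

The bare host grows at λ ≈ 0.024/min with about a quarter of its
proteome in ribosomal protein. The sweep then induces `rfp` (host pool)
from 1 to 1000 mRNAs/min while `gfp` sits on its own orthogonal pool:
`gfp` keeps 70% of its maximum across the entire induction (normalised
slope −0.30) — the orthogonal pool insulates the constitutive gene.
Running the same sweep with both genes on the host pool gives a
normalised slope of about −0.80, and putting the *induced* gene on the
o-pool while the constitutive gene stays on the host pool is worst of
all (≈ −0.91): translating o-ribosomes trap the shared empty-ribosome
protein and starve the host pool. `configuration_comparison()` computes
all four allocations in one call. `two_pool_decoupling()` dedicates one
pool per gene and optimises both pool sizes; at the optimum the
constitutive reporter falls by only ~1% across the full induction
sweep. `controller_model()` plus `robustness_mc()` analyse the feedback
controller, which cuts the coupling slope severalfold (−0.12 vs −0.90)
relative to an expression-matched fixed pool and keeps outperforming it
under ±50% parameter perturbations.

Scenarios can also be described in YAML and run from a shell via the
thin CLI (see `inst/extdata/example-isocost.yaml`):

```sh
Rscript inst/scripts/ribopool-run --config inst/extdata/example-isocost.yaml --out results/
```

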