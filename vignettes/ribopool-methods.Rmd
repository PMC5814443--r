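---
title: "Methods: a host-aware model of gene expression with orthogonal ribosome pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a host-aware model of gene expression with orthogonal ribosome pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ribopool` simulates a growing bacterial cell as a deterministic
mass-action ODE system built around three coupled constraints: a finite
energy supply from metabolism, a finite pool of ribosomes, and a finite
proteome. All amounts are molecules per cell, time is in minutes, protein
lengths are in amino acids, and no volume scaling is applied.

**Metabolism.** An external substrate at constant level $s_{ext}$ is
imported by transporter proteins ($p_T$) and catabolised by enzymes
($p_E$), each by Michaelis–Menten kinetics, yielding an internal "energy"
currency $e$ ($n_s$ units per substrate molecule). Energy is consumed by
translation: every elongation step costs one unit, so a complex
translating a protein of length $n$ drains $n$ units per completed
protein.

**Transcription.** mRNAs of the four host gene classes — transporter
$T$, enzyme $E$, housekeeping $H$ and ribosomal $R$ — are born at an
energy-saturating rate $\omega_X\, e/(o_X + e)$. The housekeeping class
carries negative autoregulation $1/(1 + (p_H/K_H)^{h_H})$, which holds
the bulk proteome share roughly constant and is what makes the remaining
capacity a meaningful shared budget. The ribosomal classes ($o_R$,
$o_r \approx 427$) are far less energy-avid than the others
($o_X \approx 4.4$), so ribosome production falls first when energy is
drained — the feedback that produces the bacterial growth laws.

**Translation.** Free ribosomes bind mRNA reversibly
($b_X$, $u_X$), forming complexes $c_X$ that complete proteins at rate
$c_X\,\gamma(e)/n_X$ with $\gamma(e) = \gamma_{max}\, e/(K_\gamma + e)$.
The growth (dilution) rate is total translational flux over proteome
mass,
$$\lambda = \frac{\gamma(e)}{M} \sum c,$$
where the sum runs over *every* translating complex — host genes,
circuit genes, controller — because all translation produces proteome
mass. Every species is diluted at $\lambda$.

**Ribosome biosynthesis.** Ribosomes are assembled from two components:
a lumped ribosomal protein, the "empty ribosome" $p_R$ (produced by
translation of the $R$-class mRNA), and an rRNA $r$ (transcribed
directly). Assembly $p_R + r \rightleftharpoons R$ is reversible
($b_r$, $u_r$). This two-component scheme makes ribosomes autocatalytic
(ribosomes translate their own protein component) and creates the shared
currency that orthogonal pools compete for.

**Orthogonal pools.** An orthogonal pool adds a synthetic 16S rRNA
$\rho$, transcribed at $\omega_\rho\, e/(o_\rho + e)$, which competes
with the host rRNA for the same $p_R$:
$p_R + \rho \rightleftharpoons P$. The resulting o-ribosomes $P$
translate only the circuit genes allocated to the pool; host ribosomes
never bind orthogonal RBSs. An optional one-way interference rate
(`b_cross`) lets o-ribosomes bind host-RBS circuit mRNAs; it defaults to
off. All dynamics follow by mass action from this reaction scheme; in
particular translation completion *releases* the ribosome and the mRNA,
and complex formation consumes them.

## Parameters and defaults

Host defaults are the published fitted parameter set of the Weisse et
al. (2015) growth model (e.g. $\gamma_{max} = 1260$ aa/min/ribosome,
$K_\gamma = 7$, $M = 10^8$ aa, $\omega_R \approx 930$,
$\omega_H \approx 949$, $o_{R} \approx 427$, $o_{T,E,H} \approx 4.38$,
$b_X = u_X = 1$, $\delta_m = 0.1$/min), extended with explicit rRNA
kinetics. Choices this package had to make itself:

* **rRNA turnover** ($\delta_r = \delta_\rho = 0.1$/min). Free
  (unassembled) rRNA is treated as turning over like mRNA. Setting
  $\delta_\rho = 0$ was examined and rejected: with no o-rRNA sink other
  than dilution, a strong o-rRNA gene becomes an unbounded trap for
  $p_R$ and the cell has no viable steady state at
  $\omega_\rho = 500$/min. Assembled ribosomes and the empty-ribosome
  protein are diluted only ($\delta_R = \delta_{p_R} = 0$).
* **rRNA transcription capacity** ($\omega_r = 10^4$/min, roughly
  tenfold the ribosomal-protein mRNA rate). rRNA operons dominate
  bacterial transcription, and the model needs that excess: an
  rRNA-starved host (with $\omega_r$ equal to the mRNA rate) supplies
  fewer rRNAs per minute than it needs ribosomes, and any orthogonal
  pool then acts as a one-way ratchet on the empty-ribosome protein —
  translation locks o-ribosomes in complexes, $p_R$ only returns through
  free $P$, and the host collapses on every trajectory. With rRNA in
  excess the host is robust and a gene-free pool at
  $\omega_\rho = 500$/min changes growth by under 3%.
* **o-rRNA energy threshold** ($o_\rho = 4.38$). The o-rRNA follows the
  same dynamics as the host rRNA, but as a plasmid-carried synthetic
  gene it responds to energy like an ordinary host gene, not like the
  tightly growth-controlled chromosomal rRNA operons. This makes the
  pool's supply nearly independent of host load, which is precisely what
  lets it insulate the genes allocated to it (using the host rRNA's
  high threshold instead couples the pool to host energy state and
  destroys the insulation the pathway study depends on).
* **Circuit RBS kinetics** ($b = u = 1$, as for host genes), following
  the principle that extension parameters default to their host
  counterparts unless a configuration overrides them.

## Quantifying coupling: isocost lines

Two reporters share a fixed resource budget: a constitutive `gfp`
($\omega = 100$/min) and an induced `rfp` whose transcription rate is
swept (default $1 \ldots 10^3$/min, 8–10 log-spaced points). Each sweep
point is an independent steady state (warm-started from its neighbour);
the straight line fitted through all (rfp, gfp) steady-state pairs by
ordinary least squares is the isocost line, and its slope measures how
much constitutive expression is lost per unit of induced expression
gained.

Raw slopes are not comparable across pool allocations because absolute
expression scales differ; each reporter is therefore also normalised by
its own maximum across the sweep, and the **normalised slope** is the
dimensionless coupling measure used in all cross-configuration
comparisons. Both raw and normalised fits are always reported. (When a
figure aggregates several pool sizes, normalising by the global maximum
across the whole panel set is an alternative convention; with a single
pool size per sweep, as used here, the two coincide.)

At the defaults ($\omega_\rho = 500$) the allocations behave as
follows. Moving the constitutive gene to its own pool insulates it
(normalised slope $\approx -0.30$ versus $-0.80$ when both genes share
the host pool), while moving the *induced* gene to the o-pool makes
coupling worse than sharing ($\approx -0.91$): translating o-ribosomes
are stabilised in complexes, which traps the shared $p_R$ component and
starves the host pool that the constitutive gene depends on.

One ordering relation that might be expected — both genes sharing the
o-pool coupling *less* than both sharing the host pool — does **not**
hold in this model family, for a structural reason worth stating.
Because mRNA is protected from degradation while ribosome-bound, a gene
transcribed at $\omega$ accumulates complexes until dilution balances
production, an effective demand of $\sim \omega/\lambda$ ribosomes
(thousands); any orthogonal pool is therefore fully subscribed
throughout the sweep. Allocation on a fully subscribed pool follows
transcription shares, so the constitutive reporter retains
$\frac{100/1100}{100/101}$ of its maximum at full induction and the
normalised slope is pinned near $-(1 - 101/1100) \approx -0.91$,
whatever the pool kinetics. The shared *host* pool escapes this bound
because the autoregulated housekeeping class yields proteome share
under load, buffering the reporters. The package reports both slopes
per configuration and the regression tests assert exactly the relations
above.

## Two pools, one per gene

`two_pool_decoupling()` dedicates one pool to each reporter and
grid-searches both pools' $\omega_\rho$ (8 × 8 log-spaced points over
$10 \ldots 10^3$) for the combination minimising the relative drop of
the constitutive reporter across the full induction sweep. At the
optimum the constitutive reporter falls by only about 1% while the
induced reporter still rises and saturates (the pools still share
$p_R$, energy and proteome).

## The violacein pathway

The five-enzyme violacein pathway is modelled as an irreversible
Michaelis–Menten chain from a constant tryptophan supply:
$v_i = k_{cat,i}\, p_i\, S_i/(K_{m,i} + S_i)$, intermediates diluted at
$\lambda$. The exact in-vivo kinetic constants are not critical to the
resource-allocation question, so uniform defaults
($k_{cat} = 10$/min, $K_m = 10^3$) are used and fully exposed. Enzyme A
is its own constitutive cassette ($\omega_A = 25$/min); B–E form one
polycistronic operon sharing a single $\omega_{BCDE}$ (the induction
input) and RBS strength, so their levels differ only through protein
length; vioB defaults to three times the length of the others,
reflecting its disproportionate ribosome sequestration. Allocating
enzyme A to an orthogonal pool protects its level as the downstream
operon is induced and raises final metabolite output at high induction.

## The feedback controller

The controller is a constitutive repressor gene translated by the
orthogonal pool it regulates; its protein gates the pool's o-rRNA
transcription by $1/(1 + (p_F/k_D)^h)$ and nothing else. Because the
repressor mRNA level is constant, its *translation* rate senses
competition for o-ribosomes: rising circuit demand lowers repressor
output, de-represses o-rRNA transcription, and co-opts more $p_R$ into
the pool.

**Defaults** ($\omega_{\rho,max} = 1000$, $\omega_F = 100$, $b_F = 20$,
$k_D = 100$, $h = 2$) follow the design principles visible in the
sensitivity sweeps rather than the raw optimum of any single objective:
the repressor must sequester o-ribosomes strongly ($b_F$ high), bind its
operator tightly ($k_D$ small relative to typical repressor levels, as
for LacI), and act cooperatively ($h = 2$, reflecting dimerisation —
`sensitivity_sweep(param = "h")` shows $h = 4$ decouples better than
$h = 1$). Varying $k_D$ over a tenfold range tunes expression several
fold while changing the normalised slope by about one percent, so
expression is tunable at essentially no decoupling cost.

**Design search.** `design_controller()` scores candidates by
$J = |s_{norm}| + w \cdot \text{shortfall}$, where the shortfall is the
relative loss of pre-induction constitutive expression against a fixed
reference (the uncontrolled pool at $\omega_\rho = 500$). The reference
is deliberately *not* the uncontrolled pool at the candidate's own
$\omega_{\rho,max}$: at a very high $\omega_{\rho,max}$ an uncontrolled
pool burdens the host until its own expression collapses, which zeroes
the shortfall for exactly the candidates that should be penalised. The
full frontier is returned so alternative objectives can be scored
without re-simulation.

**Fair comparison.** `tune_open_loop_match()` root-solves the fixed
$\omega_\rho$ at which the uncontrolled circuit produces the same
pre-induction constitutive protein as the closed loop (within 0.1%);
closed versus open loop are always compared at matched expression. The
search is bounded above by the closed loop's own $\omega_{\rho,max}$:
repression only ever reduces the effective o-rRNA rate, and far larger
fixed pools drive the host into a regime where expression is no longer
monotone in $\omega_\rho$. At the defaults the closed loop reduces the
normalised coupling slope severalfold relative to its matched open loop
(about $-0.12$ versus $-0.90$).

**Robustness.** `robustness_mc()` multiplies each of the twelve
parameters governing o-rRNA production and the controller protein
($\omega_{\rho,max}, o_\rho, b_\rho, u_\rho, \delta_\rho, \omega_F,
o_F, b_F, u_F, n_F, k_D, h$) by an independent factor drawn uniformly
from $[1-f, 1+f]$ (uniform is the minimal reading of "random values
between $\pm 50\%$"; the distribution is a documented choice). The Hill
coefficient is floored at 1. Draws are seeded and bit-reproducible;
non-converged draws are excluded and counted, conserving $n$.

## Growth-law calibration

`generate_growth_law_data()` produces synthetic datasets with the
structure of the classic growth-law experiments: steady states across a
nutrient-quality grid ($n_s$) and a translation-inhibitor grid
(multiplicative factors on $\gamma_{max}$, a coarse-grained
chloramphenicol analogue), with multiplicative Gaussian noise. The
generator emulates the *shape* of such data — the positive
$\lambda$–$\Phi_R$ nutrient law and the inhibitor law in which
$\Phi_R$ rises as $\lambda$ falls — not instrument-scale fluorescence,
RNAP competition, stochastic cell-to-cell variability or stationary-
phase effects; passing the recovery tests therefore demonstrates
identifiability of the fitted parameters from this model's own
behaviour, not agreement with any real measurement set. Real data in
the same schema can be dropped in. Fitting is weighted least squares
over joint $(\lambda, \Phi_R)$ residuals (scaled by observation means)
by Levenberg–Marquardt in log-parameter space; noiseless self-generated
data returns the generating $\{\gamma_{max}, \omega_R\}$ to well within
10%.

## Numerics

* **Steady states**: stiff integration (`deSolve::lsoda`, rtol
  $10^{-9}$, atol $10^{-12}$, horizon $10^5$ min) with an early-exit
  root condition on the scaled residual
  $\max_i |\dot y_i| / \max(1, |y_i|)$, followed by damped Newton
  refinement with a finite-difference Jacobian. Convergence is reported
  as a flag (residual $\le 10^{-8}$ by default), never silently
  assumed. Re-solving from a converged state accepts zero Newton steps.
* **Warm starts**: sweeps and Monte Carlo draws Newton-start from the
  neighbouring solution and only fall back to integration when Newton
  fails; warm and cold paths agree to $10^{-6}$ relative.
* **Non-negativity**: solver undershoot more negative than $-10^{-9}$
  rejects convergence; smaller undershoot is clipped to zero in
  reported states.
* **Degenerate inputs**: the all-zero state is an exact equilibrium
  (nothing transcribes at $e = 0$ and nothing imports without $p_T$),
  so the default initial state seeds 10 free ribosomes plus small
  substrate and energy pools — ribosome biosynthesis is autocatalytic
  and cannot bootstrap from zero.
* **Cold starts of extended models**: a model carrying pools or circuit
  genes is initialised, by default, from the memoised steady state of
  its circuit-free host core with extension species at zero — the
  in-silico analogue of transforming a construct into a healthily
  growing cell. This matters because strongly sequestering circuits
  also admit long, slow transients near a collapsed (non-growing)
  regime when started from a nearly empty cell.
* **Problem sizes**: analyses default to 8–10 point log-spaced
  induction grids, 8 × 8 pool-rate grids and 1000 Monte Carlo draws;
  these are the sizes used by the package's own tests and reproduction
  script.

## Known limitations

RNA polymerase and tRNA competition are not modelled (transcription is
limited only by energy), so transcription-level coupling is absent; the
model predicts stronger decoupling from translation-level interventions
than a real cell can show. There is no stochasticity, no cell volume
growth, no spatial structure, and no explicit 30S/50S subunit cycling
(tethered-subunit ribosomes are out of scope). Absolute molecule counts
inherit the coarse-grained calibration of the base growth model and
should be read as model units, not instrument-scale measurements. At
the top of the default induction sweeps ($\omega = 10^3$ mRNAs/min) the
simulated circuit consumes enough of the cell to slow growth roughly
tenfold; real hosts buffer such loads with mechanisms (ppGpp signalling,
mRNA competition for RNAP) outside this model, so the predicted burden
at extreme induction is an upper bound.
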