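---
title: "Growth-coupled metabolism-and-expression models and paired Ribo-Seq/RNA-Seq analysis: methods"
author: "meomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meomics methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meomics)
library(SummarizedExperiment)
```

# The model

A metabolism-and-expression (ME) model couples a stoichiometric metabolic
network to the machinery that expresses it. `meomics` represents this
coupling by letting every stoichiometric coefficient depend affinely on the
growth rate $\mu$ (in 1/h): the coefficient of metabolite $m$ in reaction
$r$ is $a + b\mu$. Three kinds of couplings are expressible this way:

* **plain stoichiometry** — $b = 0$;
* **enzyme usage with dilution** — a reaction running at flux $v$ with
  effective catalytic rate $k_\mathrm{eff}$ requires an enzyme pool
  $v/k_\mathrm{eff}$, which growth dilutes at rate $\mu$; the enzyme
  species therefore carries $b = -1/k_\mathrm{eff}$ in the catalyzed
  reaction;
* **ribosome occupancy** — translating a protein of length $L$ occupies
  ribosomes for $L/c$ of their elongation capacity $c$ (aa/h), giving
  $b = -L/c$ on the ribosome species in the translation reaction.

At fixed $\mu$ the model is an ordinary linear feasibility problem

$$S(\mu)\,v = 0,\qquad lb \le v \le ub,\qquad v_\mathrm{growth} = \mu,$$

and a model "grows at $\mu$" iff this LP is feasible. Because raising
$\mu$ only inflates dilution and machinery terms, feasibility is monotone
non-increasing in $\mu$ for the models the generators produce, and the
maximum growth rate is found by bisection between a feasible floor and an
infeasible ceiling (`maximizeGrowth()`). This feasibility-bisection
formulation — rather than putting $\mu$ in an objective — keeps the
problem linear at every step.

Flux variability analysis (`fluxVariability()`) then minimizes and
maximizes each reaction's flux with growth pinned at a fraction of the
optimum (default 1.0; the fraction is exposed as a parameter because the
choice is genuinely open). Gene essentiality (`geneEssentiality()`)
closes a gene's translation reaction and retests feasibility at
$\mu_\mathrm{test} = 10^{-3}$ 1/h: without synthesis, an enzyme cannot be
maintained against dilution, so every reaction it catalyzes dies
transitively — no explicit gene–reaction rules are needed.
`stripExpression()` removes expression-subsystem reactions and all
$b$-terms, producing the metabolism-only "M-analog" whose optimum always
dominates the coupled model's (it is a relaxation).

# Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `tol` (LP feasibility) | `1e-9` | – | double-precision active-set solves are reliable to ~1e-12 on these well-conditioned toy models; 1e-9 leaves two orders of headroom. Residuals are judged per constraint row relative to its largest live coefficient (see *Numerical choices*). |
| `bisectTol` | `1e-6` | 1/h | growth resolved far below any quantity compared across models; ~21 feasibility solves per maximization. |
| `muMaxHint` | 2 (models), 3 (minicell) | 1/h | bisection ceiling; must exceed any attainable growth rate, including the M-analog's linear optimum across the scan range. |
| `muTest` (essentiality) | `1e-3` | 1/h | the conventional "can it grow at all" probe: small enough that yield effects vanish, large enough that expression coupling binds. |
| `fraction` (FVA) | 1.0 | – | variability at the full optimum; configurable because sub-optimal fractions are equally defensible. |
| `alpha` | 0.05 | – | classification threshold on raw one-tailed MWU p-values; BH-adjusted columns are emitted alongside for reference. |
| `pccFloor` | 0.9 | – | replicates below this pairwise correlation (log10 CPM+1) fail QC. |
| `minGenes` | 3 | genes | pathways with fewer included genes are reported `ns` with a flag rather than tested. |

# The minicell generator

`makeMinicell()` builds the smallest ME model that reproduces two
signature behaviors of expression-coupled models: **proteome-limited
growth saturation** and **overflow metabolism**.

Its metabolic side has a substrate exchange, a high-yield respiration
branch ($Y_r = 0.1$ gDW/mmol) with a redundant but less efficient isozyme,
a low-yield overflow branch ($Y_o = 0.07$) secreting its by-product, and
six small biosynthesis modules that each route a share of biomass through
their own subsystem (these exist so that subsystem-level benchmarking has
~9 informative points instead of 3). The expression side has one
translation reaction per enzyme and a self-replicating ribosome
($L_{rib} = c = 3\times10^4$, i.e. a hard ceiling of 1/h where a ribosome
can no longer replicate itself — the right order for a fast-growing
bacterium).

The per-substrate biomass return of branch $i$ at growth rate $\mu$ is

$$s_i(\mu) = Y_i - m_{aa}\,\mu\,g(\mu)\,L_i/k_{\mathrm{eff},i},
\qquad g(\mu) = \frac{1}{1 - \mu L_{rib}/c},$$

where $m_{aa}$ is the biomass cost per amino acid polymerized and
$g(\mu)$ accounts for ribosomes translating ribosomes. Respiration must
have both the higher yield and the higher proteome cost
($L/k_\mathrm{eff}$: 0.4 vs 0.2 by default) — the generator refuses
parameters violating this ordering, because without it overflow
metabolism cannot arise.

Two regimes shape the uptake scan (`substrateScan()`):

1. **uptake-limited**: all substrate is respired; $\mu$ solves
   $\mu = s_r(\mu)U$ and the curve is strictly concave because $s_r$
   falls with $\mu$;
2. **capacity-limited**: the respiratory machinery has a finite
   expression capacity (`respTranslationCap`, a bound on its translation
   flux — biologically, limited membrane real estate and expression
   bandwidth for the respiratory chain). Once it saturates, every extra
   unit of uptake can only be catabolized through the proteome-cheap
   overflow branch, so secretion rises continuously from zero at a finite
   onset (~5 mmol/gDW/h by default) while growth keeps bending toward its
   proteome-limited ceiling.

Because the capacity bound lives on a translation reaction, it vanishes
under `stripExpression()`: the M-analog grows linearly ($\mu = Y_r U$)
across the whole scan and secretes nothing — the contrast the scan
criteria test. The bound is implemented as a plain flux bound rather than
a budget pseudo-metabolite after an explicit design exploration: a hard
budget on *synthesis flux* couples capacity as $P/\mu$, which makes the
mixing region of the growth curve slightly convex, while a capacity on
the machinery's translation makes the onset kink and the post-onset curve
concave — matching the qualitative shape expected of proteome-limited
growth.

`randomMinicellParams(seed)` jitters yields, catalytic rates, lengths and
the capacity within ranges where all structural invariants hold by
construction; the overflow branch's cost is drawn as a 0.35–0.65 fraction
of respiration's so the cost ordering can never be violated by an
unlucky seed.

# The omics generator

`simulateCounts()` draws paired RNA-Seq/Ribo-Seq counts for a universe of
genes partitioned into pathways (default: 50 pathways × 10 genes + 100
background genes, 3 replicates, 5×10⁶ reads):

* **abundance** is hierarchical log-normal: pathway baselines spread with
  `sdlogBetween = 2.0` (natural log) and genes scatter around their
  pathway baseline with `sdlogWithin = 0.3`. Two requirements drive this
  choice. Mean counts must span ≥ 4 orders of magnitude, which fixes the
  between-pathway spread. And a planted two-fold TE effect must move a
  pathway's Ribo ranks measurably past its RNA ranks: the rank shift a
  fold-change produces is set by the *local* density of competing genes,
  so with one flat log-normal wide enough for the dynamic range, a 2×
  effect moves ranks by only ~10% of the gene list and a 10-gene
  Mann–Whitney test has ~20% power. Tight within-pathway spread — the
  signature of co-regulated bacterial operons — concentrates that
  density, giving ~95% recovery at the default depth. This was settled by
  power analysis before the defaults were frozen;
* **TE** is the pathway's planted multiplicative effect times gene-level
  log-normal noise (`sdlogTE = 0.2`);
* **counts** are negative binomial (`dispersion = 0.1`) around
  abundance × depth for RNA and abundance × TE × depth for Ribo, each
  assay renormalized to its library size (sequencing is compositional)
  and scaled by per-replicate log-normal depth factors;
* RNA and Ribo are conditionally independent given the latent abundances
  — the two libraries are prepared separately, so no shared technical
  noise is modeled.

One consequence worth knowing: the NB dispersion does not average away
with depth, so gene-level TE estimates converge to the truth in *shape*
but retain a dispersion-limited error floor (~0.17 median absolute log
error at 3 replicates). Deeper sequencing removes Poisson noise only;
more replicates would be needed to go below the floor.

## The exchangeable null

`nullOmicsDesign()` sets all abundances equal and all TE effects to 1.
This is the design used to verify type-I error calibration of the
right-tailed Mann–Whitney test, and the flatness is essential: the test
compares the Ribo ranks of a pathway's genes against the RNA ranks *of
the same genes*. Under heterogeneous abundance those two rank vectors are
strongly paired through the shared abundances, and the unpaired MWU
becomes conservative (empirical rejection far below nominal) rather than
miscalibrated. With exchangeable genes, ranks in the two datasets are
driven by independent counting noise and the test attains its nominal
level (empirically ~0.044 at $\alpha = 0.05$ over 10⁴ pathway tests).
This mirrors the test's intended use: it detects *relative rank shifts*,
and its p-values are meaningful exactly when genes are comparable.

# The analysis chain

`cpmNormalize()` implements counts-per-million exactly
($CPM = 10^6 \cdot \mathrm{count}/\mathrm{column\ total}$).
`replicateQC()` computes pairwise Pearson correlations and two-tailed
Welch t-tests on $\log_{10}(CPM+1)$ — the log scale keeps the handful of
highly expressed genes from dominating both statistics. `geneTE()` is
the ratio of replicate-mean Ribo CPM to replicate-mean RNA CPM; genes
with zero mean RNA CPM are excluded (`included = FALSE`) rather than
pseudocounted, because any pseudocount choice would dominate exactly the
genes where the data say least.

`pathwayPrioritization()` ranks all included genes by replicate-mean CPM
within each dataset (averaging before ranking keeps ranks well-defined
and symmetric in the replicates; a per-replicate ranking mode was
considered and rejected as it triples tie handling for no statistical
gain), then runs right- and left-tailed Mann–Whitney U tests per pathway.
The U statistic uses the exact distribution when the combined sample is
≤ 25 and tie-free, and the normal approximation with tie and continuity
corrections otherwise. Classification is `up` iff mean TE ≥ 1 and right
p < α, `down` iff mean TE ≤ 1 and left p < α, else `ns`.

`aggregateSubsystem()` sums *absolute* values per subsystem — signed sums
could cancel opposing fluxes within a subsystem — and applies
$\log_{10}(f+1)$, which maps zero activity to zero and tames the
order-of-magnitude spread. `correlateProfiles()` regresses omics on
model (OLS with pointwise 95% CI) and reports the Pearson correlation on
the same pairs; when the omics profile carries all replicates (stacked),
every sample row enters the regression. Genes annotated to several
subsystems contribute to each; ids without annotation go to an `unmapped`
report, never silently away.

# Numerical choices

* **Feasibility backend.** The hot path (bisection, grid scans,
  knockouts) uses a compiled active-set quadratic-programming solve of
  the min-norm feasible point; infeasibility is the solver's
  "inconsistent constraints" verdict. Three safeguards make this robust:
  fixed variables (closed reactions, the pinned growth flux) are
  substituted out of the system, because their unit rows become
  numerically collinear with weakly coupled balance rows
  ($\mu/k_\mathrm{eff} \sim 10^{-6}$ at $\mu = 10^{-3}$); rows are
  equilibrated to unit scale; and the equality block is QR-reduced to an
  independent subset, with the full original system re-verified on the
  returned point so that an inconsistent dependent row can never be
  silently dropped.
* **Scale-aware residuals.** A residual is judged relative to its row's
  largest live coefficient. This matters for essentiality: a knocked-out
  enzyme's balance row has only the tiny $\mu/k_\mathrm{eff}$ coupling
  left, and on a raw-residual criterion a violating flux of $5\times
  10^{-5}$ would slip through as a $10^{-10}$ "residual", making weakly
  coupled constraints unenforceable in double precision.
* **Objective LPs** (FVA, parsimonious flux vectors) use a dense simplex
  method with variables shifted to the nonnegative orthant, equality
  right-hand sides sign-normalized, fixed variables substituted out and
  rows equilibrated — each of these transformations removes an input
  class the simplex implementation handles incorrectly or not at all.
* **Tie-breaking among alternate optima.** `maximizeGrowth()` reports a
  parsimonious vertex (minimum total absolute flux over sign-fixed
  reactions) at $\mu^\*$. Without this, the min-norm point spreads flux
  across parallel branches and a scan shows phantom trace secretion
  below the overflow onset. Downstream comparisons that depend on
  alternate optima use FVA ranges, not the flux vector.
* **Monotone feasibility** is an assumption of bisection, not something
  bisection can detect (each midpoint is probed once). It is enforced as
  a property of the generators and tested as such over seeded variants;
  models violating it would indict the generator, not the solver.
* **FVA ranges near zero.** With bisection tolerance $\delta$, growth is
  pinned at $\mu^\* - O(\delta)$, leaving each flux a slack of order
  $\delta / s$ for effective yield $s \approx 0.03$; comparisons
  therefore treat ranges below $10^{-5}$ mmol/gDW/h as numerically zero.

# Problem sizes used by the test suite

The suite exercises: 25 seeded minicell variants against an exhaustive
$10^{-4}$-step feasibility grid; 20-point uptake scans of the default
minicell and its M-analog; 200 null simulations × 50 pathways
($10^4$ pathway tests) for type-I calibration; 200 seeded simulations
with a planted 2× effect on a 10-gene pathway for recovery; and
three seeds of the coupled flux-to-omics benchmark. These sizes give
Monte-Carlo standard errors comfortably inside the asserted bands
(e.g. ±0.004 on the 0.05 rejection rate).

# What passing tests do and do not show

The generators emulate the *mechanisms* — growth-rate-coupled expression
cost, proteome limitation, overflow onset, overdispersed paired counts
with planted translational effects — not any real organism. Real
genome-scale ME models are four orders of magnitude larger and severely
ill-conditioned (their solvers resort to quad precision); real Ribo-Seq
has positional structure, rRNA contamination and batch effects that the
count model deliberately omits. Passing tests show the algorithms are
correct on well-conditioned instances of the right structure, and that
the statistical pipeline is calibrated and powered under its own model
of the data; they do not certify numerical adequacy at genome scale nor
robustness to artifacts upstream tools are supposed to remove.

# Session info

```{r}
sessionInfo()
```
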