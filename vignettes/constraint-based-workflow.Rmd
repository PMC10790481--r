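---
title: "Constraint-based reconstruction and analysis with gemflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based reconstruction and analysis with gemflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemflux)
```

## The modelling framework

gemflux implements the standard constraint-based analysis stack for
genome-scale metabolic models (GEMs) of bacteria such as *Pseudomonas
putida*: a GEM is a network of reactions $j$ with stoichiometric
coefficients $S_{ij}$ over metabolites $i$, flux bounds
$l_j \le v_j \le u_j$ (mmol/gDCW/h), and boolean gene-protein-reaction
(GPR) rules. Flux balance analysis (FBA) assumes an internal steady state
and solves the linear program

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\; l \le v \le u,$$

usually with $c$ selecting a biomass pseudo-reaction whose flux is the
specific growth rate $\mu$ (h$^{-1}$). Exchange reactions connect the
network to the environment; by the usual sign convention uptake is a
negative exchange flux, so a growth medium is a table of maximum uptake
rates that become lower bounds $-\text{rate}$ (`apply_medium()`), with
secretion left open.

Only the optimal *objective value* of an FBA problem is unique. Flux
distributions at the optimum are generally degenerate, so the package
contracts nothing about individual fluxes; downstream utilities that look
at flux vectors (e.g. `correlate_fluxes()`) are explicitly comparisons of
one particular optimal solution.

### The LP solver

All FBA problems are solved by a dense bounded-variable two-phase primal
simplex written for this package (`lp_solve()`), with Bland's
smallest-index pivoting rule throughout because FBA bases are massively
degenerate and cycling is otherwise a real risk. Feasibility and
optimality tolerances are $10^{-9}$; every optimal solution is
additionally checked to satisfy $\lVert S v\rVert_\infty \le 10^{-6}$.
The basis is refactorised at every pivot, an $O(m^3)$ step that is
entirely acceptable at the network sizes the package targets in its test
and fixture tier (tens of reactions; the algorithm itself has no size
limit beyond patience). The solver is validated in the test suite against
an independent vertex-enumeration oracle on every toy network shape and,
through the SBML writer, against an external constraint-based toolchain.

## Growth screening and the 5% call rule

`simulate_carbon_source()` screens sole carbon sources: the base medium is
applied carbon-free with all other exchanges closed, one carbon exchange is
opened at a maximum uptake (default 10 mmol/gDCW/h), and the biomass
objective is maximised. A substrate with no exchange reaction in the model
is reported as growth 0 with a flag — that is the model predicting
non-growth, not an error. A substrate is *called* growing when its
simulated rate reaches at least 5% of the reference (glucose) rate;
because the underlying rule defines non-utilisation as *less than* 5%,
a rate exactly at the threshold counts as growth (`call_growth()`).
The same strict-inequality reading applies to gene essentiality below.

## Maintenance energy: Pirt's law, NGAM, GAM

Chemostat cultures at steady state obey Pirt's relation

$$\frac{1}{Y} = \frac{m}{\mu} + \frac{1}{Y_G},$$

with observed yield $Y$, maintenance coefficient $m$ and maximum yield
$Y_G$. `fit_pirt()` is ordinary least squares of $1/Y$ on $1/\mu$ (slope
$m$, intercept $1/Y_G$), via `lm()` so standard errors and diagnostics
come for free. Literature constants are often on a protein basis;
`convert_pirt_units()` rescales them to dry-cell-weight and molar-glucose
units,

$$m_{\mathrm{DCW}} = m_{\mathrm{prot}} \cdot
  \frac{f_{\mathrm{prot}}}{M_{\mathrm{glc}}} \cdot 1000,$$

with glucose molar mass fixed at 180.16 g/mol. With $m = 0.023$ g
glucose/g protein/h, $Y_G = 1/3$ g protein/g glucose and a 60% protein
fraction this gives the glucose-consumption line $q = 10\,\mu + 0.077$
(mmol/gDCW/h) after rounding to the customary display precision.

Two maintenance parameters enter the model separately:

* **NGAM** (non-growth-associated, mmol ATP/gDCW/h) — `compute_ngam()`
  fixes glucose uptake at $m_{\mathrm{DCW}}$, relaxes the ATPM lower
  bound to zero (only inside this computation; it stays active
  everywhere else), does not require growth, and maximises the ATPM flux.
  The ATPM reaction is found by id `"ATPM"` first, else by its
  ATP + H₂O → ADP + Pi (+ H) stoichiometry with no GPR.
* **GAM** (growth-associated, mmol ATP/gDCW) — the ATP-hydrolysis
  coefficient of the biomass equation. `fit_gam()` scans a grid of
  candidates; for each one it installs the NGAM as the ATPM lower bound,
  fixes growth at each $\mu \in \{0.1, \dots, 0.7\}$ h$^{-1}$ (the
  working range of glucose-limited chemostats) and *minimises* glucose
  uptake — mirroring what a chemostat actually observes — then returns
  the grid point minimising the squared deviation from the target line
  $q(\mu)$. The least-squares criterion, the $\mu$ evaluation set and the
  default grid spacing (0.01 mmol ATP/gDCW at genome scale) are design
  choices of this package: the calibration literature typically says
  only "closest fit". Recovery is exact when the grid contains the true
  value and bounded by the grid spacing otherwise, which the tests assert.

## Biomass composition from the genome

`biomass_from_genome()` estimates monomer fractions the way biomass
equations are conventionally built from an annotated genome: amino-acid
fractions from translated coding sequences; dNTP fractions from the
double-stranded genome (sequence plus reverse complement, which forces
$f_A = f_T$ and $f_C = f_G$); NTP fractions from the coding-strand
nucleotide frequencies of the annotated genes. The NTP proxy deliberately
ignores transcript abundance — a transcriptome-weighted composition is out
of scope. Coefficients are

$$\mathrm{coef}_i = w_M \cdot \frac{f_i}{\sum_j f_j\, MW_j} \cdot 1000
  \;\; \text{mmol/gDCW},$$

with *polymerised* residue masses (monomer minus water) so each
macromolecule's coefficients multiply back exactly to its mass fraction
$w_M$. Lipid and cofactor composition is not measured here; real models
inherit those terms from a curated donor biomass equation.

## Gene essentiality

`screen_essential_genes()` evaluates every single-gene deletion: a
reaction is disabled (both bounds zeroed — rows are kept, so the matrix
and index maps are reused across the ~$n_{\text{genes}}$ LPs of a sweep)
when its GPR rule evaluates false without the gene; AND means complex, OR
means isozymes, the empty rule means no gene dependence. Genes whose
deletion disables nothing reuse the wild-type solution without a new LP.
A gene is essential when deletion growth falls strictly below 5% of wild
type. Multi-gene deletions must be passed to `delete_gene()` as one set —
GPR rules are re-evaluated against the whole set, which sequential
single-gene calls cannot emulate. `compare_essential_sets()` partitions
two essential sets across an ortholog map for strain-vs-strain
comparisons.

## Dynamic FBA

`run_dfba()` implements the static-optimisation formulation of dynamic
FBA for batch culture: at each Euler step the uptake bound of every
capped substrate is $\min(v_{\max}, S/(X\,\Delta t))$ — so pools cannot
go negative — the FBA is solved, then

$$X \leftarrow X\,(1 + \mu \Delta t), \qquad
  S \leftarrow S + v_{\mathrm{ex}}\, X\, \Delta t .$$

Concentrations are mM with culture volume normalised to 1 L, making mmol
pools numerically equal to mM. Default protocol: 10 mM glucose, 0.01 g/L
inoculum, $v_{\max} = 6.5$ mmol/gDCW/h, $\Delta t = 0.1$ h; the step and
horizon defaults are this package's own (the source protocol leaves them
unstated). Integration is first order: against the analytic exponential in
substrate excess, the relative error is $\approx t \mu^2 \Delta t / 2$
and halves with the step, which the tests verify, along with substrate
bookkeeping closing to $10^{-6}$ relative. The simulation stops at the
horizon, on infeasibility, or when all capped substrates are below
$10^{-9}$ mM with growth below $10^{-9}$ h$^{-1}$. Michaelis–Menten
uptake kinetics, oxygen transfer and fed-batch feeds are out of scope.

## Draft reconstruction, gap-filling and phenotype refinement

The reconstruction workflow consumes standard tabular alignment output
(qseqid, sseqid, pident, qcovs, evalue) rather than running an aligner —
that keeps tests deterministic and the package binary-free.
`map_homologs()` applies the homolog rule strictly: identity *over* the
threshold and coverage *over* the threshold (90/90 by default; a record at
exactly 90.0 fails), one best hit per query by (identity, coverage,
−E-value), ties broken by the lexicographically smaller subject id so the
result is independent of record order. A screening mode with coverage 90,
identity 40 and E ≤ 2e-21 serves the automated-reconstruction side.

`assemble_draft()` transplants the cited donor reactions — primary donor
first, secondary only for ids not already present — rewriting GPRs into
the target gene namespace. `gap_fill()` searches candidate additions in
deterministic pool order, singletons then unordered pairs (the default
`max_set_size = 2`; anything larger is combinatorial and warned about),
returns the first set restoring growth, and verifies minimality by
re-testing with each member dropped. Unfillable drafts are reported with
dead-end metabolite diagnostics rather than an error.

`refine_with_phenotypes()` reconciles predictions with phenotype-
microarray (PM) observations: false positives lose their exchange
reaction; false negatives gain the exchange and transport reactions of a
supplied evidence table (with GPR); false negatives without evidence are
only logged. Every modification lands in a change log. Raw PM kinetics are
out of scope — the package consumes binary call tables, with
`call_from_curve()` provided as a deliberately simple caller for synthetic
curves only.

## Synthetic fixtures and what passing tests show

Every stage has a generator with analytically known truth
(`make_toy_model()`, `make_chemostat_data()`,
`make_reconstruction_fixture()`, `make_phenome_fixture()`), all pure
functions of an explicit seed that save and restore the caller's RNG
state. The toy network is layered — exchange → periplasmic and
cytoplasmic transport → an energy reaction ($E$ ATP per carbon), a
precursor reaction ($A$ ATP per precursor), ATPM, biomass ($P$ precursor
and $G$ ATP per unit flux) — so its optimum has the closed form

$$v^* = k\,\frac{E\,U - \mathrm{NGAM}}{G + P\,(A + E)}$$

for total uptake $U$ and biomass scale $k$; defaults $E{=}2$, $A{=}1$,
$P{=}1$, $G{=}2$, $U{=}10$ give $v^*{=}4$. Fixtures are written in the
same formats the pipeline reads (SBML, TSV, FASTA), so I/O code is
exercised rather than bypassed, and they stay at toy scale (≤ ~50
reactions) by design. Passing on them demonstrates correctness of the
algorithms — the LP optimum, the GPR logic, the calibration arithmetic,
the bookkeeping — not fidelity to any real organism's network: fixtures
have none of the redundancy, compartment richness, cofactor coupling or
blocked-reaction structure of a curated GEM, and quantitative claims about
a real strain require that strain's model and data.

## Numerical choices and limitations

* Bounds default to (−1000, 1000) for reversible and (0, 1000) for
  irreversible reactions when a source omits them.
* Reaction categories follow precedence explicit annotation → id prefix
  (`EX_`, `DM_`, `sink_`/`SK_`) → single-extracellular-metabolite
  heuristic; unknown compartment suffixes are carried along as extra
  compartments, never rejected.
* Reported-value comparisons in tests use $10^{-2}$ absolute where a
  quantity is conventionally printed with two decimals; algebraic
  identities are tested to $10^{-9}$ or tighter.
* The simplex refactorises rather than updates; genome-scale sweeps
  (thousands of LPs on thousands of reactions) will work but are not the
  performance tier this implementation is tuned for.
* SBML support covers Level 3 core + fbc v2 (bounds as parameter
  references, GPR association trees, objectives) — the subset the
  surrounding ecosystem writes; kinetic laws, units and annotations
  beyond gene labels are ignored.
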