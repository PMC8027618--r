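---
title: "Models and estimators in crisprcost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in crisprcost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprcost)
```

`crisprcost` studies a specific eco-evolutionary question: why bacteria that
defend against lytic phage with CRISPR-Cas — an apparently cheap, targeted
immune system — are nonetheless displaced by receptor (surface) mutants when
phage pressure is sustained. The working hypothesis is an *infection-induced*
cost: a CRISPR-immune cell that is injected by a phage genome clears it, but
phage genes are expressed before clearance and can poison the cell, so the
cost of immunity is paid per infection, while the surface mutant pays a fixed
constitutive cost and is never injected. The package provides (i) a
serial-transfer competition model embodying that trade-off, (ii) an amplicon
workflow and estimators for the population-genomic signals involved
(spacer diversity, self-targeting acquisition, competitive fitness), (iii) an
expression-time-course toolkit for the phage transcriptional programme, and
(iv) seeded generators for all inputs, so every claim is testable on
synthetic data.

## The serial-transfer model

Within one growth cycle (a "day"), densities of sensitive (`S`),
CRISPR-immune (`C`) and surface-mutant (`M`) bacteria and free phage (`V`)
follow

$$
\begin{aligned}
\dot S &= r S g - a S V, &
\dot C &= r C g - a C V\,(\tau + p\,q), \\
\dot M &= r (1 - c_{sm}) M g, &
\dot V &= b\,a S V - a (S + C) V - d V,
\end{aligned}
$$

with logistic crowding $g = 1 - N/K$, $N = S + C + M$. The structural
commitments are: infections of `S` are lytic with burst size $b$; infections
of `C` are cleared, but kill the cell with probability
$\tau_{tox} + p\,q_{self}$ (induced toxicity, plus acquisition of a lethal
self-targeting spacer — only possible when acquisition happens at all, hence
the factor $p$); `M` has lost the receptor, is never adsorbed, and pays the
constitutive cost $c_{sm}$; every adsorption removes one free phage; free
phage decay at $d$. Optional influx terms (`mu_sm`, per sensitive division;
`mu_bim`, per sensitive infection survived by acquiring immunity) default to
zero: the competition scenarios are run from standing variation
(frequencies 0.45/0.45/0.10) so that selection, not mutation supply, drives
the outcome.

Default parameters are order-of-magnitude standards for a
*Pseudomonas*–phage batch culture: $r = 1\,h^{-1}$, $K = 10^9$ CFU/mL,
$a = 10^{-8}$ mL/h, $b = 50$, $d = 0.1\,h^{-1}$, $c_{sm} = 0.05$,
$\tau_{tox} = 0.3$, $p = 0.01$, $q_{self} = 0$. The transfer protocol is a
1:100 daily dilution of a 6 mL culture for 30 days, seeded with $10^6$ cells,
with $10^7$ PFU of ancestral phage added at time zero and at every transfer
(converted to per-mL densities through the culture volume).

Integration uses `deSolve`'s `lsoda` with `rtol = 1e-8`, `atol = 1e-6`; the
right-hand side clamps the tiny negative excursions adaptive steppers probe,
and end-of-day states are clipped at zero with the number of clipped entries
recorded. Against the closed-form logistic solution (phage-free, single
genotype) the integrator is accurate to better than $10^{-6}$ relative error.
Outcome classification calls the CRISPR genotype *extinct* below one cell per
culture, and a *decline* when its frequency ratio to the surface mutant drops
by more than $10^{-3}$ over the experiment.

### The scenario triad

`run_scenarios()` contrasts three parameterisations that isolate candidate
cost mechanisms:

* **baseline** — induced toxicity only ($\tau_{tox} = 0.3$, $q_{self} = 0$):
  the CRISPR genotype declines against the surface mutant;
* **no cost, no acquisition** ($\tau_{tox} = 0$, $p = 0$): immunity is free
  and cannot self-harm; no decline;
* **no cost, high self-targeting** ($\tau_{tox} = 0$, $p = 0.5$,
  $q_{self} = 0.9$): no toxicity, but acquisition is frequent and
  overwhelmingly self-directed. "High self-targeting" is a qualitative
  notion; we fix $p\,q_{self} = 0.45$ so the per-infection kill probability
  is of the same order as the baseline toxicity, making the two cost routes
  comparable. The CRISPR genotype declines.

### What the minimal model cannot reproduce, and why

The experimental trajectory this model emulates has a characteristic shape:
CRISPR immunity rises above 50% within the first few days, then surface
mutants overtake it by day 30 *while phage persists*. The minimal model
reproduces the second half but not the first, and the reason is structural,
not a matter of tuning. Write $X = \int a V\,dt$ for the per-cell phage
exposure of a day. The CRISPR genotype loses $\tau_{tox} X$ in log-frequency
per day against an uninfectable competitor, which loses $c_{sm} \ln(1/\text{dilution})$.
For the late overtake one needs sustained $X$ with
$\tau_{tox} X > c_{sm}\ln 100$; for the early CRISPR rise one needs small
early $X$. But in this model exposure is *front-loaded*: phage can only
amplify on sensitive cells, so the epidemic happens first and its cumulative
exposure is bounded by how far the sensitive population falls, while the
daily re-addition of $10^7$ PFU spread over the post-dilution population
contributes a multiplicity of infection of at most ~0.17 per day — an order
of magnitude below what the overtake requires at these costs. Once
sensitives fall below the phage-growth threshold they cannot recover against
the (constitutively cost-free) CRISPR genotype, so phage pressure
self-quenches. We verified this across ~150 structured parameter sweeps and
700 random parameterisations spanning five orders of magnitude in the
adsorption rate: no core parameterisation yields both the early peak and the
late overtake.

Biologically, the missing ingredient is phage counter-adaptation: escape
mutants that evade CRISPR interference replicate on the (abundant) immune
population, which back-loads phage exposure exactly as observed. The model
therefore carries an optional escape compartment `E` — escape phage arise as
a fraction `mu_escape` of burst progeny, replicate on both `S` and `C`, and
never infect `M`. With `mu_escape = 0` (the default) the model reduces
exactly to the four-variable core above. With the extension enabled,

```{r escape, eval = FALSE}
p <- model_params(a = 1e-10, b = 10, tau_tox = 0.3,
                  mu_bim = 1e-2, mu_sm = 1e-4, mu_escape = 1e-5)
traj <- run_serial_transfer(p, init_freqs = c(1, 0, 0))
plot_frequencies(traj)
```

an all-sensitive inoculum evolves CRISPR immunity above 50% by day 2 (via
acquisition during the primary epidemic), and escape-phage pressure then
drives the surface mutant past it by day 30 with CRISPR still segregating —
the full experimental shape. The gentler adsorption rate here keeps the
primary epidemic from annihilating the newly immune cells within a day;
the default `a = 1e-8` with mass re-infection compresses all exposure into
day 1.

## Synthetic-data generators

**Spacer acquisition** (`simulate_spacers()`): each of `n_events`
acquisitions independently targets the host genome with probability
`frac_self` (else the phage), and uses a canonical PAM with probability
$\rho/(1+\rho)$. Phage protospacer positions follow a discretised Laplace
kernel centred on the priming site (default coordinate 27847, spread
2000 bp) and truncated to the genome by rejection — the minimal peaked,
symmetric model of primed acquisition. Host positions are uniform.
Canonical-PAM self-targeting events are autoimmune; their abundance is
multiplied by `selection_against_self_canonical` before reads are drawn
multinomially to `read_depth`. Three fields beyond the obvious ones exist
because the positional model needs them: `genome_length` (36,415 bp, a
typical small lytic phage), `host_genome_length` (6.54 Mb), and
`spacer_length` (32 nt, a type I-F array spacer).

**Competition counts** (`simulate_competition()`): the marked-strain
frequency follows the logit-linear model
$\mathrm{logit}(x_t) = \mathrm{logit}(x_0) + s\,t$ and each plating is a
binomial draw of `colonies` scored colonies.

**Expression counts** (`simulate_expression()`): host genes have log-normal
baseline means constant in time; phage genes follow early/middle/late
temporal shapes (peaking at the second, third and last timepoint of the
0/35/60/120-minute design) with log-normal amplitudes; counts are negative
binomial with a shared dispersion (default 0.05), the standard RNA-seq count
model. Uninfected controls have phage means of exactly zero. The
CRISPR-immune (BIM2) infected group has phage means divided by
`phage_attenuation` (default 5). The phage share of the infected wild-type
library defaults to 3%: because *fractions* rather than raw counts are
compared across groups, the ratio of group mean fractions recovers the
attenuation factor only up to a factor $(H + P/5)/(H + P)$, which stays
within a few percent of 1 only while the phage share $P$ is small.

**Clone phenotyping** (`sample_clone_phenotypes()`): a multinomial draw of
24 clones from the genotype frequencies, as when streaking clones against a
phage panel.

`synthesize_amplicons()` closes the loop for the end-to-end demo: it plants
each simulated spacer at a genome position whose adjacent dinucleotide
matches its PAM class, builds repeat–spacer–repeat merged reads (one per
sequenced read, with optional substitution noise), and so produces raw
amplicon input whose downstream classification recovers the generating
target and PAM labels exactly.

## The amplicon workflow

Merged reads are size-selected per locus (30–140 bp for the short array,
70–500 bp for the long one, bounds inclusive) to remove primer-dimer
artefacts. Spacers are extracted by repeat anchoring: every occurrence of
the repeat with at most two substitutions is located, overlapping hits are
resolved greedily left-to-right, and inter-repeat segments are returned in
order; segments flanked by only one repeat are flagged partial and excluded
from clustering by the pipeline.

Clustering (`swarm_cluster()`) is single-linkage agglomeration on the edit
distance (substitutions *and* indels, via generalised Levenshtein): variants
within distance `d` (default 1, the strictest setting) link, clusters are
connected components grown greedily from the most abundant unassigned seed,
and the centroid is the highest-count member with lexicographic
tie-breaking. Because components are order-independent and all ties break on
canonical sort order, the output is invariant to input shuffling — verified
against a brute-force connected-components oracle on random variant sets.
The minimum-cluster-size filter (default 2) counts total reads, not unique
sequences; with unit counts the two conventions coincide, and read counting
is the stricter and more common convention for abundance tables.

Per-sample abundances are assigned by global identity to the centroid:
identity is one minus the edit distance over the longer sequence length,
with threshold 0.99 over the entire length; ties go to the more abundant
centroid and failures are kept in an `unassigned` row so column sums are
conserved.

Classification (`classify_spacers()`) maps each spacer exactly (no
mismatches — new spacers are copied verbatim from protospacers) against the
phage genome first, then the host, on both strands; multiple phage hits
resolve to the one nearest the priming site. The PAM is read on the
protospacer strand, by default the dinucleotide immediately 3' of the
protospacer, and called canonical when it equals `GG` — the type I-F
consensus for this host. Both the motif and the side are configurable
because PAM orientation conventions differ between systems; the defaults are
assumptions, not measurements.

## Estimators

**Diversity.** Observed variants, bias-corrected Chao1
($S_{obs} + F_1(F_1-1)/(2(F_2+1))$), Shannon entropy (natural log by
default; base 2 available), Simpson diversity $1-\sum p_i^2$ and Simpson
evenness (inverse Simpson over observed richness), all delegated to the
standard community-ecology routines in `vegan`. Rarefaction subsamples
counts *without replacement* (hypergeometric), 33 repetitions per depth by
default; a depth at or above the sample total returns the plug-in metric
exactly with a flag, so the curve's right endpoint is not a Monte-Carlo
estimate.

**Self-targeting frequency.** Canonical-PAM self-targeting spacers are
purged by autoimmunity, so counting them underestimates how often they are
acquired. Non-canonical-PAM self-targeters are nearly neutral, so their read
fraction estimates the *non-canonical* self-acquisition rate; multiplying by
the background canonical:non-canonical ratio $\hat\rho$ — measured among
phage-targeting spacers, which autoimmune selection does not touch — yields
the canonical (harmful) self-targeting cell fraction:
$\hat f_{self} = f^{nc}_{self} \times \hat\rho$. By default $\hat\rho$ uses
distinct spacer *types*, which post-acquisition selection distorts less than
read counts; `rho_from = "reads"` is available. The estimand is
$\texttt{frac\_self} \cdot \rho/(1+\rho)$, and simulation shows the
estimator stays unbiased under strong selection against canonical
self-targeters, which is its purpose; whether the denominator should be all
cells or only infected cells is not decidable from frequency data alone, so
the denominator is all sequenced reads.

**Competitive fitness.** The selection coefficient is the per-day change in
log-odds of the focal strain's colony frequency. Zero counts make the logit
infinite; rather than silently correcting, the fit stops with an error
suggesting the `pseudo_count = 0.5` continuity correction, and records the
correction when used. Uncertainty is a seeded percentile bootstrap (1000
binomial resamples); no p-values are produced — the package reports
estimates and intervals.

## Expression programme

Profiles are built by min–max normalising each replicate's gene timecourse
to [0, 1] and then averaging across replicates — in that order. The reverse
order (average, then normalise) is also exposed and differs whenever
replicates have different dynamic ranges (a two-replicate counterexample is
in the test suite); normalise-first weights replicates equally regardless of
depth. Constant timecourses cannot be rescaled; they map to zero and are
flagged. Counts enter profiles raw: min–max rescaling within a gene absorbs
library-size factors, and a CPM pre-step would only matter for cross-gene
comparisons, which the programme clustering does not make.

Clustering of profiles is agglomerative with complete linkage on Euclidean
distance (the defaults of the standard `hclust` routine), cut at `k = 3` for
the early/middle/late phases; genes are sorted lexicographically before
clustering so merge tie-breaking, and hence the output, is independent of
input order. On synthetic three-class programmes with Gaussian noise of
σ = 0.05, class recovery is essentially perfect, which shows the procedure
separates well-separated temporal archetypes — not that real phage
programmes are this clean.

## Problem sizes and determinism

The test suite and demo are sized to run comfortably on one CPU: the demo
amplicon time-series uses five samples of 2,500 reads (spacer richness
declining from 300 to 40 to emulate the observed loss of CRISPR diversity),
rarefaction at four depths × 33 repetitions, a 120 + 30 gene expression
design with five replicates, and twelve competition assays; estimator
recovery checks use $10^4$–$10^5$ acquisition events, $10^6$ reads, $10^5$
colonies, and 20–100 seeds. Every stochastic step takes an explicit seed,
derived in the pipeline from one global seed, and identical seeds give
byte-identical outputs; RNG state is restored after each seeded call.

## Limitations

The dynamics model is deterministic and well-mixed: no demographic noise
(stochasticity enters only through the phenotype sampler), no spatial
structure, no multi-spacer genotype tracking, and escape-phage coevolution
only as the optional single-parameter extension described above. The
generators emulate the statistical structure the analyses assume — they do
not simulate reads, quality scores, chimeras, or PCR bias, so passing tests
demonstrate correctness of the estimators under the stated models, not
robustness to raw-data artefacts. The PAM convention is configurable
precisely because it is an assumption; results that depend on it (the
self-targeting estimate above all) should be read with that in mind.
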