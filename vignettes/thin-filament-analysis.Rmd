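---
title: "Methods: structure, selection and survival analysis of thin-filament variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure, selection and survival analysis of thin-filament variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinfilament)
```

This vignette is the package's own account of its methods: the models and
procedures, the tunable parameters and their defaults, what the synthetic
generators do and do not emulate, and the numerical choices made where the
underlying conventions are genuinely open.

## Inter-chain contacts and calcium-state classification

A *contact* is a pair of residues on different chains whose minimum
atom–atom Euclidean distance is at most a cutoff. The default cutoff is
4 Å and the rule is **inclusive** (a pair at exactly 4.0 Å is a contact).
Distance-cutoff conventions in the literature are split between "closer
than" and "within"; we chose the inclusive reading, made the cutoff a
parameter of `interchain_contacts()`, and test the boundary explicitly, so
the choice is visible rather than buried.

All non-hydrogen atoms participate. Crystal structures generally lack
hydrogens; when a model does carry them, including them would make its
contact set incomparable with hydrogen-free structures, so hydrogens are
always ignored. Ligand (HETATM) atoms never enter the residue–residue
search; calcium ions are instead handled by `calcium_binding_residues()`,
which flags any residue with a heavy atom within the same cutoff of a Ca²⁺
ion — a deliberately operational definition, since "calcium-binding
residue" has no single structural definition.

Parsing (`read_structure()`, backed by `bio3d`) keeps the **first model**
of multi-model entries, resolves alternate locations by highest occupancy
(ties by altloc label order), discards waters, and retains other hetero
groups flagged as ligands. Chain-to-entity assignment (which chain is TnC,
TnI, TnT, actin, tropomyosin) is supplied by the caller: chain labels are
not comparable across crystallographic entries, and guessing them silently
would be worse than requiring one explicit line of configuration.

Because the calcium-free complex available for comparison is a skeletal
muscle structure from another species, its author numbering must be
translated to canonical human numbering before the two contact sets can be
compared. `build_residue_map()` pairs ungapped positions of two sequences
column by column in a multiple sequence alignment; columns gapped in either
sequence produce no pair, and contacts with unmapped endpoints are dropped
with a reported count rather than mapped to a sentinel.
`classify_contact_states()` is then pure set algebra on the union of the
two sets: `bound_only`, `free_only`, `common`. Structures that contribute
interactions without a state counterpart (e.g. a TnT–tropomyosin fragment)
are kept as separate, never state-classified, contact sets.

TnT analysis regions are 1–89, 90–129, 130–179 and 200–288, with 180–199
explicitly excluded (no structural interaction data to characterise it);
TnI regions are 1–130, 131–175, 176–210. The high/low risk strata over TnT
group {90–129, 130–179} against {1–89, 200–288}. Published descriptions of
the second high-risk region vary between an upper bound of 179 and 180; we
use 179 throughout for consistency with the region scheme, and the single
residue involved falls in the excluded interval either way.

## Conservation: Jensen–Shannon divergence

`jsd_conservation()` scores a column by the Jensen–Shannon divergence
between the column's empirical amino-acid distribution *p* and a background
*q*: with *m* = (*p* + *q*)/2, JSD = KL(*p*‖*m*)/2 + KL(*q*‖*m*)/2,
normalised to [0, 1] by log 2. The background is uniform by default (any
20-symbol distribution can be supplied); gaps are excluded from *p* and
reported separately as a gap fraction; an all-gap column is flagged `NA`.
Optional window smoothing combines the focal score with the mean of up to
`window` flanking scores at weight `1 − mix_weight` (defaults: window 0 —
off — and `mix_weight` 0.5). The scoring tool originally used for this kind
of conservation profile does not document its background or window, so both
are exposed as parameters rather than hard-coded.

## Site-specific Ka/Ks: a counting estimator

Maximum-likelihood codon models estimate site-wise selection well, but they
are heavy, opaque dependencies. We instead implement a transparent
Nei–Gojobori-style counting estimator, testable by exhaustive enumeration:

* **Potential sites** (`syn_nonsyn_sites()`): for each of the nine
  single-nucleotide changes of a codon, the fraction that are synonymous
  accumulates into S, the rest into N, so S + N = 3 exactly. Changes that
  create a stop codon count as nonsynonymous.
* **Observed differences** (`codon_path_counts()`): synonymous and
  nonsynonymous steps on minimal mutational paths between two codons, all
  orderings averaged with equal weight; paths through stop codons are
  excluded (if every path hits a stop, all paths are averaged with stop
  steps counted nonsynonymous).
* **Per column** (`site_kaks()`): each non-reference sequence ungapped at
  the column is compared with the reference codon; Sd, Nd and per-pair site
  counts (mean of the two codons' S and N) are pooled, proportions are
  Jukes–Cantor corrected (`K = −3/4 log(1 − 4p/3)`), and ω = Ka/Ks.

Conventions for the degenerate cases, all flagged in the output: a
proportion ≥ 0.75 cannot be JC-corrected and is used raw with a `saturated`
flag; Ks = 0 with Ka > 0 sets ω to a configurable cap (default 10) rather
than infinity; no observed substitutions at all leaves ω undefined;
columns with a gapped reference codon or fewer than 4 ungapped sequences
are returned undefined. The neutral band is |ω − 1| ≤ 0.05 by default —
"ω = 1 is neutral" needs *some* tolerance on an estimate, and the width is
a parameter.

Because this is a counting estimator fed by simulated ortholog sets rather
than a Bayesian site model fed by database orthologs, the package makes no
claim to reproduce any particular published per-protein ω range; what it
demonstrates, and what the acceptance checks measure, is *recovery*:
purifying (ω = 0.05) and neutral (ω = 1) sites simulated at 26 taxa are
separated with ≥ 90% accuracy, calling a site purifying when its estimate
falls below the geometric midpoint √0.05 ≈ 0.22 (a site with no observed
substitutions is maximally conserved and counts as purifying).

## Codon mutability and hotspots

`arginine_codon_census()` tallies the six arginine codons across a CDS;
the counts always sum to the number of arginines in the translation.
`find_cpg_codons()` flags a codon as CpG-containing when "CG" occurs
inside it (offsets 1–2 or 2–3) — note this covers all four CGN codons. A
codon ending in C followed by one starting with G is a *junction* CpG,
reported in a separate column when requested and never merged into the
in-codon flag, because the two have different mutational consequences for
the codon itself.

`call_hotspots()` marks sites whose index-case count reaches a threshold.
Recurrence has no canonical cutoff; the default is 5 index cases and the
threshold is recorded in the output. Association between phenotype and
gene/region uses Pearson's chi-square without continuity correction
(matching the convention of the clinical statistics packages such tables
are usually analysed with); the fraction of cells with expected counts
below 5 is reported, and a Fisher exact option exists for small tables.

## Survival analysis

Time origin is **birth**: age at last follow-up is the time scale, because
literature-curated cohorts rarely report consistent follow-up-from-
diagnosis. Events are cause-specific flags (cardiovascular death overall;
sudden cardiac death; heart-failure death/transplant; stroke death;
procedure-related death); for a cause-specific endpoint, deaths from other
causes are right-censored at the death age. This is the classical
cause-specific Kaplan–Meier treatment; a competing-risks cumulative
incidence analysis is deliberately out of scope. At tied times events
precede censorings (standard product-limit convention). `filter_cases()`
excludes carriers of more than one pathogenic variant ("complex"
genotypes) and cases without a follow-up age, each with a recorded reason.

Estimation is by `survival::survfit`/`survdiff` behind the package's
interface; the test suite cross-checks them against independently coded
product-limit and O−E/V log-rank evaluations (agreement to 1e-12 for the
estimator). Pairwise log-rank comparisons are uncorrected by default —
mirroring how region-wise prognosis contrasts are typically reported — with
Bonferroni and Holm corrections available.

## Conformer-ensemble metrics

Superposition is Kabsch/SVD with a determinant guard against reflections;
the fitting method behind published RMSD curves is usually unstated, and
Kabsch is the field default. Backbone = {N, CA, C, O}. `rmsd_series()`
superposes each frame on a reference frame over the selection;
`rmsf_profile()` superposes frames onto an iterated mean structure (two
passes) and reports per-atom root-mean-square fluctuation. The rigid fit
removes six degrees of freedom and therefore slightly shrinks apparent
fluctuations — for ensembles already in a common frame `superpose = FALSE`
skips it, and the planted-amplitude tests use that mode while the
superposed mode is cross-checked against an independent fitting engine
(`bio3d::fit.xyz`).

SASA is Shrake–Rupley with a deterministic golden-spiral point lattice
(default 960 points/atom), probe radius 1.4 Å (water), and Bondi van der
Waals radii shipped as a plain-text table. A lattice point is buried when
strictly inside a neighbour's expanded sphere; coincident duplicate atoms
therefore each keep their full area (their points lie exactly *on* each
other's sphere), a documented convention for degenerate input. RMSD and
RMSF are rigid-motion invariant to better than 1e-8; SASA is exactly
invariant under translation, while under rotation the fixed lattice
resolves burial boundaries only to the point density, so rotational
agreement is at lattice resolution (≪ 1%), not machine precision.

No molecular dynamics is run here: published time-averaged RMSD/SASA values
from nanosecond-scale simulations require an MD engine and are not
reproducible at desk scale. The metrics are therefore validated by
properties — analytic sphere areas, high-resolution numeric oracles,
rigid-motion invariance, planted-amplitude recovery — rather than by
matching simulation figures.

## Synthetic generators: what they emulate, and what they do not

All three generators are deterministic given a seed and return
machine-readable ground truth alongside their output files.

* `make_complex()` plants contacts at exact distances between single-atom
  (Cα-only) residues on widely separated chains, so the planted pairs are
  provably the complete contact set. One atom per residue suffices because
  the contact rule is a minimum over atom pairs. Specs that cannot be
  realised without side-effect contacts (a residue moved twice, anchors
  closer than three positions on one chain) are rejected rather than
  silently repaired. Toy complexes have no realistic stereochemistry; they
  test the search, not biology.
* `simulate_orthologs()` evolves a root CDS along a **star phylogeny** —
  chosen over a realistic species tree because independent branches make ω
  recovery analytically transparent. Defaults: 26 taxa (the ortholog-set
  size typical for this protein family), 0.3 expected mutation attempts
  per nucleotide site per branch (enough divergence to accumulate
  informative synonymous counts while staying below Jukes–Cantor
  saturation), transition bias κ = 2. Nonsynonymous attempts are accepted
  with probability ω; stop codons are resampled, never emitted. The
  reference sequence is the unevolved root, so comparisons are
  root-to-taxon, one branch long.
* `simulate_cohort()` draws variant positions by region, phenotypes from
  region-dependent mixes, and cause-specific death times from exponential
  hazards with per-region multipliers, against uniform censoring at ages
  30–80. The default phenotype mixes and the arginine share (68.6% of TnT
  index cases) emulate the published cohort's composition; baseline
  hazards (SCD 0.004/yr, HF death/transplant 0.003/yr, stroke and
  procedural deaths 0.0005/yr each) give the event fractions by late
  middle age typical of severe cardiomyopathy cohorts. Default region
  multipliers are all 1 — a null cohort — so any planted effect is an
  explicit test condition. Exponential event times are a deliberate
  simplification: the Kaplan–Meier machinery is nonparametric, and
  exponential truth gives closed-form checks. No covariate confounding,
  family structure or ascertainment bias is modelled, so passing tests
  demonstrate statistical correctness of the machinery, not robustness to
  the heterogeneity of real literature-curated cohorts.

## Problem sizes and test design

The test suite validates each operation against an independent oracle —
brute-force double loops for contacts, hand product-limit and O−E/V
evaluations for survival, exhaustive enumeration for codon counts,
closed-form geometry and a 10⁵-point lattice for SASA — and then checks the
pipeline end to end at these sizes: 100 planted complexes (3 × 20
residues); 100 random cohorts for estimator agreement; 1000 two-arm null
cohorts (n = 100/arm) for log-rank calibration, with the rejection rate
required to fall in [0.035, 0.065] at α = 0.05; 200 cohorts of n = 300
with a hazard ratio of 3 planted in the high-risk stratum, requiring
detection in ≥ 80% (observed power ≈ 0.99); and 100 codon sites at 26 taxa
for ω recovery. These sizes give stable pass/fail behaviour under the
documented seeds while keeping the default test run to about a minute and
a half.

Two checks require data that cannot be redistributed with the package: the
curated literature case table (`published_case_table()`) and the canonical
adult cardiac TNNT2 CDS (`tnnt2_gene_model()`). The corresponding tests
state the expected published values (total and per-gene variant counts,
arginine fractions, phenotype proportions, arginine codon census) and fail
with instructions until the files are supplied.

## Known limitations

* Contact mapping reads PDB-format text only; mmCIF is out of scope, as is
  any automatic chain identification or density fitting.
* The counting ω estimator has no rate-matrix model and no tree: multiple
  hits are handled only through the Jukes–Cantor correction, and shared
  ancestry in real (non-star) phylogenies will correlate branch counts.
* Cause-specific survival treats competing deaths as censoring; cumulative
  incidence under competing risks is not estimated, and no Cox regression
  or hazard-ratio estimation is provided.
* Trajectory I/O covers multi-model PDB and a documented CSV; binary MD
  formats are not read.
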