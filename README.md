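# thinfilament

Integrative analysis of amino-acid variants in the cardiac thin filament:
from the geometry of the troponin complex, through evolutionary constraint
and codon-level mutability, to the clinical outcomes of variant carriers.

## Who this is for

Variants in the troponin subunits (TnC, TnI, TnT) cause inherited
cardiomyopathies — mostly hypertrophic (HCM), less often dilated (DCM),
restrictive (RCM) or left-ventricular non-compaction (LVNC) — with
strikingly uneven prognosis depending on *where* in the protein the variant
falls. This package provides the full analysis chain used to connect those
layers, for structural bioinformaticians and clinical genetics researchers:

1. **Contact mapping** — inter-chain residue contacts in troponin complex
   structures at a distance cutoff (default 4 Å, inclusive, heavy atoms),
   classified by calcium state by comparing a calcium-saturated and a
   calcium-free complex: a residue pair is `bound_only`, `free_only` or
   `common`. Author numbering is translated to canonical human numbering
   through alignment-based residue maps.
2. **Conservation and selection** — per-column Jensen–Shannon divergence
   conservation scores, and site-specific Ka/Ks (ω) from codon alignments
   built by back-translating a protein alignment onto coding sequences. ω is
   estimated with a Nei–Gojobori-style counting method: observed synonymous
   and nonsynonymous differences on minimal mutational paths, potential
   sites with S + N = 3 per codon, Jukes–Cantor correction, ω = Ka/Ks
   (ω < 1 purifying, ≈ 1 neutral, > 1 positive selection).
3. **Codon mutability** — census of the six arginine codons (CGU/CGT, CGC,
   CGA, CGG, AGA, AGG), CpG-dinucleotide flags per codon (methylated CpG
   cytosines deaminate to thymine at elevated rates, making these codons
   hotspots), per-site variant summaries and recurrence-based hotspot calls.
4. **Survival analysis** — cause-specific Kaplan–Meier curves with age from
   birth as the time scale, log-rank (Mantel–Cox) omnibus and pairwise
   tests, stratified by structural region. TnT regions: 1–89, 90–129,
   130–179, 200–288 (180–199 excluded); risk strata: high = {90–129,
   130–179}, low = {1–89, 200–288}.
5. **Conformer-ensemble metrics** — Kabsch superposition, backbone RMSD
   series, Cα RMSF, and Shrake–Rupley solvent-accessible surface area.
6. **Synthetic data** — generators for planted-contact complexes, ortholog
   sets evolved under site-specific ω on a star phylogeny, and clinical
   cohorts with region-dependent phenotypes and hazards, each paired with a
   machine-readable ground truth, so the whole pipeline runs and is tested
   without any downloads.

## Worked example

Simulate a cohort of 400 TnT variant carriers with a threefold
sudden-cardiac-death hazard planted in the high-risk regions, then run the
region-stratified survival analysis:

```r
library(thinfilament)

sim  <- simulate_cohort(n_cases = 400, seed = 42,
                        region_multipliers = c(`1-89` = 1, `90-129` = 3,
                                               `130-179` = 3, `200-288` = 1))
kept <- filter_cases(sim$cases)$kept   # drops complex genotypes etc.
rs   <- survival_by_region(kept, endpoint = "scd",
                           strata = tnt_risk_strata())
rs$omnibus
#> Log-rank (Mantel-Cox) test, endpoint: scd
#>   chi-square = 29.07 on 1 df, p = 6.975e-08
#> # A tibble: 2 × 4
#>   group     n observed expected
#>   <chr> <int>    <dbl>    <dbl>
#> 1 high    246       76     51.0
#> 2 low     127       14     39.0
```

The high-risk stratum shows 76 sudden cardiac deaths against 51 expected
under a common hazard — the planted excess — and the log-rank test rejects
decisively. `autoplot(rs)` draws the stratified step curves;
`variant_site_summary()` + `call_hotspots()` tabulate recurrent sites:

```r
sm <- variant_site_summary(kept, index_only = TRUE)
call_hotspots(sm, threshold = 5)
#> # A tibble: 6 × 10
#>   gene  position ref_aa n_index_cases   HCM   DCM   RCM  LVNC other threshold
#> 1 TNNT2       99 R                  5     4     0     1     0     0         5
#> 2 TNNT2      107 T                  5     3     0     2     0     0         5
#> ...
```

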