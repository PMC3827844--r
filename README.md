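# compactdm

Distilling multi-platform differential-expression evidence into **compact
disease models**: small, mechanism-centered gene lists tiered by the
consistency of their evidence, validated by expression-matched functional
enrichment and literature co-occurrence, and re-expanded into scored
interaction sub-networks.

The package is for analysts who hold two or more case/control expression
studies of the same disease (different platforms, tissue subsets or
cohorts), a gene-set collection, optionally an offline gene–literature
corpus and a global interaction network, and who want a short, prioritized
gene list rather than a thousand-gene t-test ranking.

## The method

**Primary Consistency Score (PCS).** Within one dataset, probes in the
upper 40% by mean intensity are tested with two-tailed unequal-variance
Welch t-tests in every supported case/control comparison — within each
mixed tissue subset, and across the full control-split × disease-split
cross product for cohort-split designs. The PCS of a probe is the mean of
−log10 p over those comparisons; the direction of change is the sign of
the mean log ratio of group-average intensities.

**Consistency tiers.** The top 10% of probes by PCS per platform are
flagged, and genes are tiered by concordant evidence: Tier 2 for two
same-platform probes or cross-platform agreement; Tier 1 for
cross-platform agreement with multi-probe support, three concordant
same-platform probes, or simultaneous Tier 2 + pathway co-membership;
Tier 3 for pathway co-membership alone; Tier 0 for Tier 1/2 genes that are
also top-ranked in an auxiliary multi-disease dataset. Discordant
directions disqualify the strong rules.

**Enrichment with an expression-matched background.** For a changed list
L against background T, each category scores
`ENR = (CG / L) / (TG / T)` with a one-sided Fisher p-value and a
randomization-cycle FDR (100 random size-L lists, per-term
`FDR = mean #(random p ≤ p) / #(observed p ≤ p)`). The background is first
trimmed to its top-expression prefix so its mean intensity matches the
changed list, removing the intensity bias of consistency selection.

**Semantic-tag validation.** Gene lists become Boolean OR queries against
an offline corpus; delimiters (`disease`, `cancer`,
`disease AND stress`, ...) restrict the hits, and the delimited/total hit
ratio is compared with a size-matched random control to give a fold
enrichment per tier.

**Sub-network scoring.** The tier list plus first-order neighbors is
induced from a global interactome, partitioned by greedy modularity with
single-node refinement, and each sub-network scored as −log10 of the
upper-tail hypergeometric probability of its focus-molecule count.

Two framing formulas quantify the payoff: recall across platform
combinations `REC = C(N, m) · P(m)`, and the probability that an n-step
mechanistic hypothesis from a list with true-positive fraction q is fully
correct, `PEC = q^n`.

## Worked example

```r
library(compactdm)

sim <- simulate_study(n_genes = 2000, seed = 11)      # 2 primary platforms + auxiliary
gs  <- simulate_gene_sets(sim$truth$genes, sim$truth$planted_genes,
                          n_terms = 120, seed = 12)
net <- simulate_network(sim$truth$genes,
                        planted_module = head(sim$truth$planted_genes, 20),
                        planted_density = 0.5, seed = 13)

result <- run_cdm(
  primary    = sim$datasets[c("AFFY", "ILMN")],
  annotation = sim$annotation,
  auxiliary  = sim$datasets$ILMN_AUX,
  gene_sets  = gs,
  network    = net,
  seed       = 14
)
result
#> <cdm_result>
#>   tiers: 10 tier0 / 40 tier1 / 2 tier2 / 148 tier3 / 35 unconfirmed genes
#>   enrichment: tier0 (1 terms), tier1 (3 terms), tier1_plus_2 (3 terms), tier1_plus_2_plus_3 (2 terms)
#>   sub-networks: 17, top score 6.9

glance(result$tiers)
#> # A tibble: 1 × 7
#>   n_genes n_tier0 n_tier1 n_tier2 n_tier3 n_unconfirmed frac_down_tier12
#>     <int>   <int>   <int>   <int>   <int>         <int>            <dbl>
#> 1     225      10      40       2     148            35            0.571

head(tidy(result$enrichment$tier1)[, c("term_id", "TG", "CG", "ENR", "p_value", "fdr")], 3)
#> # A tibble: 3 × 6
#>   term_id         TG    CG   ENR      p_value   fdr
#>   <chr>        <int> <int> <dbl>        <dbl> <dbl>
#> 1 PLANTED:0002    12     7 16.4  0.0000000292  0
#> 2 PLANTED:0001     8     4 14.1  0.0000868     0
#> 3 NULL:0010       18     4  6.25 0.00293       0.04
```

Reading the output: of 2,000 genes the pipeline promotes 40 to Tier 1
(cross-platform, multi-probe concordance) and 10 of those to Tier 0
(also top-ranked in the auxiliary multi-disease study). The enrichment
report recovers the two planted functional categories at the head of the
Tier 1 list with enrichment coefficients ~14–16 and FDR 0, and the top
sub-network concentrates 8 focus molecules for a non-randomness score of
6.9 (p ≈ 10⁻⁷). Each result is a tibble with `tidy()`/`glance()` methods
and an `autoplot()`; `run_cdm(..., out_dir = )` writes all stage outputs
as TSV/GraphML plus a checksummed run manifest, and `run_cdm_config()`
drives the same pipeline from a YAML/JSON file (a thin CLI wrapper is
installed under `inst/scripts/cdm`).

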