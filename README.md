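# SeedCoNet

Seeded brain-region co-expression networks for disease-gene prioritization.

## The problem

Established risk genes for a neurodegenerative disease such as Alzheimer
disease (AD) do not act uniformly across the brain: pathology is graded by
region, and so, plausibly, is the coordinated expression of the genes
involved. SeedCoNet asks two questions of a multi-donor, multi-region
expression dataset:

1. **Does an established ("seed") disease-gene set cluster in a
   co-expression network, and does that clustering vary by brain region?**
2. **Which other genes look like the seed set** — strongly co-expressed with
   it in the relevant regions *and* supported by GWAS association — and do
   their knockouts in a model organism produce disease-related phenotypes?

## The method

Expression is first collapsed from probes to genes and adjusted to the
region level with a per-gene mixed model, `y ~ region + (1 | brain)`, whose
region cell means (donor random intercept marginalized out) become the
gene × region matrix. A co-expression network over a stated region subset
(all of one structure, or the cerebral regions affected at an early or late
Braak stage) has edge weights `w(i,j) = |r_ij|`, the absolute Pearson
correlation across regions.

Seed-set clustering is scored with a leave-one-out rank statistic. For seed
*g* with seed set *S*, every gene's summed absolute correlation to
*S* \ {*g*} is computed; *g* is ranked within the pooled list and converted
to a percentile, `percentile = rank / (N + 1)`. Its **correlation rank**
is `CR = 1 − percentile` (high = tightly seed-co-expressed), and the
**median ranking by correlation (MRC)** — the median seed CR — summarizes
the whole set on a scale comparable across networks.

Candidate (non-seed) genes are prioritized by combining two one-tailed
Z-scores with an equal-weight Stouffer sum:

    Z_combined = (0.5 Z_gwas + 0.5 Z_network) / sqrt(0.5^2 + 0.5^2)

where `Z_network = qnorm(percentile, lower.tail = FALSE)` from the seeded
network ranking and `Z_gwas` comes from the gene's best-SNP GWAS p-value
after the hotspot/LD/gene-size correction
`p_gene = 1 − (1 − p_best)^((N+1)/2)` for a gene with `N` SNPs. Candidates
are filtered to genes whose model-organism knockout shows an AD-related
phenotype (defective memory DM, defective aging DA, oxidative stress OS,
premature aging PA), and ranked by one-tailed p with Benjamini–Hochberg FDR
over the filtered set.

A synthetic-data generator (`simulateStudy`) plants a structure-graded seed
co-expression module plus matched GWAS and phenotype signal, so the whole
chain is testable end to end without any external download. Curated
reference tables for a 52-gene AD seed set ship in `inst/extdata`.

## Worked example

```r
library(SeedCoNet)

sim <- simulateStudy(simConfig(nGenes = 300, rngSeed = 7))
re  <- fitRegionExpression(sim$expression)      # genes x regions, mixed model
lateNet <- buildNetwork(re, sim$truth$lateRegions)

mrc(seedCrLoo(lateNet, sim$truth$seedGenes))
#> [1] 0.982
cb <- regionLabels(re)[regionStructures(re) == "cerebellum"]
mrc(seedCrLoo(buildNetwork(re, cb), sim$truth$seedGenes))
#> [1] 0.56

res <- rankNovelGenes(lateNet, sim$truth$seedGenes, sim$gwas, sim$phenotypes)
head(as.data.frame(res), 5)
#>     gene phenotype zGwas zNetwork zCombined pOneTailed     qFdr
#> 1 sig009        PA  3.60    2.651      4.42   4.96e-06 0.000804
#> 2 sig010     DM,PA  3.16    2.407      3.93   4.17e-05 0.003377
#> 3 sig001        DM  3.51    1.749      3.72   9.88e-05 0.004704
#> 4 sig006     DA,PA  2.89    2.256      3.64   1.38e-04 0.004704
#> 5 sig002        DM  4.29    0.839      3.62   1.45e-04 0.004704
```

The generator planted its seed module most strongly in the late-stage
cerebral regions (default loading 0.60 versus 0.25 in the cerebellum), and
the MRC reads that out:
seed CRs cluster near 1 in the late-stage network but sit near the null
median 0.5 in the cerebellum. The ranked table recovers the planted signal
genes (`sig*`): both evidence channels are high, and the top candidate's
FDR q is computed over the phenotype-filtered set only.

On the shipped reference tables:

```r
mrc(radStructureRanks()$cerebrum)                 # 0.7485
stoufferCombine(3.16, 2.78)                       # 4.200214
bhFdr(combinedRankingTable()$p_unadjusted, m = 654)[1]  # 0.0087636
```

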