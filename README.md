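# hybridRI

Quantify stage-specific reproductive isolation (RI) between a pair of
plant species and classify the hybrids between them.

Hybrid-zone studies need two calculations done carefully and together.
First, each potential barrier — geographic separation, flowering-time
mismatch, pollinator assemblages and pollinator behavior, fruit and seed
production after heterospecific crosses — must be expressed on a common
0–1 scale and combined **in life-history order**, because a barrier can
only block gene flow that survived the barriers before it. Second,
morphologically intermediate individuals must be assigned to a genotype
class (pure parent, F1, F2, backcross) from diagnostic SNPs, since the
class spectrum of a hybrid zone (F1-dominated, backcross-dominated,
F2-dominated) is what reveals the zone's evolutionary trajectory.
`hybridRI` is aimed at field evolutionary biologists with exactly these
data: observation tables as CSV, genotypes as a VCF or dosage matrix.

## The statistics

Prezygotic barriers use the co-occurrence index, postzygotic barriers the
mating-success index:

    RI_pre  = 1 − S/(S+U)        S shared, U unshared (records, days, visits)
    RI_post = 1 − 2H/(H+C)       H heterospecific, C conspecific success

Pollinator foraging adds the ethological barrier
`1 − (cross bouts/total bouts) × (het transitions/total transitions)` and
Bateman's constancy index
`BI = (√(aa·bb) − √(ab·ba)) / (√(aa·bb) + √(ab·ba))`.

Ordered components v₁…vₖ combine by the sequential-contribution scheme:

    AC_n = v_n · Π_{i<n} (1 − v_i)      absolute contribution of stage n
    T    = Σ AC_n = 1 − Π (1 − v_i)     total RI
    RC_n = AC_n / T                      relative contribution

On the genetic side, loci fixed for alternative alleles between the
parental samples (Hudson F_ST = 1) form the diagnostic panel; each
individual then gets an exact posterior over the six canonical classes
from Mendelian genotype frequencies — P1 (1,0,0), P2 (0,0,1), F1 (0,1,0),
F2 (¼,½,¼), BC1 (½,½,0), BC2 (0,½,½) — with a symmetric genotyping-error
rate ε, plus a hybrid index and interclass heterozygosity (the F1-vs-F2
separator: expected 1.0 vs 0.5).

## Worked example

The package ships the published field summaries of an alpine *Salvia
flava* / *S. castanea* hybrid zone. Pushing the purple-flowered species'
four prezygotic components through the cascade:

```r
library(hybridRI)
fx <- salviaFixture()
pre <- fx$components[fx$components$stage_class == "prezygotic", ]
sequentialContributions(pre$castanea, pre$stage)
#> CascadeResult (allopatric), 4 stages
#>                   stage component     AC     RC
#>              Geographic    0.8800 0.8800 0.8802
#>               Phenology    0.2600 0.0312 0.0312
#>   Pollinator assemblage    0.0183 0.0016 0.0016
#>  Pollinator ethological    0.9973 0.0869 0.0870
#> Total RI: 0.9998
```

Geography alone removes 88% of potential gene flow; the near-perfect
ethological barrier (0.9973), acting last, can only contribute 0.0869
more because little gene flow survives to reach it — the signature
insight of the sequential decomposition. `riTable(fx$components,
speciesCols = c("flava", "castanea"))` renders the full two-species
report with sympatric columns (geography excluded) and separate
postzygotic totals.

Classification, on simulated genotypes with known truth:

```r
gt <- simulateGenotypes(c(P1 = 20, P2 = 20, F1 = 5, F2 = 15),
                        nLoci = 80, seed = 42)
panel <- selectDiagnosticLoci(gt, minParentalN = 10)
assignHybridClasses(gt, panel)
#> HybridClassification: 20 individuals, 47 diagnostic loci,  epsilon = 0.01
#>
#> F1 F2
#>  5 15
```

All 20 unknowns recover their true class (the panel is 47 of 80 planted
loci because 1% genotyping error in 40 parental reference genotypes
knocks a locus out of strict fixation — the intended, conservative
behavior). Per-individual posteriors, hybrid index and heterozygosity
come from `hybridCalls()`.

A thin command-line wrapper with `simulate`, `classify` and `ri-table`
subcommands is installed at `inst/scripts/ri-tool.R`.

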