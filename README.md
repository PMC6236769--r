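# AuxREfusion

Fuzzy Dempster–Shafer data fusion for predicting Auxin-response elements
(AuxREs) in plant promoter sequences.

AuxREs are short cis-regulatory motifs (TGTCTC-family core) through which
auxin-responsive transcription factors activate plant genes. Any single
signal — motif overrepresentation, promoter position, base composition — is
a weak predictor that drowns in false positives. This package fuses three
evidence sources with Dempster's rule of combination on the two-hypothesis
frame Θ = {H₁: AuxRE, H₂: not AuxRE}. Each source is a *learning graph*: a
2-D feature space partitioned into confidence regions whose graded
propositions (P1 total ignorance … P4 certainty) resolve to basic
probability assignments (m(H₁), m(H₂), m(H₁∪H₂)). Trapezoidal fuzzy
partitions replace the hard region boundaries, so a feature point receives
the membership-weighted mixture

    m(S) = Σᵢⱼ μᵢ(x) μⱼ(y) m_Rij(S),

and the three graph masses combine by the orthogonal sum

    (m_a ⊕ m_b)(A) = 1/(1−K) Σ_{B∩C=A} m_a(B) m_b(C),
    K = m_a(H₁)m_b(H₂) + m_a(H₂)m_b(H₁).

The per-window decision score is the fused belief in H₁ ("credibility"),
thresholded at 0.9 by default. The three graphs are: significance score ×
position from the ATG; occurrence × density (share of a word's matches that
fall in auxin-responsive promoters); and two linear-discriminant projections
of the Z-curve composition parameters and GC fraction.

The package ships the complete apparatus: the mass-function algebra, the
fuzzified region tables (YAML-configurable), a promoter scanner with
TSV/BED output, a synthetic 64-element training fixture and planted
reference promoter collection, and a spike-in gold-standard benchmark with
a sensitivity/PPV metric panel. See the vignette
(`vignettes/auxre-fusion-model.Rmd`) for the model, its design decisions and
its limits.

## Worked example

Combining two strong-preference propositions (the algebra is exact on the
printed table constants):

```r
library(AuxREfusion)
combineMasses(massFromProposition("P3", "H1"), massFromProposition("P3", "H1"))
#> CombinationResult  K=0.0000
#>   MassFunction  m(H1)=0.8911  m(H2)=0.0000  m(Theta)=0.1089
```

Running the spike-in benchmark with the packaged model: 100 random 1000-bp
sequences, each carrying one of the 14 AuxRE variants at a random position,
scanned against the planted reference collection (about 200,000 candidate
windows):

```r
model     <- defaultFusionModel()
reference <- makeReferenceCollection()
bm <- runBenchmark(model, seed = 1, reference = reference)

bm$result
#> ScanResult: 198533 candidates, 163 hits at threshold 0.90, 267 conflict rejects

subset(bm$sweep, threshold %in% c(0.5, 0.8, 0.9),
       c(threshold, tp, fp, fn, sn, ppv, yi))
#>   threshold tp  fp fn sn      ppv        yi
#> 5       0.5 99 196  1 99 33.55932 0.9890131
#> 8       0.8 99  75  1 99 56.89655 0.9896224
#> 9       0.9 72  40 28 72 64.28571 0.7197986

bm$bestThreshold
#> [1] 0.9

round(bm$comparison$auc, 4)
#> method1 method2  fusion
#>  0.9998  0.8955  0.9998
```

Reading the numbers: of the 100 spiked elements, 72 are recovered at the
0.9 cutoff (the misses sit within ~250 bp of the ATG, where the model's
training structure contains only non-AuxRE elements — its designed blind
spot); precision rises monotonically with the cutoff and peaks at 0.9; the
fused ranking dominates the single evidence sources. The 40 residual false
calls are dominated by *chance* occurrences of the variant words themselves
in random sequence, which are indistinguishable from spikes at the word
level. Individual hits carry the full evidence record:

```r
head(scanHits(bm$result)[, c("promoter_id", "start", "end", "seq",
                             "P", "Sc", "O", "D", "credibility")], 3)
#>   promoter_id start end      seq   P        Sc  O         D credibility
#> 1     gold002   273 281 TTGTCTCA 727 10.260015 16 0.5000000           1
#> 2     gold002   274 282 TGTCTCAC 726  5.240737  9 0.6666667           1
#> 3     gold003   733 741 ATGTCTCA 267 10.352844 16 0.5000000           1
```

Scanning your own promoters takes a FASTA of upstream regions (3' ends at
the ATG) plus a background collection:

```r
coll <- readPromoterCollection("promoters.fa", "responsive_ids.txt")
res  <- scanPromoters("my_promoters.fa", defaultFusionModel(), coll)
writeScanTSV(res, "hits.tsv"); writeScanBED(res, "hits.bed")
```

A thin command-line wrapper with `scan`, `benchmark`, `make-fixtures` and
`model-dump` subcommands is installed at `inst/scripts/auxrefusion`.

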