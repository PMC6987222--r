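# neatquant

Isoform-resolved quantification of the overlapping *NEAT1* lncRNA
transcripts, paraspeckle RNA-FISH scoring, ΔΔCq qPCR normalization, and the
cohort association statistics that tie them to clinicopathological
variables — with synthetic-data generators so the entire pipeline can be
exercised and validated at desk scale.

## The problem

The *NEAT1* locus on chr11 produces two isoforms: a short polyadenylated
transcript (*NEAT1_1*, ~3.7 kb) that completely overlaps the 5′ end of a
long non-polyadenylated transcript (*NEAT1_2*, the scaffold of nuclear
paraspeckles). Because the short isoform is a strict subsequence of the
long one, standard transcript quantification cannot separate them. For
anyone studying isoform-specific expression — e.g. the association of
*NEAT1_2* with HER2-positive, high-grade breast cancer — three measurement
problems recur:

1. **RNA-seq**: attribute paired-end fragments to a *common* region
   (chr11:65,422,798–65,426,532, 3,735 bp, covered by both isoforms) or the
   *NEAT1_2*-specific region (chr11:65,426,533–65,445,540, 19,008 bp,
   GRCh38). Fragments spanning the junction between the two regions are
   excluded from both counts. Expression is
   FPKM = RM<sub>g</sub>·10⁹ / (RM<sub>t</sub>·L), with RM<sub>g</sub> the
   fragments in the region, RM<sub>t</sub> the library's total mapped
   fragments, and L the region length. Samples with specific-region
   FPKM ≥ 1.0 carry real *NEAT1_2* signal, so only samples **below** that
   threshold can have their common-region FPKM read as *NEAT1_1*.
2. **RNA-FISH**: quantify punctate nuclear *NEAT1_2* foci (paraspeckles) in
   two-channel confocal z-stacks — maximum-intensity projection, automatic
   (Otsu) DAPI nucleus segmentation, per-nucleus mean signal intensity and
   foci detection — and roll nuclei up into an ordinal 0–3 sample score.
   Samples scoring ≥ 1 are "*NEAT1_2*-positive".
3. **qPCR**: ΔΔCq fold changes normalized to the geometric mean of a
   *GAPDH*/*B2M*/*RPLP0* reference panel against a calibrator sample
   (fold = 2^(−ΔΔCq)).

Score-by-variable cross-tabulations are tested with Pearson chi-square;
group comparisons with Mann-Whitney / Kruskal-Wallis / pairwise Wilcoxon;
correlations with Spearman's rank.

## Worked example

```r
library(neatquant)

model <- neat1RegionModel()
model
#> RegionModel on chr11
#>   common  : 65422798-65426532 (3735 bp)
#>   specific: 65426533-65445540 (19008 bp)

# a synthetic library: mostly short isoform, a little NEAT1_2, background
sim <- simulateLocusFragments(
    ReadSimParams(nShort = 4000, nLong = 150, nBackground = 6000, seed = 42),
    model)
quantifySample("TCGA-like-01", sim$fragments, model)
#>     sample_id rm_common rm_specific n_spanning_excluded rm_total fpkm_common
#>  TCGA-like-01      4019         129                   2    10150    106013.5
#>  fpkm_specific neat1_1_eligible neat1_1_fpkm
#>       668.6321            FALSE           NA
```

4,019 fragments landed wholly in the common region, 129 wholly in the
specific region and 2 spanned the junction (excluded). At this depth the
specific-region FPKM (668.6) is far above 1.0, so the sample is **not**
eligible for *NEAT1_1* analysis — its common-region signal is contaminated
by the long isoform, exactly what the filter is for.

The packaged 74-patient screening-cohort cross-tabulations reproduce the
published association tests:

```r
summarizeCohort(screeningCohort(), variables = c("grade", "her2"))
#> == grade (n = 74, p = 0.027 *)
#>    0 1  2 3
#> 1 10 5  3 0
#> 2  8 9  5 1
#> 3  7 6 15 5
#> == her2 (n = 74, p = 0.042 *)
#>           0  1  2 3
#> negative 22 13 15 2
#> positive  3  7  8 4

positivityRate(screeningCohort()$score)   # 49/74 = 66% NEAT1_2-positive
```

The ordinal score associates with tumor grade (p = 0.027) and HER2 status
(p = 0.042): *NEAT1_2*/paraspeckle expression concentrates in high-grade
and HER2-positive disease.

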