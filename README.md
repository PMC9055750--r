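# embryophase

Proband-free preimplantation genetic testing (PGT-M) for recessive
thalassemia, using **affected embryos of the same IVF cohort as the
haplotype phasing reference**.

Linkage-based PGT-M normally needs a proband or pedigree to establish
which parental allele at each linked SNP rides the disease chromosome.
Couples who first learn they are carriers during an IVF work-up — common
for α-thalassemia, where affected pregnancies rarely reach term — have
neither. This package implements the alternative: embryos shown by
direct mutation detection to be homozygous-affected are themselves the
phasing reference, so every sibling embryo can be genotyped by SNP
linkage with the direct mutation call as cross-validation. It is aimed
at scientists developing or evaluating embryo-based PGT-M workflows; a
seeded synthetic-cohort simulator stands in for patient data, which the
underlying study could not deposit.

## Method

For two carrier parents and a disease locus (the SEA α-globin deletion,
hg19 chr16:215,400–234,700, or HBB CD41–42 −AAAG, chr11:5,246,696–5,248,301):

1. **Direct mutation call per embryo.** Large deletions are genotyped
   from the in-region/flank read-depth ratio (homozygous deletions fail
   to amplify); small indels from the mutant-allele read fraction.
   Embryos with 2 disease alleles form the affected reference set.
2. **Informative SNPs.** A marker heterozygous in one parent and
   homozygous in the other (within 1–2 Mb windows flanking the locus)
   identifies the transmitted allele of the heterozygous parent once the
   obligate allele of the homozygous parent is subtracted.
3. **Phasing.** At each informative site, subtracting the obligate
   allele from an affected embryo's genotype leaves the disease-linked
   allele: that allele defines haplotype M0 (maternal) or F0 (paternal);
   the complementary allele is M1/F1. Suspected allele-dropout (ADO)
   observations are withheld; disagreement between affected embryos
   marks a site as conflicted and removes it.
4. **Linkage genotyping.** Every resolved site votes H0/H1 for each
   embryo and side; an assignment needs ≥2 concordant upstream and ≥2
   downstream votes and a 0.8 winner fraction, with positional
   vote-changepoints flagged as suspected recombination. Two disease
   haplotypes → affected, one → carrier, none → noncarrier, always
   cross-checked against the direct mutation call.
5. **Aneuploidy screen and transfer decision.** Binned read counts
   (~1.5 M fragments, 1 Mb bins) are normalised against a reference
   profile; per-chromosome ratio bands call gains/losses/mosaics.
   Transferable = unaffected **and** euploid.

The WGA error model behind the simulator uses the study's measured
rates: 94.71% site amplification, 4.26% allele dropout per heterozygous
site, depth >30× (default 100×).

## Worked example

```r
library(embryophase)

cfg <- sim_config("alpha_SEA", n_families = 1, embryos_per_family = 8,
                  require_affected = TRUE, simulate_cnv = TRUE,
                  n_fragments = 2e5, seed = 7)
fam <- simulate_cohort(cfg)[[1]]
res <- genotype_family(fam)
res$phase
#> <pgt_phase> 143 sites: 131 resolved, 12 unresolved (ADO), 0 conflict; 1 affected embryo(s) used
#>           location
#> side       upstream downstream
#>   maternal       31         33
#>   paternal       36         31
res$calls[, c("embryo", "maternal_assignment", "paternal_assignment",
              "direct_genotype", "final_status")]
#>   embryo maternal_assignment paternal_assignment direct_genotype final_status
#> 1     E1                  H1                  H1               0   noncarrier
#> 2     E2                  H0                  H1               1      carrier
#> ...
#> 7     E7                  H0                  H0               2     affected
#> 8     E8                  H1                  H0               1      carrier
```

Of the 270-SNP panel, 143 sites were informative and 131 could be
phased from the single affected embryo (12 lost to suspected ADO). Each
embryo's H0/H1 columns say which maternal/paternal haplotype it
inherited; `direct_genotype` is the independent depth-based mutation
call (0/1/2 disease alleles), which agrees with the linkage result for
every embryo. Adding the aneuploidy screen:

```r
cnv <- do.call(rbind, lapply(fam$embryos, function(e) {
  prof <- fam$cnv[fam$cnv$sample == e,
                  c("chrom", "start", "end", "length", "count")]
  data.frame(embryo = e, call = cnv_screen(prof,
             reference_profile(1e6, 2e5))$call)
}))
decide_transferable(res$calls, cnv)
#>   embryo final_status cnv_call transferable
#> 1     E1   noncarrier  euploid         TRUE
#> 3     E3   noncarrier     loss        FALSE
#> 7     E7     affected  euploid        FALSE
#> ...
```

Six of eight embryos are transferable; the affected embryo and a
monosomic embryo are not. The packaged per-family outcome table of the
36-couple study cohort reproduces the published arithmetic:

```r
summarize_cohort(family_outcomes())
#> <pgt_cohort_summary> 36 families
#>   biopsied 217, unaffected 160 (73.7%), transferable 112 (70.0% of unaffected)
#>   per couple: 6.0 biopsied, 3.1 transferable
#>   per FET cycle: clinical pregnancy 60.4%, live birth 43.4%
p_none_affected(8)
#> [1] 0.1001129
```

`p_none_affected(n) = (3/4)^n` is the counselling probability that a
cohort of `n` embryos contains no affected embryo, i.e. no phasing
reference — about 10% even with 8 embryos.

A YAML-configurable end-to-end runner (`run_pipeline()`) executes
simulate → phase → genotype → cnv → report over on-disk artifacts
(parental VCF, observation TSVs, haplotype tables, JSON report), each
stage re-runnable in isolation.

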