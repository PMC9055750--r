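---
title: "Affected-embryo haplotype phasing for thalassemia PGT-M: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Affected-embryo haplotype phasing for thalassemia PGT-M: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryophase)
```

## The problem

Couples in which both partners carry a recessive thalassemia allele can
avoid an affected pregnancy through preimplantation genetic testing for
monogenic disease (PGT-M). Because trophectoderm biopsies yield only a
few cells, genotyping runs on whole-genome-amplified (WGA) DNA, and WGA
suffers allele dropout (ADO): a heterozygous site randomly loses one
allele and looks homozygous. Direct mutation detection alone therefore
misdiagnoses; clinical practice adds linkage analysis over SNPs flanking
the disease gene. Linkage, however, requires knowing the parental
*phase* — which allele at each SNP lies on the disease chromosome — and
phase is classically obtained from a proband or pedigree. Many carrier
couples, especially for α-thalassemia (homozygous SEA-deletion fetuses
die perinatally), have neither.

This package implements the proband-free alternative: in a cohort of
embryos from two carriers, each embryo is independently affected with
probability 1/4, so a reasonable-sized cohort usually contains
homozygous-affected embryos. Those embryos, identified by direct
mutation detection, carry both parental disease haplotypes and can
serve as the phasing reference for their siblings.

## Direct mutation detection

Two mutation classes are supported, matching the two thalassemia loci:

* **Large deletion** (SEA α-globin deletion, hg19
  chr16:215,400–234,700). Primers inside a homozygously deleted region
  find no template, so the mean read depth over in-region sites
  collapses relative to flanking baseline sites. `call_deletion_state()`
  bands the in-region/flank depth ratio: below 0.10 → two disease
  alleles; 0.30–0.70 → one; above 0.80 → none; anything between bands is
  `ambiguous`, and flank depth under 30× downgrades confidence to
  `low_depth`. The published description states only that affected
  embryos show "very low read counts", so the band edges are this
  package's reconstruction — chosen to separate the three copy states
  (expected ratios ≈ 0.02, 0.5, 1.0 at ≥30× with Poisson noise) with
  wide margins — and all are configurable arguments.
* **Small indel** (HBB CD41–42 −AAAG). The deletion allele is visible
  in reads, so `call_indel_genotype()` bands the mutant-allele read
  fraction: ≥0.90 → homozygous, 0.25–0.75 → heterozygous, ≤0.10 →
  wild-type, with a 30× minimum total depth.

An ambiguous direct call is deliberately not fatal: the linkage result
can stand on its own, flagged `ADO_at_mutation_site`. A *passing* direct
call that contradicts a conclusive linkage result, however, makes the
embryo `inconclusive` (`discordant_direct_vs_linkage`) — diagnosis
prefers withholding a result to guessing between contradictory assays.

## Informative SNPs and phasing

A SNP is informative when one parent is heterozygous (alleles
$a_1/a_2$) and the other homozygous ($b/b$): the homozygous parent
always transmits $b$, so subtracting one $b$ from an embryo genotype
reveals the heterozygous parent's transmitted allele.
`select_informative()` applies exactly this rule inside the configured
windows (α preset: 1 Mb upstream / 2 Mb downstream of the deletion; β
preset: 1 Mb each side) and tags each marker with its side and
location. "Upstream/downstream" follow forward-strand hg19 coordinates
relative to the region boundaries.

`build_haplotypes()` performs the subtraction at every informative site
using the affected embryos: the remaining allele of the heterozygous
parent defines haplotype index 0 (M0/F0, disease-associated by
construction); the complementary allele is M1/F1. Site status becomes:

* `resolved` — every informative affected-embryo observation agrees;
* `unresolved_ADO` — no observation can disambiguate (site failed to
  amplify, or only the obligate allele was seen under suspected
  dropout, see below);
* `conflict` — affected embryos disagree, or an observation is
  Mendelian-impossible. Conflicted sites are excluded from all
  downstream voting. Strict unanimity (rather than majority) is the
  default because a diagnostic workflow should drop a marker rather
  than trust a noisy one.

### Dropout detection by depth

With biallelic markers the homozygous parent's allele is always one of
the heterozygous pair, so an embryo observed $b/b$ is genuinely either
homozygous (transmitted allele $= b$) or a dropout casualty
(transmitted allele hidden). Genotype identity alone cannot separate
the two, yet the observation is not worthless: under the package's
depth model a site that lost one allele retains roughly *half* the
expected depth on the survivor, whereas a true homozygote keeps full
depth. `genotype_calls()` therefore flags a homozygous call as
`dropout_suspected` when its total depth falls below `hom_depth_frac`
(default 0.8) of the sample's median panel depth; flagged observations
of the obligate allele are withheld from phasing and abstain from
voting. The 0.8 default sits between the one-copy (≈0.5) and two-copy
(≈1.0) depth regimes and deliberately leans toward flagging: a falsely
flagged marker merely abstains, while a missed dropout could mis-phase
a site. At 100× this misses a dropout with probability on the order of
10⁻⁴ and falsely flags a true homozygote in ≈2% of calls — an
acceptable trade for a workflow holding hundreds of markers.

Phasing requires at least 2 resolved markers upstream *and* downstream
on each parental side (the flanking-marker rule); a family failing any
cell aborts with the deficient cell named. A minimum cohort size of 3
biopsied embryos (configurable) mirrors the clinical practice of
deferring sequencing for two-blastocyst cycles, although a single
affected embryo is mathematically sufficient for phasing itself.

### Verification oracle

`phase_oracle()` is an independent test-only check: given the
simulator's true parental diplotypes, it enumerates both assignments of
each parent's haplotypes to disease/normal status, scores every
assignment by how many affected-embryo observations are consistent with
it (observed alleles a subset of the predicted genotype, allowing
dropout), and returns the winner, declaring ties ambiguous. The test
suite verifies site-level agreement with `build_haplotypes()` across
hundreds of seeded families. The comparison is run with recombination
disabled: a crossover inside an affected embryo makes the global 2×2
assignment and the per-site subtraction answer different — correct —
questions, so their equality is only defined in the crossover-free
setting.

## Linkage genotyping of sibling embryos

`assign_side()` lets every resolved site vote: the embryo's transmitted
allele (after subtracting the obligate allele, with the same dropout
handling) matches M0/F0 → vote H0, M1/F1 → vote H1; undecidable
observations abstain. An assignment requires

* ≥2 concordant votes upstream and ≥2 downstream for the winner
  (the published flanking-marker minimum), and
* a winner fraction ≥0.8 of non-abstaining votes, so that a single
  corrupted vote cannot flip an assignment backed by many markers
  (this fraction is a package design choice, not a published value).

A single positional changepoint — one contiguous H0 block followed by
one H1 block, both of length ≥2 when ordered by coordinate — is the
signature of a crossover and sets `recombination_suspected`. If the
changepoint falls inside one flank, the gene-proximal run of that flank
plus the whole opposite flank is re-scored under the same minima
(markers beyond the crossover no longer reflect the haplotype at the
gene); if it straddles the gene, the side is `inconclusive`. The
published workflow acknowledges recombination risk without giving a
procedure; this rule is the package's own, and single stray votes
(run length 1) are deliberately left to the winner-fraction rule rather
than interpreted as crossovers.

`classify_embryo()` maps the two sides to the final status (H0+H0
affected, one H0 carrier, H1+H1 noncarrier; "carrier" is reported
without sidedness, as clinical tables do, though the maternal/paternal
assignments are retained) and cross-checks the direct call as described
above. Raising the flank minimum can only shrink the conclusive set
(monotonicity), and voting is invariant to site and embryo order; both
are property-tested.

## WGA error model and estimators

`apply_wga()` models the two error processes measured in the study:

* a site fails to amplify entirely with probability $1 - 0.9471$;
* an amplified heterozygous site loses one allele (chosen at random)
  with probability $0.0426$.

`simulate_depths()` then gives each surviving haplotype copy
Poisson(`mean_depth`/2) reads — so heterozygotes split ~`mean_depth`
evenly, homozygotes draw Poisson(`mean_depth`), and dropout survivors
sit near half depth, which is what makes depth-based dropout flagging
possible. Inside a homozygous deletion the depth is
Poisson(0.02 × `mean_depth`): WGA background is near-zero but not zero
in practice. The defaults (94.71%, 4.26%, 100×, panel designed for
>30×) are the study's stated conditions and are estimator-recoverable:
`estimate_wga_metrics()` computes the amplification rate as amplified
site-calls over attempted, and the ADO rate as single-allele
observations over amplified *obligate-heterozygous* sites (both parents
homozygous for different alleles, forcing a heterozygous embryo — the
only sites where dropout is directly observable without phase).

## Synthetic cohort generator

`simulate_cohort()` is first-class, tested code, not a fixture. Per
family it draws:

* SNP positions uniformly within the configured windows on the hg19
  locus coordinates; panel sizes default to the α preset 138 upstream /
  132 downstream. For β the published marker counts conflict (85 within
  1 Mb in the methods; 95 within 2 Mb in the worked example); the
  default follows the methods (43/42, 1 Mb), and both variants are
  reachable through configuration.
* Parental haplotypes at population allele frequency 0.5 (so roughly
  half the panel is informative; configurable). Both parents are
  carriers with the disease allele phase-linked to haplotype 0.
* Per-embryo transmissions as a Poisson crossover process along the
  marker coordinates at 10⁻⁸ per bp (≈1 cM/Mb; the study never states
  a rate, only that recombination can affect accuracy). The haplotype
  label at the locus determines the transmitted disease allele, making
  the truth record Mendelian by construction.
* Karyotypes: full aneuploidy with probability 0.2 and mosaicism with
  probability 0.106, the latter matching the study's reported 10.6%
  blastocyst mosaicism; together they leave ≈69% euploid, matching the
  reported 70% euploidy among unaffected embryos. Mosaic fractions are
  uniform on 0.3–0.7. (The generator exposes `mosaic_rate` in addition
  to `aneuploidy_rate` because a single rate cannot reproduce both
  reported figures.)
* Observations through `apply_wga()` + `simulate_depths()`, a mutation
  depth profile (20 in-region and 16 flank baseline sites for the
  deletion; allele counts at the variant for the indel), and
  multinomial binned read counts (~1.5 M fragments, 1 Mb bins over the
  22 hg19 autosomes) for the aneuploidy screen.

Two rejection-sampling switches support study-like cohorts:
`require_affected` redraws transmissions until ≥1 affected embryo
exists (the clinical precondition — without it the cycle cannot be
analysed, which is why `p_none_affected()` matters for counselling),
and `min_informative_per_cell` redraws parental genotypes until each
side × flank cell holds a minimum number of informative markers
(emulating panel design). A single session RNG seeded from
`config$seed` makes cohorts byte-reproducible.

What the generator does **not** emulate: read-level artifacts
(sequencing error, GC and mappability bias, primer competition),
site-to-site or embryo-to-embryo variability in ADO and amplification
(the study reports only cohort-level rates, so the defaults are flat),
segmental aneuploidy, and contamination. Passing tests therefore
demonstrate correctness of the inference logic under the stated error
model, not robustness to every artifact of real MDA sequencing data.

## Aneuploidy screening

The study delegates copy-number calling to a prior publication and a
cloud service, so `cnv_screen()` is a transparent reconstruction:
1 Mb bins, ratios of count shares against a reference profile rescaled
to genome-median 1 (scale-invariant), per-chromosome median ratio, and
banded calls — euploid [0.9, 1.1], mosaic gain (1.15, 1.35], full gain
>1.35, losses mirrored, gap zones assigned to the nearest band and
flagged borderline. The mosaic fraction estimate is $2\,|r-1|$ clipped
to [0, 1]. The reference defaults to the deterministic expected euploid
profile (length-proportional); a measured reference table can be
substituted. The bands follow common PGT-A practice; the study's
clinical thresholds are unpublished. GC correction is omitted because
the simulator generates no GC bias; the reference-profile argument is
the natural hook for adding it. At 1.5 M fragments the per-chromosome
median ratio has noise well under 1%, so full trisomies (ratio 1.5) and
the euploid band are separated by dozens of standard errors — the
≥99%/≤1% detection/false-positive properties in the test suite follow
directly.

## Cohort reporting

`decide_transferable()` encodes the transfer rule: unaffected (carrier
or noncarrier) **and** euploid; mosaic embryos are never transferable.
`summarize_cohort()` aggregates the per-family outcome table (the
packaged fixture transcribes the study's per-family table; totals
verified against every printed cohort figure) and computes each rate
from its summed numerator and denominator. Where a printed rate
disagrees with its own printed fraction (the study prints a 60.1%
clinical-pregnancy rate beside the fraction 32/53 = 60.4%), the package
reports the value computed from the fraction rather than silently
matching the printed percentage. Live-birth rate uses babies over FET
cycles (23/53), reproducing the published 43.4% — one twin pregnancy
makes babies exceed cycles. The fixture stores live-birth cycles and
babies as separate columns for exactly this reason, and stores
miscarriages implicitly (clinical pregnancies without live birth),
since the study counts them per cycle.

## Numerical and degenerate-input choices

* Genotype calls need ≥10 total reads; an allele needs ≥2 reads and
  ≥15% of the site's reads. Thresholds are arguments everywhere.
* Degenerate WGA rates (0 and 1) are permitted and exercised in tests;
  an estimator facing zero amplified obligate-heterozygous sites errors
  rather than returning NaN.
* Zero-denominator cohort rates are reported as `NA` and named in an
  `undefined` field, never propagated as NaN.
* Ratio band gaps resolve to the nearest band *with a borderline flag*
  rather than erroring, because a clinical report must say something
  about every chromosome.
* All tie-breaks are deterministic; re-running any stage with the same
  seed and inputs is byte-identical, which the pipeline tests assert.

## Problem sizes used in the test suite

The packaged tests run the full workflow at study scale where it
matters — a 36-family cohort (216 embryos, 270-SNP panels) for
end-to-end conclusiveness, 60,000 sites for error-rate recovery, 500
seeded families for oracle agreement, and 1,000 profiles per arm for
CNV detection — and smaller panels (40 + 40 SNPs, 6-embryo families)
for the per-module property tests, which keeps the whole suite around a
minute on one CPU without changing any scientific conclusion.

## Known limitations

* Phase can only be established when the cohort contains an affected
  embryo; `p_none_affected()` quantifies that risk ((3/4)^8 ≈ 10% even
  with 8 embryos) but the package cannot remove it.
* Consanguineous couples may yield too few informative SNPs; the
  flanking-marker minima then abort phasing by design.
* Depth-based dropout flagging assumes roughly uniform amplification
  across the panel; in real MDA data with heavy-tailed depth the
  `hom_depth_frac` threshold would need recalibration, or flagged
  status taken from an orthogonal source.
* The CNV module targets whole-chromosome and mosaic whole-chromosome
  events only; segmental events and the study's actual cloud pipeline
  are out of scope.
* Double crossovers between adjacent markers, and crossover plus ADO at
  the same site, can evade the changepoint heuristic; with hundreds of
  markers over ≤3 Mb both are vanishingly rare but not impossible.
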