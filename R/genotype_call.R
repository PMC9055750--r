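#' Call diploid genotypes from allele-specific read depths
#'
#' Converts a long allele-depth table into per-sample, per-site genotype
#' calls. An allele is observed when it carries at least
#' `min_allele_frac` of the site's reads and at least 2 reads. Sites
#' below `min_site_depth` total reads are no-calls. A homozygous call
#' whose total depth falls below `hom_depth_frac` times the sample's
#' median panel depth is flagged `dropout_suspected`: under the WGA depth
#' model a site that lost one allele retains roughly half depth on the
#' survivor, so low-depth homozygous observations are the typical
#' fingerprint of allele dropout and are withheld from phasing and
#' voting when the surviving allele is the uninformative obligate one.
#'
#' @param obs Long observation table: `chrom`, `pos`, `ref`, `alt`,
#'   `sample`, `ref_depth`, `alt_depth`.
#' @param min_site_depth Minimum total reads for a call (default 10).
#' @param min_allele_frac Minimum read fraction to observe an allele.
#' @param hom_depth_frac Fraction of the sample median depth below which
#'   a homozygous call is flagged as suspected dropout (default 0.8:
#'   one-copy sites concentrate near 0.5 of expected depth, two-copy
#'   sites near 1.0, and flagging generously favours withholding a
#'   marker over trusting one).
#' @return Data frame with one row per input row: the identifying
#'   columns plus `total`, `called`, `allele1`, `allele2` (sorted; equal
#'   for homozygous calls; `NA` when not called), `n_alleles`, and
#'   `dropout_suspected`.
#' @export
genotype_calls <- function(obs, min_site_depth = 10, min_allele_frac = 0.15,
                           hom_depth_frac = 0.8) {
  total <- obs$ref_depth + obs$alt_depth
  med <- stats::ave(total, obs$sample, FUN = function(x) {
    x <- x[x >= min_site_depth]
    if (length(x)) stats::median(x) else NA_real_
  })
  called <- total >= min_site_depth
  ref_in <- called & obs$ref_depth >= pmax(2, min_allele_frac * total)
  alt_in <- called & obs$alt_depth >= pmax(2, min_allele_frac * total)
  called <- called & (ref_in | alt_in)
  n_alleles <- ifelse(called, ref_in + alt_in, NA_integer_)
  allele1 <- ifelse(!called, NA_character_,
                    ifelse(ref_in, obs$ref, obs$alt))
  allele2 <- ifelse(!called, NA_character_,
                    ifelse(alt_in, obs$alt, obs$ref))
  lo <- pmin(allele1, allele2)
  hi <- pmax(allele1, allele2)
  dropout <- called & n_alleles == 1L & !is.na(med) &
    total < hom_depth_frac * med
  out <- obs[, c("chrom", "pos", "ref", "alt", "sample",
                 "ref_depth", "alt_depth")]
  out$total <- total
  out$called <- called
  out$allele1 <- lo
  out$allele2 <- hi
  out$n_alleles <- n_alleles
  out$dropout_suspected <- dropout
  out
}

# Deduce which allele the heterozygous parent transmitted, given a
# genotype call at an informative site. Returns the allele, NA when the
# observation cannot disambiguate (no-call, or a suspected-dropout
# observation of the obligate allele alone), or "conflict" when the
# observation is Mendelian-impossible for the site.
#
# het_a1/het_a2: the heterozygous parent's alleles; hom: the obligate
# allele contributed by the homozygous parent. All arguments vectorised.
transmitted_allele <- function(het_a1, het_a2, hom,
                               called, allele1, allele2, dropout) {
  two <- called & allele1 != allele2
  one <- called & allele1 == allele2
  m <- rep(NA_character_, length(het_a1))
  # two distinct alleles: subtract the obligate one
  m[two] <- ifelse(allele1[two] == hom[two], allele2[two],
                   ifelse(allele2[two] == hom[two], allele1[two],
                          "conflict"))
  # single allele x: if x differs from the obligate allele the obligate
  # copy dropped and x is the transmitted allele; if x equals the
  # obligate allele the homozygous reading is taken at face value unless
  # depth marks it as a suspected dropout
  x <- allele1[one]
  m[one] <- ifelse(x != hom[one], x,
                   ifelse(dropout[one], NA_character_,
                          ifelse(hom[one] == het_a1[one] |
                                   hom[one] == het_a2[one],
                                 hom[one], NA_character_)))
  bad <- !is.na(m) & m != "conflict" & m != het_a1 & m != het_a2
  m[bad] <- "conflict"
  m
}
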