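# Worked-example fixtures built in code: clean observations (no WGA
# noise, depth 100x) reproducing the published alpha and beta example
# families, plus a generic builder.

# sites: data.frame(pos, mother, father, side, hap0) where hap0 is the
# allele the heterozygous parent transmits on the disease haplotype.
# mat_h0 / pat_h0: embryo labels inheriting the disease haplotype on
# that side. Depths: 50 per haplotype copy.
fixture_family <- function(disease, locus, sites, embryos, mat_h0, pat_h0,
                           window_upstream_bp = 1e6,
                           window_downstream_bp = 2e6) {
  gt_alleles <- function(gt) strsplit(gt, "/", fixed = TRUE)[[1]]
  sites$ref <- NA_character_; sites$alt <- NA_character_
  for (i in seq_len(nrow(sites))) {
    al <- sort(unique(c(gt_alleles(sites$mother[i]),
                        gt_alleles(sites$father[i]))))
    stopifnot(length(al) == 2)
    sites$ref[i] <- al[1]; sites$alt[i] <- al[2]
  }
  parents <- data.frame(chrom = locus$chrom, pos = sites$pos,
                        ref = sites$ref, alt = sites$alt,
                        mother = sites$mother, father = sites$father,
                        stringsAsFactors = FALSE)

  obs <- do.call(rbind, lapply(embryos, function(e) {
    do.call(rbind, lapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      het <- gt_alleles(if (s$side == "maternal") s$mother else s$father)
      hom <- gt_alleles(if (s$side == "maternal") s$father else s$mother)[1]
      h0 <- e %in% (if (s$side == "maternal") mat_h0 else pat_h0)
      trans <- if (h0) s$hap0 else setdiff(het, s$hap0)
      alleles <- c(trans, hom)
      data.frame(chrom = locus$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                 sample = e,
                 ref_depth = 50L * sum(alleles == s$ref),
                 alt_depth = 50L * sum(alleles == s$alt),
                 stringsAsFactors = FALSE)
    }))
  }))

  genotype <- vapply(embryos, function(e)
    (e %in% mat_h0) + (e %in% pat_h0), 0L)
  names(genotype) <- embryos

  mut <- do.call(rbind, lapply(embryos, function(e) {
    g <- genotype[[e]]
    if (locus$kind == "large_deletion") {
      region_pos <- round(seq(locus$start + 100, locus$end - 100,
                              length.out = 10))
      flank_pos <- c(round(seq(locus$flank_left[1], locus$flank_left[2],
                               length.out = 6)),
                     round(seq(locus$flank_right[1], locus$flank_right[2],
                               length.out = 6)))
      data.frame(sample = e, chrom = locus$chrom,
                 pos = c(region_pos, flank_pos),
                 location = c(rep("region", 10), rep("flank", 12)),
                 ref_depth = c(rep(c(100L, 50L, 2L)[g + 1], 10),
                               rep(100L, 12)),
                 alt_depth = 0L, stringsAsFactors = FALSE)
    } else {
      flank_pos <- round(seq(locus$flank_left[1], locus$flank_left[2],
                             length.out = 8))
      data.frame(sample = e, chrom = locus$chrom,
                 pos = c(locus$mutation_pos, flank_pos),
                 location = c("region", rep("flank", 8)),
                 ref_depth = c(c(60L, 30L, 0L)[g + 1], rep(100L, 8)),
                 alt_depth = c(c(0L, 28L, 60L)[g + 1], rep(0L, 8)),
                 stringsAsFactors = FALSE)
    }
  }))

  list(family_id = "worked", disease = disease, locus = locus,
       config = list(window_upstream_bp = window_upstream_bp,
                     window_downstream_bp = window_downstream_bp),
       embryos = embryos, parents = parents, snp_obs = obs,
       mutation_obs = mut, truth_genotype = genotype)
}

# The alpha-thalassemia worked example: nine embryos, SEA deletion,
# affected embryos E5 and E7 define the phase; maternal-informative SNP
# at 119,006 (mother A/C, father A/A, disease allele A) and
# paternal-informative SNP at 207,611 (mother C/C, father C/T, disease
# allele C).
worked_alpha_family <- function() {
  locus <- locus_sea_hba()
  sites <- data.frame(
    pos    = c(119006L, 150000L, 300000L, 400000L,
               207611L, 140000L, 320000L, 420000L),
    mother = c("A/C", "G/T", "A/G", "C/T", "C/C", "G/G", "T/T", "A/A"),
    father = c("A/A", "G/G", "A/A", "C/C", "C/T", "A/G", "C/T", "A/G"),
    side   = rep(c("maternal", "paternal"), each = 4),
    hap0   = c("A", "T", "G", "T", "C", "A", "C", "G"),
    stringsAsFactors = FALSE)
  fixture_family("alpha_SEA", locus, sites, paste0("E", 1:9),
                 mat_h0 = c("E1", "E5", "E7"),
                 pat_h0 = c("E2", "E3", "E4", "E5", "E7"))
}

# The beta-thalassemia worked example: six embryos, CD41-42 (-AAAG),
# affected embryos E4 and E6.
worked_beta_family <- function() {
  locus <- locus_hbb_cd41_42()
  sites <- data.frame(
    pos    = c(5100000L, 5150000L, 5400000L, 5500000L,
               5120000L, 5160000L, 5420000L, 5520000L),
    mother = c("A/G", "C/T", "A/C", "G/T", "T/T", "G/G", "C/C", "T/T"),
    father = c("A/A", "C/C", "A/A", "G/G", "C/T", "A/G", "A/C", "G/T"),
    side   = rep(c("maternal", "paternal"), each = 4),
    hap0   = c("G", "T", "C", "T", "C", "A", "A", "G"),
    stringsAsFactors = FALSE)
  fixture_family("beta_CD41_42", locus, sites, paste0("E", 1:6),
                 mat_h0 = c("E1", "E4", "E5", "E6"),
                 pat_h0 = c("E2", "E4", "E6"),
                 window_upstream_bp = 1e6, window_downstream_bp = 1e6)
}

# Shared path: select, phase and genotype a fixture family.
genotype_fixture <- function(fam, ...) {
  genotype_family(fam, ...)
}

# Small simulator config used across tests; panels kept modest for
# speed with enough informative markers per flank for the 2+2 rule.
test_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(disease = "alpha_SEA", n_families = 1L,
                   embryos_per_family = 6L,
                   n_snps_upstream = 40L, n_snps_downstream = 40L,
                   min_informative_per_cell = 4L,
                   require_affected = TRUE, simulate_cnv = FALSE)
  do.call(sim_config, utils::modifyList(defaults, args))
}
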