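# Build genotype-call rows directly for single-site deduction tests.
call_row <- function(ref, alt, ref_depth, alt_depth, sample = "E5",
                     pos = 119006L, median_total = 100) {
  obs <- data.frame(chrom = "chr16", pos = pos, ref = ref, alt = alt,
                    sample = sample, ref_depth = ref_depth,
                    alt_depth = alt_depth, stringsAsFactors = FALSE)
  # pad with ordinary sites so the per-sample median depth is realistic
  pad <- data.frame(chrom = "chr16", pos = pos + seq_len(9) * 1000L,
                    ref = "A", alt = "G", sample = sample,
                    ref_depth = as.integer(median_total / 2),
                    alt_depth = as.integer(median_total / 2),
                    stringsAsFactors = FALSE)
  calls <- genotype_calls(rbind(obs, pad))
  calls[calls$pos == pos, , drop = FALSE]
}

snp_row <- function(het_a1, het_a2, hom, side = "maternal",
                    pos = 119006L) {
  data.frame(chrom = "chr16", pos = pos, ref = min(het_a1, het_a2),
             alt = max(het_a1, het_a2), side = side,
             het_a1 = het_a1, het_a2 = het_a2, hom_allele = hom,
             location = "upstream", stringsAsFactors = FALSE)
}

test_that("site phase deduction subtracts the obligate allele", {
  # mother A/C, father A/A, affected embryos A/A: the maternal A is M0
  d <- deduce_site_phase(snp_row("A", "C", "A"),
                         call_row("A", "C", 100L, 0L))
  expect_equal(d$status, "resolved")
  expect_equal(d$allele, "A")
  # mother C/C, father C/T, affected embryos C/C: the paternal C is F0
  d <- deduce_site_phase(snp_row("C", "T", "C", side = "paternal"),
                         call_row("C", "T", 100L, 0L))
  expect_equal(d$allele, "C")
  # mother A/C, father T/T, affected embryo A/T: paternal T is obligate
  d <- deduce_site_phase(snp_row("A", "C", "T"),
                         call_row("A", "T", 50L, 50L))
  expect_equal(d$allele, "A")
})

test_that("suspected dropouts and conflicts are withheld", {
  # single obligate allele at half depth: dropout suspected, unresolved
  d <- deduce_site_phase(snp_row("A", "C", "A"),
                         call_row("A", "C", 45L, 0L))
  expect_equal(d$status, "unresolved_ADO")
  # amplification failure: unresolved
  d <- deduce_site_phase(snp_row("A", "C", "A"),
                         call_row("A", "C", 0L, 0L))
  expect_equal(d$status, "unresolved_ADO")
  # two affected embryos disagreeing: conflict
  two <- rbind(call_row("A", "C", 50L, 50L, sample = "E5"),
               call_row("A", "C", 100L, 0L, sample = "E7"))
  d <- deduce_site_phase(snp_row("A", "C", "A"), two)
  expect_equal(d$status, "conflict")
  # no affected embryos at all: the reference is unavailable
  expect_error(deduce_site_phase(snp_row("A", "C", "A"),
                                 call_row("A", "C", 50L, 50L)[0, ]),
               "phasing reference unavailable")
})

test_that("worked families phase to the published disease haplotypes", {
  fam <- worked_alpha_family()
  panel <- select_informative(fam$parents, fam$locus)
  phase <- build_haplotypes(panel, c("E5", "E7"), fam$snp_obs,
                            locus = fam$locus,
                            n_embryos = length(fam$embryos))
  p <- phase$panel
  expect_true(all(p$status == "resolved"))
  expect_equal(p$hap0_allele[p$pos == 119006], "A")
  famb <- worked_beta_family()
  panelb <- select_informative(famb$parents, famb$locus,
                               window_upstream_bp = 1e6,
                               window_downstream_bp = 1e6)
  phaseb <- build_haplotypes(panelb, c("E4", "E6"), famb$snp_obs,
                             locus = famb$locus,
                             n_embryos = length(famb$embryos))
  expect_equal(phaseb$panel$hap0_allele[phaseb$panel$pos == 5120000], "C")
  # at every resolved site {hap0, hap1} is the het parent's allele pair
  expect_true(all(
    (p$hap0_allele == p$het_a1 & p$hap1_allele == p$het_a2) |
      (p$hap0_allele == p$het_a2 & p$hap1_allele == p$het_a1)))
})

test_that("noise-free simulated families phase perfectly", {
  set.seed(71)
  cfg <- test_sim_config(ado_rate = 0, amplification_rate = 1,
                         recombination_rate = 0)
  fam <- simulate_family(cfg, "f")
  affected <- names(which(fam$truth$mutation_genotype == 2L))
  panel <- select_informative(fam$parents, fam$locus)
  phase <- build_haplotypes(panel, affected, fam$snp_obs,
                            locus = fam$locus,
                            n_embryos = length(fam$embryos))
  expect_true(all(phase$panel$status == "resolved"))
  idx <- match(phase$panel$pos, fam$truth$sites$pos)
  truth0 <- ifelse(phase$panel$side == "maternal",
                   fam$truth$maternal_haps[1, idx],
                   fam$truth$paternal_haps[1, idx])
  expect_equal(phase$panel$hap0_allele, unname(truth0))
})

test_that("phasing under ADO stays accurate and mostly resolved", {
  set.seed(72)
  cfg <- test_sim_config(n_snps_upstream = 138, n_snps_downstream = 132,
                         recombination_rate = 0,
                         min_informative_per_cell = NULL,
                         embryos_per_family = 8)
  fam <- simulate_family(cfg, "f")
  affected <- names(which(fam$truth$mutation_genotype == 2L))
  panel <- select_informative(fam$parents, fam$locus)
  phase <- build_haplotypes(panel, affected, fam$snp_obs,
                            locus = fam$locus,
                            n_embryos = length(fam$embryos))
  p <- phase$panel
  expect_gte(mean(p$status == "resolved"), 0.9)
  res <- p[p$status == "resolved", ]
  idx <- match(res$pos, fam$truth$sites$pos)
  truth0 <- ifelse(res$side == "maternal",
                   fam$truth$maternal_haps[1, idx],
                   fam$truth$paternal_haps[1, idx])
  expect_equal(res$hap0_allele, unname(truth0))
})

test_that("an injected discordant genotype flags the site as conflict", {
  fam <- worked_alpha_family()
  obs <- fam$snp_obs
  # corrupt E7 at the 119,006 site: show the other maternal allele
  k <- obs$sample == "E7" & obs$pos == 119006
  obs$ref_depth[k] <- 50L; obs$alt_depth[k] <- 50L  # A/C instead of A/A
  panel <- select_informative(fam$parents, fam$locus)
  # drop the site requirement pressure by adding nothing: site 119006 is
  # one of two upstream maternal markers, so relax the minimum
  phase <- build_haplotypes(panel, c("E5", "E7"), obs, locus = fam$locus,
                            min_flank_resolved = 1,
                            n_embryos = length(fam$embryos))
  expect_equal(phase$panel$status[phase$panel$pos == 119006], "conflict")
  expect_true(is.na(phase$panel$hap0_allele[phase$panel$pos == 119006]))
})

test_that("too few resolved flanking markers abort with the deficient cell", {
  fam <- worked_alpha_family()
  panel <- select_informative(fam$parents, fam$locus)
  # remove the maternal downstream markers entirely
  panel2 <- panel[!(panel$side == "maternal" &
                      panel$location == "downstream"), ]
  expect_error(build_haplotypes(panel2, c("E5", "E7"), fam$snp_obs,
                                locus = fam$locus,
                                n_embryos = length(fam$embryos)),
               "maternal downstream")
  # cohorts below the clinical minimum are not phased
  expect_error(build_haplotypes(panel, c("E5", "E7"), fam$snp_obs,
                                locus = fam$locus, n_embryos = 2),
               "below the phasing minimum")
  expect_error(build_haplotypes(panel, character(), fam$snp_obs,
                                locus = fam$locus,
                                n_embryos = length(fam$embryos)),
               "phasing reference unavailable")
})

test_that("phasing is deterministic and order-independent", {
  fam <- worked_alpha_family()
  panel <- select_informative(fam$parents, fam$locus)
  a <- build_haplotypes(panel, c("E5", "E7"), fam$snp_obs,
                        locus = fam$locus, n_embryos = 9)
  shuffled <- fam$snp_obs[rev(seq_len(nrow(fam$snp_obs))), ]
  b <- build_haplotypes(panel, c("E7", "E5"), shuffled,
                        locus = fam$locus, n_embryos = 9)
  expect_equal(a$panel, b$panel)
})

test_that("the brute-force oracle agrees with subtraction phasing", {
  set.seed(73)
  # clean family: oracle and builder must match exactly
  cfg <- test_sim_config(ado_rate = 0, amplification_rate = 1,
                         recombination_rate = 0)
  fam <- simulate_family(cfg, "f")
  affected <- names(which(fam$truth$mutation_genotype == 2L))
  panel <- select_informative(fam$parents, fam$locus)
  phase <- build_haplotypes(panel, affected, fam$snp_obs,
                            locus = fam$locus,
                            n_embryos = length(fam$embryos))
  orc <- phase_oracle(fam$truth, panel, affected, fam$snp_obs)
  for (sd in c("maternal", "paternal")) {
    expect_false(orc[[sd]]$ambiguous)
    sub <- phase$panel[phase$panel$side == sd &
                         phase$panel$status == "resolved", ]
    expect_equal(sub$hap0_allele,
                 unname(orc[[sd]]$hap0[as.character(sub$pos)]))
  }
  # noisy seeded families: agreement on every resolved site
  for (i in 1:30) {
    fam <- simulate_family(test_sim_config(recombination_rate = 0), "f")
    affected <- names(which(fam$truth$mutation_genotype == 2L))
    panel <- select_informative(fam$parents, fam$locus)
    phase <- tryCatch(
      build_haplotypes(panel, affected, fam$snp_obs, locus = fam$locus,
                       n_embryos = length(fam$embryos)),
      error = function(e) NULL)
    if (is.null(phase)) next
    orc <- phase_oracle(fam$truth, panel, affected, fam$snp_obs)
    for (sd in c("maternal", "paternal")) {
      if (orc[[sd]]$ambiguous) next
      sub <- phase$panel[phase$panel$side == sd &
                           phase$panel$status == "resolved", ]
      expect_equal(sub$hap0_allele,
                   unname(orc[[sd]]$hap0[as.character(sub$pos)]))
    }
  }
})

test_that("a single marker per side leaves the oracle ambiguous under ADO", {
  # one maternal site: mother A/C, father A/A, disease allele A
  truth <- list(
    sites = data.frame(chrom = "chr16", pos = 119006L, ref = "A",
                       alt = "C", stringsAsFactors = FALSE),
    maternal_haps = rbind(hap0 = "A", hap1 = "C"),
    paternal_haps = rbind(hap0 = "A", hap1 = "A"))
  panel <- snp_row("A", "C", "A")
  # affected embryo observed A/A at full depth: both assignments fit the
  # observed-subset rule, so the genotype-only oracle cannot decide
  obs_hom <- data.frame(chrom = "chr16", pos = 119006L, ref = "A",
                        alt = "C", sample = "E1", ref_depth = 100L,
                        alt_depth = 0L, stringsAsFactors = FALSE)
  orc <- phase_oracle(truth, panel, "E1", obs_hom)
  expect_true(orc$maternal$ambiguous)
  # observed A/C: only hap0 = C fits after subtracting the obligate A
  truth2 <- truth
  truth2$maternal_haps <- rbind(hap0 = "C", hap1 = "A")
  obs_het <- obs_hom; obs_het$alt_depth <- 50L; obs_het$ref_depth <- 50L
  orc2 <- phase_oracle(truth2, panel, "E1", obs_het)
  expect_false(orc2$maternal$ambiguous)
  expect_equal(unname(orc2$maternal$hap0), "C")
})
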