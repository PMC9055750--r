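worked_phase <- function(fam) {
  panel <- select_informative(fam$parents, fam$locus,
                              fam$config$window_upstream_bp,
                              fam$config$window_downstream_bp)
  affected <- identify_affected_embryos(
    call_mutation_all(fam$mutation_obs, fam$locus, fam$embryos))
  build_haplotypes(panel, affected, fam$snp_obs, locus = fam$locus,
                   n_embryos = length(fam$embryos))
}

test_that("linkage voting reproduces the published haplotype carriers", {
  fam <- worked_alpha_family()
  phase <- worked_phase(fam)
  calls <- genotype_calls(fam$snp_obs)
  mat_h0 <- pat_h0 <- character()
  for (e in fam$embryos) {
    ec <- calls[calls$sample == e, ]
    m <- assign_side(ec, phase, "maternal")
    p <- assign_side(ec, phase, "paternal")
    if (m$assignment == "H0") mat_h0 <- c(mat_h0, e)
    if (p$assignment == "H0") pat_h0 <- c(pat_h0, e)
    expect_true(all(colSums(m$support) <= sum(phase$panel$side ==
                                                "maternal")))
  }
  expect_setequal(mat_h0, c("E1", "E5", "E7"))
  expect_setequal(pat_h0, c("E2", "E3", "E4", "E5", "E7"))
})

test_that("the worked families classify to the published partitions", {
  res <- genotype_family(worked_alpha_family())
  st <- setNames(res$calls$final_status, res$calls$embryo)
  expect_setequal(names(st)[st == "affected"], c("E5", "E7"))
  expect_setequal(names(st)[st == "carrier"], c("E1", "E2", "E3", "E4"))
  expect_setequal(names(st)[st == "noncarrier"], c("E6", "E8", "E9"))
  expect_true(all(res$calls$flags == ""))

  resb <- genotype_family(worked_beta_family())
  stb <- setNames(resb$calls$final_status, resb$calls$embryo)
  expect_setequal(names(stb)[stb == "affected"], c("E4", "E6"))
  expect_setequal(names(stb)[stb == "carrier"], c("E1", "E2", "E5"))
  expect_setequal(names(stb)[stb == "noncarrier"], "E3")
})

test_that("a positional vote changepoint is treated as recombination", {
  fam <- worked_alpha_family()
  phase <- worked_phase(fam)
  # craft an embryo whose maternal votes are H0 upstream, H1 downstream
  mk_obs <- function(upstream_h0, downstream_h0) {
    p <- phase$panel
    do.call(rbind, lapply(seq_len(nrow(p)), function(i) {
      s <- p[i, ]
      h0 <- if (s$side == "paternal") FALSE
      else if (s$location == "upstream") upstream_h0 else downstream_h0
      trans <- if (h0) s$hap0_allele else s$hap1_allele
      alleles <- c(trans, s$hom_allele)
      data.frame(chrom = s$chrom, pos = s$pos, ref = s$ref, alt = s$alt,
                 sample = "EX",
                 ref_depth = 50L * sum(alleles == s$ref),
                 alt_depth = 50L * sum(alleles == s$alt),
                 stringsAsFactors = FALSE)
    }))
  }
  ec <- genotype_calls(mk_obs(TRUE, FALSE))
  m <- assign_side(ec, phase, "maternal")
  # the crossover straddles the gene: no haplotype can be assigned there
  expect_equal(m$assignment, "inconclusive")
  expect_true("recombination_suspected" %in% m$flags)
  # concordant votes on both flanks carry no flag
  clean <- assign_side(ec, phase, "paternal")
  expect_equal(clean$assignment, "H1")
  expect_length(clean$flags, 0)
})

test_that("a crossover inside one flank keeps the gene-proximal markers", {
  # 4 upstream + 2 downstream maternal markers; votes flip between the
  # two most distal upstream markers -> gene-proximal run decides
  panel <- data.frame(
    chrom = "chr16",
    pos = c(100000L, 110000L, 120000L, 130000L, 300000L, 310000L),
    ref = "A", alt = "C", side = "maternal",
    het_a1 = "A", het_a2 = "C", hom_allele = "A",
    location = c(rep("upstream", 4), rep("downstream", 2)),
    hap0_allele = "A", hap1_allele = "C", status = "resolved",
    stringsAsFactors = FALSE)
  phase <- structure(list(panel = panel, n_affected_used = 1L),
                     class = "pgt_phase")
  # two distal H1 votes (observed C), then four H0 votes (observed A)
  obs <- data.frame(chrom = "chr16", pos = panel$pos, ref = "A", alt = "C",
                    sample = "EX",
                    ref_depth = c(50L, 50L, 100L, 100L, 100L, 100L),
                    alt_depth = c(50L, 50L, 0L, 0L, 0L, 0L),
                    stringsAsFactors = FALSE)
  m <- assign_side(genotype_calls(obs), phase, "maternal")
  expect_equal(m$assignment, "H0")
  expect_true("recombination_suspected" %in% m$flags)
  # flip so that only one upstream marker stays gene-proximal: the
  # reduced set misses the 2-upstream minimum and stays inconclusive
  obs2 <- obs
  obs2$ref_depth <- c(50L, 50L, 50L, 100L, 100L, 100L)
  obs2$alt_depth <- c(50L, 50L, 50L, 0L, 0L, 0L)
  m2 <- assign_side(genotype_calls(obs2), phase, "maternal")
  expect_equal(m2$assignment, "inconclusive")
  expect_true("recombination_suspected" %in% m2$flags)
})

test_that("classification combines sides and the direct call", {
  h0 <- list(assignment = "H0", support = NULL, flags = character())
  h1 <- list(assignment = "H1", support = NULL, flags = character())
  inc <- list(assignment = "inconclusive", support = NULL,
              flags = character())
  pass2 <- structure(list(genotype = 2L, confidence = "pass"),
                     class = "depth_call")
  amb <- structure(list(genotype = NA_integer_, confidence = "ambiguous"),
                   class = "depth_call")
  expect_equal(classify_embryo(h0, h0, pass2)$final_status, "affected")
  expect_equal(classify_embryo(h0, h1)$final_status, "carrier")
  expect_equal(classify_embryo(h1, h1)$final_status, "noncarrier")
  expect_equal(classify_embryo(inc, inc)$final_status, "inconclusive")
  expect_equal(classify_embryo(h0, inc)$final_status, "inconclusive")
  # ambiguous direct call: linkage stands, ADO flagged at the mutation
  cl <- classify_embryo(h0, h1, amb)
  expect_equal(cl$final_status, "carrier")
  expect_true("ADO_at_mutation_site" %in% cl$flags)
  # hard contradiction: withheld rather than guessed
  cl2 <- classify_embryo(h1, h1, pass2)
  expect_equal(cl2$final_status, "inconclusive")
  expect_true("discordant_direct_vs_linkage" %in% cl2$flags)
})

test_that("voting is invariant to site and embryo order", {
  fam <- worked_alpha_family()
  phase <- worked_phase(fam)
  calls <- genotype_calls(fam$snp_obs)
  ec <- calls[calls$sample == "E3", ]
  a <- assign_side(ec, phase, "paternal")
  b <- assign_side(ec[rev(seq_len(nrow(ec))), ], phase, "paternal")
  expect_equal(a$assignment, b$assignment)
  expect_equal(a$support, b$support)
})

test_that("raising the flank minimum never creates a conclusive call", {
  set.seed(81)
  for (i in 1:5) {
    fam <- simulate_family(test_sim_config(min_informative_per_cell = 6L),
                           "f")
    res2 <- genotype_family(fam, min_flank_votes = 2)
    res6 <- genotype_family(fam, min_flank_votes = 6)
    # conclusiveness can only shrink as the flank minimum rises
    for (sd in c("maternal_assignment", "paternal_assignment")) {
      inc2 <- res2$calls[[sd]] == "inconclusive"
      inc6 <- res6$calls[[sd]] == "inconclusive"
      expect_true(all(inc6[inc2]))
      # and conclusive assignments that survive are unchanged
      keep <- !inc2 & !inc6
      expect_equal(res6$calls[[sd]][keep], res2$calls[[sd]][keep])
    }
  }
})

test_that("simulated cohorts genotype to simulation truth", {
  set.seed(82)
  cfg <- test_sim_config(n_families = 10, embryos_per_family = 8,
                         recombination_rate = 0,
                         min_informative_per_cell = 6L)
  cohort <- simulate_cohort(cfg)
  n_concl <- 0L; n_total <- 0L
  for (fam in cohort) {
    res <- genotype_family(fam)
    truth <- c("noncarrier", "carrier", "affected")[
      fam$truth$mutation_genotype[res$calls$embryo] + 1L]
    concl <- res$calls$final_status != "inconclusive"
    expect_equal(res$calls$final_status[concl], truth[concl])
    n_concl <- n_concl + sum(concl); n_total <- n_total + length(concl)
  }
  expect_gte(n_concl / n_total, 0.99)
})

test_that("WGA metrics are recovered from their own annotations", {
  n <- 20000
  parents <- data.frame(chrom = "chr16", pos = seq_len(n),
                        ref = "A", alt = "C",
                        mother = "A/A", father = "C/C",
                        stringsAsFactors = FALSE)
  g <- data.frame(chrom = "chr16", pos = seq_len(n), ref = "A", alt = "C",
                  allele1 = "A", allele2 = "C", stringsAsFactors = FALSE)
  # zero noise: amplification 1, ADO 0
  set.seed(83)
  clean <- simulate_depths(apply_wga(g, 0, 1), 100)
  clean$sample <- "E1"
  m <- estimate_wga_metrics(clean, parents)
  expect_equal(m$amplification_rate, 1)
  expect_equal(m$ado_rate, 0)
  # configured rates recovered within 3 binomial SEs
  obs <- simulate_depths(apply_wga(g, 0.0426, 0.9471), 100)
  obs$sample <- "E1"
  est <- estimate_wga_metrics(obs, parents)
  expect_lt(abs(est$amplification_rate - 0.9471),
            3 * sqrt(0.9471 * 0.0529 / n))
  expect_lt(abs(est$ado_rate - 0.0426),
            3 * sqrt(0.0426 * (1 - 0.0426) / est$n_obligate_het))
  # every site failed: ADO undefined, reported as an error
  dead <- obs; dead$ref_depth <- 0L; dead$alt_depth <- 0L
  expect_error(estimate_wga_metrics(dead, parents), "undefined")
})
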