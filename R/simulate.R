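#' Apply whole-genome-amplification artifacts to true genotypes
#'
#' Models the two WGA error processes seen in few-cell MDA: complete
#' amplification failure of a site (probability `1 - amplification_rate`)
#' and allele dropout at heterozygous sites (one of the two alleles is
#' lost with probability `ado_rate`; the lost allele is chosen at
#' random). Homozygous sites cannot drop out. Truth annotations are kept
#' so the error rates can be re-estimated downstream.
#'
#' @param genotypes Data frame with character columns `allele1` and
#'   `allele2`, one row per site-call.
#' @param ado_rate,amplification_rate Probabilities in `[0, 1]`;
#'   degenerate values 0 and 1 are permitted.
#' @return The input with added columns `obs1`, `obs2` (observed alleles,
#'   `NA` when lost), `amplified` (logical), `ado` (logical) and
#'   `dropped_allele`.
#' @export
apply_wga <- function(genotypes, ado_rate, amplification_rate) {
  if (ado_rate < 0 || ado_rate > 1 ||
      amplification_rate < 0 || amplification_rate > 1)
    stop("apply_wga: rates must be in [0, 1]")
  n <- nrow(genotypes)
  out <- genotypes
  out$amplified <- stats::runif(n) < amplification_rate
  het <- out$allele1 != out$allele2
  out$ado <- het & out$amplified & (stats::runif(n) < ado_rate)
  drop_first <- stats::runif(n) < 0.5
  out$dropped_allele <- ifelse(out$ado,
                               ifelse(drop_first, out$allele1, out$allele2),
                               NA_character_)
  out$obs1 <- ifelse(out$amplified &
                       !(out$ado & drop_first), out$allele1, NA_character_)
  out$obs2 <- ifelse(out$amplified &
                       !(out$ado & !drop_first), out$allele2, NA_character_)
  out
}

#' Draw allele-specific read depths for observed genotypes
#'
#' Each surviving haplotype copy of an allele contributes
#' Poisson(`mean_depth / 2`) reads, so a clean heterozygote receives
#' roughly `mean_depth` total reads split evenly, a homozygote receives
#' Poisson(`mean_depth`) on one allele, and a dropout site receives about
#' half depth on the surviving allele. Unamplified sites get zero reads.
#'
#' @param observed Data frame as returned by [apply_wga()], additionally
#'   carrying `ref` and `alt` columns naming the site alleles.
#' @param mean_depth Mean total depth at a two-copy site; must be > 0.
#' @return The input with integer columns `ref_depth` and `alt_depth`.
#' @export
simulate_depths <- function(observed, mean_depth) {
  if (mean_depth <= 0) stop("simulate_depths: mean_depth must be > 0")
  n <- nrow(observed)
  ref_copies <- (!is.na(observed$obs1) & observed$obs1 == observed$ref) +
    (!is.na(observed$obs2) & observed$obs2 == observed$ref)
  alt_copies <- (!is.na(observed$obs1) & observed$obs1 == observed$alt) +
    (!is.na(observed$obs2) & observed$obs2 == observed$alt)
  observed$ref_depth <- stats::rpois(n, mean_depth / 2 * ref_copies)
  observed$alt_depth <- stats::rpois(n, mean_depth / 2 * alt_copies)
  observed
}

# One meiosis along a sorted coordinate vector: returns 0/1 haplotype
# labels per coordinate under a Poisson crossover process.
transmit_side <- function(pos_sorted, recombination_rate) {
  n <- length(pos_sorted)
  start <- sample(0:1, 1L)
  if (n == 1L) return(start)
  gaps <- diff(pos_sorted)
  switch <- stats::rbinom(n - 1L, 1L, 1 - exp(-recombination_rate * gaps))
  (start + cumsum(c(0L, switch))) %% 2L
}

draw_panel <- function(cfg) {
  locus <- cfg$locus
  pos_up <- locus$start - cfg$window_upstream_bp +
    sort(sample.int(cfg$window_upstream_bp, cfg$n_snps_upstream)) - 1L
  pos_down <- locus$end +
    sort(sample.int(cfg$window_downstream_bp, cfg$n_snps_downstream))
  pos <- as.integer(c(pos_up, pos_down))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(chrom = locus$chrom, pos = pos, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

# Two haplotype allele vectors per parent; row 1 is the disease-linked
# haplotype (both parents are carriers by construction).
draw_parent_haps <- function(sites, allele_freq) {
  n <- nrow(sites)
  draw <- function() ifelse(stats::runif(n) < allele_freq, sites$alt, sites$ref)
  rbind(hap0 = draw(), hap1 = draw())
}

informative_cell_counts <- function(sites, m_haps, f_haps, locus) {
  m_het <- m_haps[1, ] != m_haps[2, ]
  f_het <- f_haps[1, ] != f_haps[2, ]
  side <- ifelse(m_het & !f_het, "maternal",
                 ifelse(f_het & !m_het, "paternal", NA))
  loc <- locus_location(sites$pos, locus)
  table(factor(side, c("maternal", "paternal")),
        factor(loc, c("upstream", "downstream")))
}

draw_karyotype <- function(cfg) {
  u <- stats::runif(1)
  if (u < cfg$aneuploidy_rate) {
    state <- sample(c("gain", "loss"), 1L)
    frac <- 1
  } else if (u < cfg$aneuploidy_rate + cfg$mosaic_rate) {
    state <- sample(c("mosaic_gain", "mosaic_loss"), 1L)
    frac <- stats::runif(1, cfg$mosaic_fraction_range[1],
                         cfg$mosaic_fraction_range[2])
  } else {
    return(list(state = "euploid", chrom = NA_character_, fraction = 0))
  }
  list(state = state, chrom = paste0("chr", sample.int(22L, 1L)),
       fraction = frac)
}

#' Simulate one carrier-couple family with embryos and observations
#'
#' Both parents carry exactly one disease allele, phase-linked by
#' construction to their haplotype 0 (the M0/F0 convention: index 0 is
#' disease-associated). Each embryo draws one haplotype per side with
#' crossovers at the configured per-bp rate; the haplotype label at the
#' mutation locus determines the transmitted disease allele, so the
#' mutation genotype equals the number of sides on haplotype 0.
#' Observations are produced by [apply_wga()] followed by
#' [simulate_depths()]; the mutation region gets its own depth profile
#' (near-zero inside a homozygous SEA deletion), and binned read counts
#' for aneuploidy screening are drawn per embryo.
#'
#' Randomness comes from the R session RNG; seed it (or use
#' [simulate_cohort()], which seeds from `config$seed`) for
#' reproducibility.
#'
#' @param config A [sim_config()].
#' @param family_id Label for the family.
#' @return A list of class `pgt_family` with elements `parents` (genotype
#'   table), `snp_obs` (long allele-depth table: chrom, pos, ref, alt,
#'   sample, ref_depth, alt_depth), `mutation_obs` (depth profile over
#'   the mutation region and flanks), `cnv` (binned counts, or `NULL`),
#'   `karyotypes`, and `truth` (parental diplotypes, per-embryo
#'   haplotype labels, crossovers, mutation genotypes, WGA annotations).
#' @export
simulate_family <- function(config, family_id = "fam_01") {
  validate_sim_config(config)
  cfg <- config
  locus <- cfg$locus
  sites <- draw_panel(cfg)
  n_sites <- nrow(sites)

  m_haps <- draw_parent_haps(sites, cfg$allele_freq)
  f_haps <- draw_parent_haps(sites, cfg$allele_freq)
  if (!is.null(cfg$min_informative_per_cell)) {
    for (try in seq_len(1000L)) {
      if (all(informative_cell_counts(sites, m_haps, f_haps, locus) >=
              cfg$min_informative_per_cell)) break
      if (try == 1000L)
        stop("simulate_family: could not reach 'min_informative_per_cell'; ",
             "enlarge the panel or lower the requirement")
      m_haps <- draw_parent_haps(sites, cfg$allele_freq)
      f_haps <- draw_parent_haps(sites, cfg$allele_freq)
    }
  }

  gt <- function(h) paste(pmin(h[1, ], h[2, ]), pmax(h[1, ], h[2, ]), sep = "/")
  parents <- cbind(sites, mother = gt(m_haps), father = gt(f_haps),
                   stringsAsFactors = FALSE)

  n_embryos <- if (length(cfg$embryos_per_family) == 2L)
    sample(seq(cfg$embryos_per_family[1], cfg$embryos_per_family[2]), 1L)
  else cfg$embryos_per_family
  embryos <- paste0("E", seq_len(n_embryos))

  locus_mid <- as.integer(round((locus$start + locus$end) / 2))
  path <- sort(c(sites$pos, locus_mid))
  locus_idx <- match(locus_mid, path)
  site_idx <- match(sites$pos, path)

  draw_transmissions <- function() {
    mat <- matrix(0L, n_embryos, n_sites)
    pat <- matrix(0L, n_embryos, n_sites)
    mat_at <- pat_at <- integer(n_embryos)
    for (e in seq_len(n_embryos)) {
      lm <- transmit_side(path, cfg$recombination_rate)
      lp <- transmit_side(path, cfg$recombination_rate)
      mat[e, ] <- lm[site_idx]; pat[e, ] <- lp[site_idx]
      mat_at[e] <- lm[locus_idx]; pat_at[e] <- lp[locus_idx]
    }
    list(mat = mat, pat = pat, mat_at = mat_at, pat_at = pat_at,
         genotype = (mat_at == 0L) + (pat_at == 0L))
  }
  tr <- draw_transmissions()
  if (cfg$require_affected) {
    for (try in seq_len(10000L)) {
      if (any(tr$genotype == 2L)) break
      tr <- draw_transmissions()
    }
    if (!any(tr$genotype == 2L))
      stop("simulate_family: no affected embryo after 10000 redraws")
  }

  # SNP observations: WGA artifacts then allele-specific depths
  obs_list <- vector("list", n_embryos)
  for (e in seq_len(n_embryos)) {
    g <- data.frame(
      chrom = sites$chrom, pos = sites$pos,
      ref = sites$ref, alt = sites$alt,
      allele1 = m_haps[cbind(tr$mat[e, ] + 1L, seq_len(n_sites))],
      allele2 = f_haps[cbind(tr$pat[e, ] + 1L, seq_len(n_sites))],
      stringsAsFactors = FALSE)
    g <- apply_wga(g, cfg$ado_rate, cfg$amplification_rate)
    g <- simulate_depths(g, cfg$mean_depth)
    g$sample <- embryos[e]
    obs_list[[e]] <- g
  }
  obs_full <- do.call(rbind, obs_list)
  snp_obs <- obs_full[, c("chrom", "pos", "ref", "alt", "sample",
                          "ref_depth", "alt_depth")]
  rownames(snp_obs) <- NULL
  wga_truth <- obs_full[, c("sample", "pos", "allele1", "allele2",
                            "amplified", "ado", "dropped_allele")]
  rownames(wga_truth) <- NULL

  geno <- stats::setNames(tr$genotype, embryos)
  mutation_obs <- simulate_mutation_obs(locus, geno, cfg)

  karyotypes <- do.call(rbind, lapply(embryos, function(e) {
    k <- draw_karyotype(cfg)
    data.frame(sample = e, state = k$state, chrom = k$chrom,
               fraction = k$fraction, stringsAsFactors = FALSE)
  }))

  cnv <- NULL
  if (cfg$simulate_cnv) {
    cnv <- do.call(rbind, lapply(seq_len(n_embryos), function(e) {
      k <- as.list(karyotypes[e, c("state", "chrom", "fraction")])
      prof <- simulate_cnv_profile(k, n_fragments = cfg$n_fragments,
                                   bin_size = cfg$cnv_bin_size)
      prof$sample <- embryos[e]
      prof
    }))
  }

  structure(list(
    family_id = family_id, disease = cfg$disease, locus = locus,
    config = cfg, embryos = embryos,
    parents = parents, snp_obs = snp_obs, mutation_obs = mutation_obs,
    cnv = cnv, karyotypes = karyotypes,
    truth = list(
      maternal_haps = m_haps, paternal_haps = f_haps, sites = sites,
      maternal_labels = tr$mat, paternal_labels = tr$pat,
      maternal_at_locus = stats::setNames(tr$mat_at, embryos),
      paternal_at_locus = stats::setNames(tr$pat_at, embryos),
      mutation_genotype = geno,
      wga = wga_truth)),
    class = "pgt_family")
}

# Depth profile over the mutation region and its flanks. For a large
# deletion the copy state inside the region is 2 minus the number of
# disease alleles; zero copies leave only WGA background reads
# (Poisson(0.02 x mean_depth), near-zero but not strictly zero). For a
# small indel, allele counts at the mutation site go through the same
# ADO/amplification model as any heterozygous site.
simulate_mutation_obs <- function(locus, mutation_genotype, cfg) {
  embryos <- names(mutation_genotype)
  flank_pos <- c(
    as.integer(round(seq(locus$flank_left[1], locus$flank_left[2],
                         length.out = 8))),
    as.integer(round(seq(locus$flank_right[1], locus$flank_right[2],
                         length.out = 8))))
  res <- list()
  for (e in embryos) {
    g <- mutation_genotype[[e]]
    if (locus$kind == "large_deletion") {
      region_pos <- as.integer(round(seq(locus$start, locus$end,
                                         length.out = 20)))
      pos <- c(region_pos, flank_pos)
      copies <- c(rep(2L - g, 20), rep(2L, length(flank_pos)))
      lam <- ifelse(copies > 0L, cfg$mean_depth / 2 * copies,
                    0.02 * cfg$mean_depth)
      amp <- stats::runif(length(pos)) < cfg$amplification_rate
      depth <- ifelse(amp, stats::rpois(length(pos), lam), 0L)
      res[[e]] <- data.frame(
        sample = e, chrom = locus$chrom, pos = pos,
        location = c(rep("region", 20), rep("flank", length(flank_pos))),
        ref_depth = as.integer(depth), alt_depth = 0L,
        stringsAsFactors = FALSE)
    } else {
      site <- data.frame(chrom = locus$chrom, pos = locus$mutation_pos,
                         ref = "REF", alt = "DEL",
                         allele1 = if (g >= 1) "DEL" else "REF",
                         allele2 = if (g == 2) "DEL" else "REF",
                         stringsAsFactors = FALSE)
      site <- simulate_depths(
        apply_wga(site, cfg$ado_rate, cfg$amplification_rate),
        cfg$mean_depth)
      amp <- stats::runif(length(flank_pos)) < cfg$amplification_rate
      fl_depth <- ifelse(amp, stats::rpois(length(flank_pos), cfg$mean_depth),
                         0L)
      res[[e]] <- data.frame(
        sample = e, chrom = locus$chrom,
        pos = c(site$pos, flank_pos),
        location = c("region", rep("flank", length(flank_pos))),
        ref_depth = as.integer(c(site$ref_depth, fl_depth)),
        alt_depth = as.integer(c(site$alt_depth, rep(0L, length(flank_pos)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Simulate a whole cohort of families
#'
#' Seeds the session RNG from `config$seed` (when set) and generates
#' `config$n_families` families, so a fixed seed reproduces the full
#' cohort byte-identically.
#'
#' @param config A [sim_config()].
#' @return Named list of [simulate_family()] results
#'   (`fam_01`, `fam_02`, ...).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  ids <- sprintf("fam_%02d", seq_len(config$n_families))
  stats::setNames(lapply(ids, function(id) simulate_family(config, id)), ids)
}

#' @export
print.pgt_family <- function(x, ...) {
  cat(sprintf("<pgt_family> %s (%s): %d embryos, %d panel SNPs, %d affected\n",
              x$family_id, x$disease, length(x$embryos),
              nrow(x$parents), sum(x$truth$mutation_genotype == 2L)))
  invisible(x)
}
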