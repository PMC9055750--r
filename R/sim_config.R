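#' Simulator configuration
#'
#' Builds and validates the configuration for the synthetic-cohort
#' generator. Defaults reproduce the study conditions: SNP panels of 138
#' markers within 1 Mb upstream and 132 within 2 Mb downstream of the
#' alpha-globin SEA deletion (beta preset: 85 markers within 1 Mb), a
#' per-site amplification rate of 94.71%, a per-heterozygous-site allele
#' dropout (ADO) rate of 4.26%, mean sequencing depth 100x (panel
#' designed for >30x), and recombination at 1e-8 per bp (~1 cM/Mb).
#'
#' @param disease `"alpha_SEA"` or `"beta_CD41_42"`.
#' @param n_families Number of families to simulate.
#' @param embryos_per_family A count, or a length-2 range sampled
#'   uniformly per family.
#' @param n_snps_upstream,n_snps_downstream Panel sizes per window;
#'   `NULL` uses the disease preset.
#' @param window_upstream_bp,window_downstream_bp Window widths flanking
#'   the mutation region; `NULL` uses the disease preset.
#' @param ado_rate Probability that a heterozygous site loses one allele
#'   during whole-genome amplification.
#' @param amplification_rate Probability that a site amplifies at all.
#' @param mean_depth Mean total read depth at a diploid site (each
#'   haplotype copy contributes Poisson(mean_depth/2) reads).
#' @param recombination_rate Per-bp crossover probability per meiosis.
#' @param aneuploidy_rate Probability an embryo carries a full-chromosome
#'   gain or loss.
#' @param mosaic_rate Probability an embryo is mosaic for a gain or loss
#'   (the study reports 10.6% blastocyst mosaicism).
#' @param mosaic_fraction_range Range of the aneuploid cell fraction in
#'   mosaic embryos.
#' @param allele_freq Population alternate-allele frequency used to draw
#'   parental haplotypes (0.5 makes roughly half the panel informative).
#' @param require_affected If `TRUE`, embryo transmissions are redrawn
#'   until the family contains at least one affected embryo (the clinical
#'   precondition for phasing).
#' @param min_informative_per_cell If set, parental genotypes are redrawn
#'   until each side x location cell (maternal/paternal x
#'   upstream/downstream) holds at least this many informative SNPs.
#' @param n_fragments Fragments sequenced per embryo for copy-number
#'   screening (~1.5 million in the study).
#' @param cnv_bin_size Bin width for copy-number profiles.
#' @param simulate_cnv If `FALSE`, skip binned-count generation (the
#'   monogenic pipeline does not need it).
#' @param seed Integer seed; fixing it makes the whole cohort
#'   byte-reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(disease = c("alpha_SEA", "beta_CD41_42"),
                       n_families = 1L,
                       embryos_per_family = 8L,
                       n_snps_upstream = NULL,
                       n_snps_downstream = NULL,
                       window_upstream_bp = NULL,
                       window_downstream_bp = NULL,
                       ado_rate = 0.0426,
                       amplification_rate = 0.9471,
                       mean_depth = 100,
                       recombination_rate = 1e-8,
                       aneuploidy_rate = 0.2,
                       mosaic_rate = 0.106,
                       mosaic_fraction_range = c(0.3, 0.7),
                       allele_freq = 0.5,
                       require_affected = FALSE,
                       min_informative_per_cell = NULL,
                       n_fragments = 1.5e6,
                       cnv_bin_size = 1e6,
                       simulate_cnv = TRUE,
                       seed = NULL) {
  disease <- match.arg(disease)
  preset <- switch(disease,
    alpha_SEA    = list(n_up = 138L, n_down = 132L, w_up = 1e6, w_down = 2e6,
                        locus = locus_sea_hba()),
    beta_CD41_42 = list(n_up = 43L, n_down = 42L, w_up = 1e6, w_down = 1e6,
                        locus = locus_hbb_cd41_42()))
  cfg <- list(
    disease = disease,
    n_families = as.integer(n_families),
    embryos_per_family = as.integer(embryos_per_family),
    n_snps_upstream = as.integer(n_snps_upstream %||% preset$n_up),
    n_snps_downstream = as.integer(n_snps_downstream %||% preset$n_down),
    window_upstream_bp = window_upstream_bp %||% preset$w_up,
    window_downstream_bp = window_downstream_bp %||% preset$w_down,
    ado_rate = ado_rate,
    amplification_rate = amplification_rate,
    mean_depth = mean_depth,
    recombination_rate = recombination_rate,
    aneuploidy_rate = aneuploidy_rate,
    mosaic_rate = mosaic_rate,
    mosaic_fraction_range = mosaic_fraction_range,
    allele_freq = allele_freq,
    require_affected = isTRUE(require_affected),
    min_informative_per_cell = min_informative_per_cell,
    n_fragments = n_fragments,
    cnv_bin_size = cnv_bin_size,
    simulate_cnv = isTRUE(simulate_cnv),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    locus = preset$locus)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_sim_config <- function(cfg) {
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0) || any(v > 1))
      stop(sprintf("sim_config: '%s' must be a probability in [0, 1]", field),
           call. = FALSE)
  }
  for (f in c("ado_rate", "amplification_rate", "recombination_rate",
              "aneuploidy_rate", "mosaic_rate", "mosaic_fraction_range",
              "allele_freq"))
    chk_prob(f)
  if (cfg$aneuploidy_rate + cfg$mosaic_rate > 1)
    stop("sim_config: 'aneuploidy_rate' + 'mosaic_rate' must not exceed 1",
         call. = FALSE)
  if (!is.numeric(cfg$mean_depth) || cfg$mean_depth <= 0)
    stop("sim_config: 'mean_depth' must be > 0", call. = FALSE)
  if (cfg$window_upstream_bp <= 0 || cfg$window_downstream_bp <= 0)
    stop("sim_config: 'window_upstream_bp'/'window_downstream_bp' must be > 0",
         call. = FALSE)
  if (cfg$n_snps_upstream < 0 || cfg$n_snps_downstream < 0)
    stop("sim_config: SNP panel sizes must be non-negative", call. = FALSE)
  if (any(cfg$embryos_per_family < 1) ||
      !length(cfg$embryos_per_family) %in% 1:2)
    stop("sim_config: 'embryos_per_family' must be a count or a range",
         call. = FALSE)
  if (cfg$n_families < 1)
    stop("sim_config: 'n_families' must be >= 1", call. = FALSE)
  if (cfg$n_fragments <= 0)
    stop("sim_config: 'n_fragments' must be > 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s: %d family(ies), %s embryos, panel %d up + %d down\n",
    x$disease, x$n_families,
    paste(x$embryos_per_family, collapse = "-"),
    x$n_snps_upstream, x$n_snps_downstream))
  cat(sprintf("  ADO %.4f, amplification %.4f, depth %gx, recomb %g/bp\n",
              x$ado_rate, x$amplification_rate, x$mean_depth,
              x$recombination_rate))
  invisible(x)
}
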