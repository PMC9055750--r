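pipeline_stage_names <- c("simulate", "phase", "genotype", "cnv", "report")

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("run_pipeline: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- c(pipeline_stage_names, "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("run_pipeline: unknown config key(s): ",
         paste(unknown, collapse = ", "))
  config
}

#' Run the PGT pipeline end to end or stage by stage
#'
#' Wires the stages `simulate` -> `phase` -> `genotype` -> `cnv` ->
#' `report` over an output directory of per-family artifacts. Each
#' stage reads only the on-disk outputs of its predecessors, so a
#' single stage can be re-run from existing artifacts; identical config
#' and seed reproduce identical outputs. The resolved configuration is
#' written next to the outputs.
#'
#' @param config A list (or YAML file path) with optional blocks
#'   `simulate` (arguments of [sim_config()]), `phase`
#'   (`min_flank_resolved`, `min_cohort`), `genotype`
#'   (`min_flank_votes`, `winner_frac`), `cnv`, `report`, and a
#'   top-level `seed`. Unknown keys are rejected.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `config$seed`.
#' @param stages Subset of stages to execute, in order.
#' @param quiet Suppress per-family progress messages.
#' @return Invisibly, the path of the report JSON (or `out_dir` when
#'   the report stage was not run).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL,
                         stages = pipeline_stage_names, quiet = FALSE) {
  config <- load_run_config(config)
  stages <- match.arg(stages, pipeline_stage_names, several.ok = TRUE)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  cfg <- do.call(sim_config, sim_args)

  if ("simulate" %in% stages) {
    cohort <- simulate_cohort(cfg)
    write_locus(cfg$locus, file.path(out_dir, "locus.bed"),
                file.path(out_dir, "locus.json"))
    for (fam in cohort) {
      fdir <- file.path(out_dir, fam$family_id)
      dir.create(fdir, showWarnings = FALSE)
      write_parental_vcf(fam$parents, file.path(fdir, "parents.vcf"))
      write_tsv_versioned(fam$snp_obs, file.path(fdir, "snp_obs.tsv"),
                          "embryo_observations")
      write_tsv_versioned(fam$mutation_obs,
                          file.path(fdir, "mutation_obs.tsv"),
                          "mutation_depth_profile")
      write_tsv_versioned(fam$karyotypes,
                          file.path(fdir, "karyotypes.tsv"),
                          "true_karyotypes")
      if (!is.null(fam$cnv))
        write_tsv_versioned(fam$cnv, file.path(fdir, "cnv_counts.tsv"),
                            "cnv_bin_counts")
      write_truth_json(fam$truth, file.path(fdir, "truth.json"))
      say("simulate: wrote ", fam$family_id, " (",
          length(fam$embryos), " embryos)")
    }
    resolved <- config
    resolved$simulate <- cfg[setdiff(names(cfg), "locus")]
    yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
  }

  fam_dirs <- sort(list.dirs(out_dir, recursive = FALSE))
  fam_dirs <- fam_dirs[grepl("fam_", basename(fam_dirs))]
  locus <- if (file.exists(file.path(out_dir, "locus.bed")))
    read_locus(file.path(out_dir, "locus.bed"),
               file.path(out_dir, "locus.json"))
  else cfg$locus

  read_family_inputs <- function(fdir) {
    vcf <- file.path(fdir, "parents.vcf")
    if (!file.exists(vcf))
      stop("run_pipeline: missing parental VCF: ", vcf)
    list(parents = read_parental_vcf(vcf),
         snp_obs = read_tsv_versioned(file.path(fdir, "snp_obs.tsv")),
         mutation_obs = read_tsv_versioned(
           file.path(fdir, "mutation_obs.tsv")))
  }

  if ("phase" %in% stages) {
    pcfg <- config$phase %||% list()
    for (fdir in fam_dirs) {
      inp <- read_family_inputs(fdir)
      mut <- call_mutation_all(inp$mutation_obs, locus)
      affected <- identify_affected_embryos(mut)
      panel <- select_informative(inp$parents, locus,
                                  cfg$window_upstream_bp,
                                  cfg$window_downstream_bp)
      phase <- build_haplotypes(
        panel, affected, inp$snp_obs, locus = locus,
        min_flank_resolved = pcfg$min_flank_resolved %||% 2,
        min_cohort = pcfg$min_cohort %||% 3)
      write_phase_tsv(phase, file.path(fdir, "haplotypes.tsv"))
      jsonlite::write_json(list(affected = affected),
                           file.path(fdir, "affected.json"),
                           auto_unbox = FALSE)
      t <- phase$status_tally
      say("phase: ", basename(fdir), " informative=", nrow(phase$panel),
          " resolved=", t[["resolved"]],
          " ADO=", t[["unresolved_ADO"]],
          " conflict=", t[["conflict"]],
          " affected={", paste(affected, collapse = ","), "}")
    }
  }

  if ("genotype" %in% stages) {
    gcfg <- config$genotype %||% list()
    for (fdir in fam_dirs) {
      inp <- read_family_inputs(fdir)
      hap_path <- file.path(fdir, "haplotypes.tsv")
      if (!file.exists(hap_path))
        stop("run_pipeline: missing phased haplotypes: ", hap_path)
      phase <- read_phase_tsv(hap_path)
      mut <- call_mutation_all(inp$mutation_obs, locus)
      calls <- genotype_calls(inp$snp_obs)
      embryos <- unique(inp$snp_obs$sample)
      rows <- lapply(embryos, function(e) {
        ec <- calls[calls$sample == e, , drop = FALSE]
        mat <- assign_side(ec, phase, "maternal",
                           gcfg$min_flank_votes %||% 2,
                           gcfg$winner_frac %||% 0.8)
        pat <- assign_side(ec, phase, "paternal",
                           gcfg$min_flank_votes %||% 2,
                           gcfg$winner_frac %||% 0.8)
        cl <- classify_embryo(mat, pat, mut[[e]], embryo = e)
        data.frame(embryo = e,
                   maternal_assignment = cl$maternal_assignment,
                   paternal_assignment = cl$paternal_assignment,
                   direct_genotype = cl$direct_genotype,
                   direct_confidence = cl$direct_confidence,
                   final_status = cl$final_status,
                   flags = paste(cl$flags, collapse = ","),
                   stringsAsFactors = FALSE)
      })
      write_tsv_versioned(do.call(rbind, rows),
                          file.path(fdir, "calls.tsv"), "embryo_calls")
      say("genotype: ", basename(fdir), " called ", length(embryos),
          " embryos")
    }
  }

  if ("cnv" %in% stages) {
    for (fdir in fam_dirs) {
      cnv_path <- file.path(fdir, "cnv_counts.tsv")
      if (!file.exists(cnv_path))
        stop("run_pipeline: missing CNV bin counts: ", cnv_path)
      counts <- read_tsv_versioned(cnv_path)
      ref <- reference_profile(cfg$cnv_bin_size, cfg$n_fragments)
      rows <- lapply(unique(counts$sample), function(e) {
        prof <- counts[counts$sample == e,
                       c("chrom", "start", "end", "length", "count")]
        scr <- cnv_screen(prof, ref)
        data.frame(embryo = e, call = scr$call,
                   mosaic_fraction = scr$mosaic_fraction_estimate,
                   stringsAsFactors = FALSE)
      })
      write_tsv_versioned(do.call(rbind, rows),
                          file.path(fdir, "cnv_calls.tsv"), "cnv_calls")
      say("cnv: ", basename(fdir), " screened")
    }
  }

  report_path <- file.path(out_dir, "report.json")
  if ("report" %in% stages) {
    fam_rows <- lapply(fam_dirs, function(fdir) {
      calls <- read_tsv_versioned(file.path(fdir, "calls.tsv"))
      cnv <- read_tsv_versioned(file.path(fdir, "cnv_calls.tsv"))
      tr <- decide_transferable(calls, cnv)
      data.frame(
        family = basename(fdir),
        biopsied = nrow(calls),
        conclusive = sum(calls$final_status != "inconclusive"),
        affected = sum(calls$final_status == "affected"),
        unaffected = sum(calls$final_status %in% c("carrier", "noncarrier")),
        euploid = sum(cnv$call == "euploid"),
        mosaic = sum(grepl("mosaic", cnv$call)),
        transferable = sum(tr$transferable),
        stringsAsFactors = FALSE)
    })
    fam_df <- do.call(rbind, fam_rows)
    totals <- vapply(fam_df[-1], sum, 0)
    rep <- list(
      families = fam_df,
      totals = as.list(totals),
      rates = list(
        conclusive_pct = pct1(totals[["conclusive"]],
                              totals[["biopsied"]]),
        unaffected_pct = pct1(totals[["unaffected"]],
                              totals[["biopsied"]]),
        euploid_of_unaffected_pct = pct1(totals[["transferable"]],
                                         totals[["unaffected"]]),
        mosaic_pct = pct1(totals[["mosaic"]], totals[["biopsied"]])))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    md <- c("# PGT cohort report",
            "",
            sprintf("- families: %d", nrow(fam_df)),
            sprintf("- biopsied embryos: %d", totals[["biopsied"]]),
            sprintf("- conclusive: %d (%.1f%%)", totals[["conclusive"]],
                    rep$rates$conclusive_pct),
            sprintf("- unaffected: %d (%.1f%%)", totals[["unaffected"]],
                    rep$rates$unaffected_pct),
            sprintf("- transferable (unaffected + euploid): %d",
                    totals[["transferable"]]))
    writeLines(md, file.path(out_dir, "report.md"))
    say("report: ", report_path)
    return(invisible(report_path))
  }
  invisible(out_dir)
}
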