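#' Assign one parental side of an embryo by linkage voting
#'
#' Every resolved informative site of the requested side casts a vote:
#' the embryo's genotype call, minus the obligate allele of the
#' homozygous parent, reveals which allele the heterozygous parent
#' transmitted; the site votes H0 if that allele matches the disease
#' haplotype and H1 otherwise. Observations that cannot disambiguate
#' (no-call, suspected dropout of the informative allele) abstain. An
#' assignment requires at least `min_flank_votes` concordant upstream
#' and downstream votes for the winner and a winner fraction of at
#' least `winner_frac` among non-abstaining votes; otherwise the side
#' is `inconclusive`.
#'
#' A single positional changepoint in the vote sequence (one block of
#' H0 then one block of H1, both of length >= 2, ordered by coordinate)
#' is treated as a suspected crossover: votes between the changepoint
#' and the gene, together with the whole opposite flank, are re-scored
#' under the same minima, and the side stays inconclusive if the
#' changepoint straddles the gene itself or the reduced marker set no
#' longer meets the minima.
#'
#' @param embryo_calls Genotype-call rows ([genotype_calls()]) for one
#'   embryo.
#' @param phase A `pgt_phase` from [build_haplotypes()].
#' @param side `"maternal"` or `"paternal"`.
#' @param min_flank_votes Minimum concordant winner votes per flank
#'   (default 2).
#' @param winner_frac Minimum winner share of non-abstaining votes
#'   (default 0.8, so one corrupted vote cannot flip a well-supported
#'   assignment).
#' @return List with `assignment` (`"H0"`, `"H1"`, `"inconclusive"`),
#'   `support` (vote counts split by flank), `flags` (character vector,
#'   e.g. `"recombination_suspected"`), and `votes` (per-site detail).
#' @export
assign_side <- function(embryo_calls, phase, side = c("maternal", "paternal"),
                        min_flank_votes = 2, winner_frac = 0.8) {
  side <- match.arg(side)
  pan <- phase$panel
  pan <- pan[pan$side == side & pan$status == "resolved", , drop = FALSE]
  if (nrow(pan) == 0)
    return(list(assignment = "inconclusive",
                support = empty_support(), flags = character(),
                votes = NULL))
  rows <- embryo_calls[match(pan$pos, embryo_calls$pos), , drop = FALSE]
  m <- transmitted_allele(pan$het_a1, pan$het_a2, pan$hom_allele,
                          !is.na(rows$called) & rows$called,
                          rows$allele1, rows$allele2,
                          !is.na(rows$dropout_suspected) &
                            rows$dropout_suspected)
  vote <- ifelse(is.na(m) | m == "conflict", NA_character_,
                 ifelse(m == pan$hap0_allele, "H0", "H1"))
  votes <- data.frame(pos = pan$pos, location = pan$location, vote = vote,
                      stringsAsFactors = FALSE)
  votes <- votes[!is.na(votes$vote), , drop = FALSE]
  votes <- votes[order(votes$pos), , drop = FALSE]
  flags <- character()

  decide <- function(v) {
    if (nrow(v) == 0) return(NULL)
    tab <- support_table(v)
    winner <- if (sum(v$vote == "H0") >= sum(v$vote == "H1")) "H0" else "H1"
    frac <- sum(v$vote == winner) / nrow(v)
    ok <- tab[winner, "upstream"] >= min_flank_votes &&
      tab[winner, "downstream"] >= min_flank_votes &&
      frac >= winner_frac
    if (ok) winner else NULL
  }

  r <- rle(votes$vote)
  if (length(r$lengths) == 2 && all(r$lengths >= 2)) {
    flags <- "recombination_suspected"
    cut <- r$lengths[1]
    if (votes$location[cut] == votes$location[cut + 1]) {
      # crossover inside one flank: keep the gene-proximal run of that
      # flank plus the whole opposite flank
      keep <- if (votes$location[cut] == "upstream")
        seq(cut + 1, nrow(votes)) else seq_len(cut)
      win <- decide(votes[keep, , drop = FALSE])
      return(list(assignment = win %||% "inconclusive",
                  support = support_table(votes), flags = flags,
                  votes = votes))
    }
    # changepoint straddles the gene: transmitted haplotype at the
    # locus cannot be determined
    return(list(assignment = "inconclusive",
                support = support_table(votes), flags = flags,
                votes = votes))
  }
  win <- decide(votes)
  list(assignment = win %||% "inconclusive",
       support = support_table(votes), flags = flags, votes = votes)
}

support_table <- function(votes) {
  tab <- table(factor(votes$vote, c("H0", "H1")),
               factor(votes$location, c("upstream", "downstream")))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("H0", "H1"), c("upstream", "downstream")))
  m
}

empty_support <- function() {
  matrix(0L, 2, 2, dimnames = list(c("H0", "H1"),
                                   c("upstream", "downstream")))
}

#' Combine the two side assignments with the direct mutation call
#'
#' Two disease haplotypes give an affected embryo, one a carrier, none a
#' noncarrier. The direct mutation call cross-validates the linkage
#' result: agreement passes; an ambiguous or low-depth direct call lets
#' the linkage result stand with an `ADO_at_mutation_site` flag; a hard
#' contradiction between a passing direct call and a conclusive linkage
#' result makes the embryo `inconclusive` with a
#' `discordant_direct_vs_linkage` flag.
#'
#' @param maternal,paternal Results of [assign_side()].
#' @param direct_call Optional `depth_call` at the mutation locus.
#' @param embryo Embryo label carried into the result.
#' @return List of class `embryo_call`: `embryo`, the two assignments
#'   with support, `direct_genotype`, `direct_confidence`,
#'   `final_status`
#'   (`affected`/`carrier`/`noncarrier`/`inconclusive`), `flags`.
#' @export
classify_embryo <- function(maternal, paternal, direct_call = NULL,
                            embryo = NA_character_) {
  flags <- union(maternal$flags, paternal$flags)
  conclusive <- maternal$assignment != "inconclusive" &&
    paternal$assignment != "inconclusive"
  if (!conclusive) {
    status <- "inconclusive"
  } else {
    n_h0 <- (maternal$assignment == "H0") + (paternal$assignment == "H0")
    status <- c("noncarrier", "carrier", "affected")[n_h0 + 1]
    if (!is.null(direct_call)) {
      if (direct_call$confidence != "pass" || is.na(direct_call$genotype)) {
        flags <- union(flags, "ADO_at_mutation_site")
      } else if (direct_call$genotype != n_h0) {
        status <- "inconclusive"
        flags <- union(flags, "discordant_direct_vs_linkage")
      }
    }
  }
  structure(list(embryo = embryo,
                 maternal_assignment = maternal$assignment,
                 paternal_assignment = paternal$assignment,
                 maternal_support = maternal$support,
                 paternal_support = paternal$support,
                 direct_genotype = if (is.null(direct_call)) NA_integer_
                                   else direct_call$genotype,
                 direct_confidence = if (is.null(direct_call)) NA_character_
                                     else direct_call$confidence,
                 final_status = status, flags = flags),
            class = "embryo_call")
}

#' @export
print.embryo_call <- function(x, ...) {
  cat(sprintf("<embryo_call> %s: maternal %s, paternal %s -> %s%s\n",
              x$embryo, x$maternal_assignment, x$paternal_assignment,
              x$final_status,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Phase and genotype every embryo of a family
#'
#' End-to-end monogenic workup of one family: direct mutation calls,
#' affected-embryo identification, informative-SNP selection, haplotype
#' phasing, and per-embryo linkage classification.
#'
#' @param family A `pgt_family` from [simulate_family()], or a list with
#'   the same `parents`, `snp_obs`, `mutation_obs`, `locus`, `embryos`
#'   and `config` elements.
#' @param min_flank_votes,winner_frac Voting thresholds
#'   ([assign_side()]).
#' @param ... Tuning for [genotype_calls()].
#' @return List with `phase` (the `pgt_phase`), `affected`,
#'   `mutation_calls`, and `calls` — a data frame with one row per
#'   embryo: assignments, direct genotype/confidence, `final_status`,
#'   comma-joined `flags`.
#' @export
genotype_family <- function(family, min_flank_votes = 2, winner_frac = 0.8,
                            ...) {
  mut_calls <- call_mutation_all(family$mutation_obs, family$locus,
                                 family$embryos)
  affected <- identify_affected_embryos(mut_calls)
  panel <- select_informative(family$parents, family$locus,
                              family$config$window_upstream_bp,
                              family$config$window_downstream_bp)
  phase <- build_haplotypes(panel, affected, family$snp_obs,
                            locus = family$locus,
                            n_embryos = length(family$embryos), ...)
  all_calls <- genotype_calls(family$snp_obs, ...)
  rows <- lapply(family$embryos, function(e) {
    ec <- all_calls[all_calls$sample == e, , drop = FALSE]
    mat <- assign_side(ec, phase, "maternal", min_flank_votes, winner_frac)
    pat <- assign_side(ec, phase, "paternal", min_flank_votes, winner_frac)
    cl <- classify_embryo(mat, pat, mut_calls[[e]], embryo = e)
    data.frame(embryo = e,
               maternal_assignment = cl$maternal_assignment,
               paternal_assignment = cl$paternal_assignment,
               direct_genotype = cl$direct_genotype,
               direct_confidence = cl$direct_confidence,
               final_status = cl$final_status,
               flags = paste(cl$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  list(phase = phase, affected = affected, mutation_calls = mut_calls,
       calls = do.call(rbind, rows))
}

#' Estimate WGA amplification and allele-dropout rates
#'
#' The amplification rate is the fraction of attempted embryo-site calls
#' that yielded reads; the ADO rate is the fraction of amplified
#' obligate-heterozygous sites (both parents homozygous for different
#' alleles, forcing a heterozygous embryo) observed with a single
#' allele.
#'
#' @param observations Long allele-depth table for the embryos.
#' @param parents Parental genotype table covering the same sites.
#' @param min_reads Minimum total reads for a site to count as amplified
#'   (default 5); an allele counts as observed at >= 2 reads.
#' @return List with `amplification_rate`, `ado_rate`, `n_attempted`,
#'   `n_obligate_het`.
#' @export
estimate_wga_metrics <- function(observations, parents, min_reads = 5) {
  total <- observations$ref_depth + observations$alt_depth
  amplified <- total >= min_reads
  n_att <- length(total)
  if (n_att == 0) stop("estimate_wga_metrics: no observations")
  pg <- parents[match(observations$pos, parents$pos), ]
  m <- split_gt(pg$mother); f <- split_gt(pg$father)
  m1 <- vapply(m, `[`, "", 1L); m2 <- vapply(m, `[`, "", 2L)
  f1 <- vapply(f, `[`, "", 1L); f2 <- vapply(f, `[`, "", 2L)
  obligate <- !is.na(m1) & !is.na(f1) & m1 == m2 & f1 == f2 & m1 != f1
  ob_amp <- obligate & amplified
  if (!any(ob_amp))
    stop("estimate_wga_metrics: no amplified obligate-heterozygous sites; ",
         "ADO rate undefined")
  single <- (observations$ref_depth >= 2) + (observations$alt_depth >= 2) == 1L
  list(amplification_rate = mean(amplified),
       ado_rate = sum(single & ob_amp) / sum(ob_amp),
       n_attempted = n_att,
       n_obligate_het = sum(ob_amp))
}
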