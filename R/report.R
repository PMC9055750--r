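#' Load the per-family study outcomes table
#'
#' Reads the packaged per-family outcome fixture (one row per carrier
#' couple: cycle counts, the oocyte-to-blastocyst funnel, diagnosis and
#' pregnancy outcomes) or a user table with the same columns, and
#' checks the funnel invariants (`biopsied >= unaffected >=
#' transferable`, non-increasing oocyte-to-blastocyst counts).
#'
#' @param path Path to a TSV; default, the packaged fixture.
#' @return Data frame of family outcomes.
#' @export
family_outcomes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_families.tsv",
                        package = "embryophase")
  out <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  funnel <- c("oocytes", "mii", "fertilized_2pn", "cleavage", "blastocysts",
              "biopsied", "unaffected", "transferable")
  for (i in seq_len(length(funnel) - 1)) {
    bad <- out[[funnel[i]]] < out[[funnel[i + 1]]]
    if (any(bad))
      warning("family_outcomes: funnel violation (", funnel[i], " < ",
              funnel[i + 1], ") in family ",
              paste(out$family[bad], collapse = ", "))
  }
  out
}

#' Decide which embryos are transferable
#'
#' Transferable means unaffected by the monogenic disease (carrier or
#' noncarrier) AND euploid; mosaic embryos are not transferred.
#'
#' @param embryo_calls Data frame with `embryo` and `final_status`
#'   (from [genotype_family()]).
#' @param cnv_calls Data frame with `embryo` and `call` (embryo-level
#'   [cnv_screen()] calls).
#' @return Data frame `embryo`, `final_status`, `cnv_call`,
#'   `transferable`; embryos missing either call are excluded and
#'   counted in the `"excluded"` attribute.
#' @export
decide_transferable <- function(embryo_calls, cnv_calls) {
  merged <- merge(embryo_calls[, c("embryo", "final_status")],
                  cnv_calls[, c("embryo", "call")],
                  by = "embryo", all = TRUE)
  names(merged)[names(merged) == "call"] <- "cnv_call"
  excluded <- merged[is.na(merged$final_status) | is.na(merged$cnv_call), ]
  if (nrow(excluded) > 0)
    message("decide_transferable: ", nrow(excluded),
            " embryo(s) missing a call, excluded: ",
            paste(excluded$embryo, collapse = ", "))
  merged <- merged[!is.na(merged$final_status) & !is.na(merged$cnv_call), ]
  merged$transferable <- merged$final_status %in% c("carrier", "noncarrier") &
    merged$cnv_call == "euploid"
  attr(merged, "excluded") <- nrow(excluded)
  merged
}

pct1 <- function(num, den) {
  if (is.na(den) || den == 0) return(NA_real_)
  round(100 * num / den, 1)
}

#' Aggregate a cohort of family outcomes
#'
#' Sums the per-family columns and derives the study's descriptive
#' rates: unaffected fraction of biopsied embryos, euploid fraction of
#' unaffected embryos (= transferable), mean biopsied blastocysts and
#' mean transferable embryos per couple, and clinical-pregnancy /
#' live-birth rates per FET cycle. Every rate is computed from its
#' summed numerator and denominator (percentages and means to one
#' decimal); zero denominators report `NA` and are listed in
#' `undefined`.
#'
#' @param outcomes Data frame as returned by [family_outcomes()].
#' @return List of class `pgt_cohort_summary`: `n_families`, `totals`,
#'   `rates`, `means`, `undefined`.
#' @export
summarize_cohort <- function(outcomes) {
  if (nrow(outcomes) < 1) stop("summarize_cohort: no families")
  num_cols <- c("pgt_cycles", "fet_cycles", "oocytes", "mii",
                "fertilized_2pn", "cleavage", "blastocysts", "biopsied",
                "unaffected", "transferable", "clinical_pregnancy",
                "live_birth_cycles", "live_birth_babies")
  num_cols <- intersect(num_cols, names(outcomes))
  totals <- vapply(outcomes[num_cols], sum, 0)
  n_fam <- nrow(outcomes)
  rates <- list(
    unaffected_pct = pct1(totals[["unaffected"]], totals[["biopsied"]]),
    euploid_of_unaffected_pct = pct1(totals[["transferable"]],
                                     totals[["unaffected"]]),
    clinical_pregnancy_per_fet_pct = pct1(totals[["clinical_pregnancy"]],
                                          totals[["fet_cycles"]]),
    live_birth_per_fet_pct = pct1(totals[["live_birth_babies"]],
                                  totals[["fet_cycles"]]))
  means <- list(
    biopsied_per_couple = round(totals[["biopsied"]] / n_fam, 1),
    transferable_per_couple = round(totals[["transferable"]] / n_fam, 1))
  undefined <- names(rates)[vapply(rates, is.na, TRUE)]
  structure(list(n_families = n_fam, totals = totals, rates = rates,
                 means = means, undefined = undefined),
            class = "pgt_cohort_summary")
}

#' @export
print.pgt_cohort_summary <- function(x, ...) {
  cat(sprintf("<pgt_cohort_summary> %d families\n", x$n_families))
  cat(sprintf("  biopsied %d, unaffected %d (%.1f%%), transferable %d (%.1f%% of unaffected)\n",
              x$totals[["biopsied"]], x$totals[["unaffected"]],
              x$rates$unaffected_pct, x$totals[["transferable"]],
              x$rates$euploid_of_unaffected_pct))
  cat(sprintf("  per couple: %.1f biopsied, %.1f transferable\n",
              x$means$biopsied_per_couple, x$means$transferable_per_couple))
  cat(sprintf("  per FET cycle: clinical pregnancy %.1f%%, live birth %.1f%%\n",
              x$rates$clinical_pregnancy_per_fet_pct,
              x$rates$live_birth_per_fet_pct))
  if (length(x$undefined))
    cat("  undefined rates:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Probability that no embryo in a cohort is affected
#'
#' For two carrier parents each embryo is independently affected with
#' probability 1/4, so a cohort of `n` embryos contains no affected
#' embryo — and therefore no phasing reference — with probability
#' `(3/4)^n` (about 10% even with 8 embryos). Used for pre-cycle
#' counselling.
#'
#' @param n_embryos Non-negative integer count(s).
#' @return `(3/4)^n_embryos`.
#' @export
p_none_affected <- function(n_embryos) {
  if (any(is.na(n_embryos)) || any(n_embryos < 0) ||
      any(n_embryos != round(n_embryos)))
    stop("p_none_affected: 'n_embryos' must be a non-negative integer")
  (3 / 4)^n_embryos
}
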