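#' Deduce the disease-haplotype allele at one informative SNP
#'
#' For a maternal-informative site (mother heterozygous a1/a2, father
#' homozygous b/b), each affected embryo's genotype call, minus the
#' obligate paternal b, leaves the maternal allele riding the disease
#' haplotype (M0). Observations that cannot disambiguate — a no-call, or
#' a suspected-dropout observation showing only the obligate allele —
#' yield `unresolved_ADO`; Mendelian-impossible observations, or
#' disagreement among affected embryos, yield `conflict` (strict
#' unanimity: a conflicted site is withheld from voting entirely).
#'
#' @param snp One-row informative panel entry (see
#'   [select_informative()]).
#' @param affected_calls Genotype-call rows ([genotype_calls()]) of the
#'   affected embryos at that site.
#' @return List with `status`
#'   (`"resolved"`/`"unresolved_ADO"`/`"conflict"`) and `allele` (the
#'   disease-haplotype allele of the heterozygous parent, or `NA`).
#' @export
deduce_site_phase <- function(snp, affected_calls) {
  if (nrow(affected_calls) == 0)
    stop("deduce_site_phase: phasing reference unavailable ",
         "(no affected embryos supplied)")
  m <- transmitted_allele(
    rep(snp$het_a1, nrow(affected_calls)),
    rep(snp$het_a2, nrow(affected_calls)),
    rep(snp$hom_allele, nrow(affected_calls)),
    affected_calls$called, affected_calls$allele1, affected_calls$allele2,
    affected_calls$dropout_suspected)
  if (any(m == "conflict", na.rm = TRUE))
    return(list(status = "conflict", allele = NA_character_))
  vals <- unique(m[!is.na(m)])
  if (length(vals) == 0) list(status = "unresolved_ADO",
                              allele = NA_character_)
  else if (length(vals) == 1) list(status = "resolved", allele = vals)
  else list(status = "conflict", allele = NA_character_)
}

#' Phase the parental disease haplotypes from affected embryos
#'
#' Applies [deduce_site_phase()] at every informative SNP, using the
#' embryos called homozygous-affected by direct mutation detection as
#' the linkage reference (the proband substitute). At resolved sites the
#' haplotype-0 allele is the deduced disease-linked allele and
#' haplotype 1 carries the complementary allele of the heterozygous
#' parent; index 0 is disease-associated by construction (the M0/F0
#' convention).
#'
#' Sites inside a large deletion cannot be read in homozygous-affected
#' embryos and are excluded from phasing when the locus is a deletion
#' (set `include_intragenic` to override; intragenic sites are kept for
#' small indels).
#'
#' @param panel Informative panel from [select_informative()].
#' @param affected Character vector of affected embryo labels
#'   ([identify_affected_embryos()]).
#' @param observations Long allele-depth table covering the affected
#'   embryos.
#' @param locus Optional [mutation_locus()] controlling the intragenic
#'   default.
#' @param include_intragenic Keep intragenic sites? Defaults to `FALSE`
#'   for large deletions, `TRUE` otherwise.
#' @param min_flank_resolved Minimum resolved markers required upstream
#'   and downstream on each side (default 2, the "at least two upstream
#'   and two downstream markers" rule); failing either flank on either
#'   side aborts with an error naming the deficient cell.
#' @param min_cohort Minimum number of biopsied embryos before phasing
#'   is attempted (default 3, mirroring clinical practice of deferring
#'   NGS for two-blastocyst cycles); pass the cohort size via
#'   `n_embryos` when it differs from the samples present in
#'   `observations`.
#' @param n_embryos Cohort size used for the `min_cohort` check.
#' @param ... Tuning for [genotype_calls()].
#' @return Object of class `pgt_phase`: `panel` (the informative panel
#'   with `hap0_allele`, `hap1_allele`, `status`), `n_affected_used`,
#'   and `counts` (resolved-site tallies by side and location).
#' @export
build_haplotypes <- function(panel, affected, observations, locus = NULL,
                             include_intragenic = NULL,
                             min_flank_resolved = 2,
                             min_cohort = 3, n_embryos = NULL, ...) {
  if (length(affected) == 0)
    stop("build_haplotypes: phasing reference unavailable ",
         "(no affected embryos)")
  if (nrow(panel) == 0)
    stop("build_haplotypes: empty informative panel")
  if (is.null(n_embryos))
    n_embryos <- length(unique(observations$sample))
  if (n_embryos < min_cohort)
    stop("build_haplotypes: cohort of ", n_embryos,
         " embryos is below the phasing minimum of ", min_cohort)
  if (is.null(include_intragenic))
    include_intragenic <- is.null(locus) || locus$kind != "large_deletion"
  if (!include_intragenic)
    panel <- panel[panel$location != "intragenic", ]

  calls <- genotype_calls(
    observations[observations$sample %in% affected, ], ...)
  key <- paste(calls$pos, calls$sample)

  status <- character(nrow(panel))
  hap0 <- character(nrow(panel))
  for (i in seq_len(nrow(panel))) {
    rows <- calls[calls$pos == panel$pos[i], , drop = FALSE]
    if (nrow(rows) == 0) {
      status[i] <- "unresolved_ADO"
      hap0[i] <- NA_character_
      next
    }
    d <- deduce_site_phase(panel[i, ], rows)
    status[i] <- d$status
    hap0[i] <- d$allele
  }
  panel$hap0_allele <- hap0
  panel$hap1_allele <- ifelse(status == "resolved",
                              ifelse(hap0 == panel$het_a1, panel$het_a2,
                                     panel$het_a1),
                              NA_character_)
  panel$status <- status

  res <- panel[panel$status == "resolved", ]
  counts <- table(side = factor(res$side, c("maternal", "paternal")),
                  location = factor(res$location,
                                    c("upstream", "downstream")))
  for (s in rownames(counts)) for (l in colnames(counts)) {
    if (counts[s, l] < min_flank_resolved)
      stop(sprintf(
        "build_haplotypes: only %d resolved %s %s marker(s); need >= %d",
        counts[s, l], s, l, min_flank_resolved))
  }
  structure(list(panel = panel,
                 n_affected_used = length(affected),
                 counts = counts,
                 status_tally = table(factor(status,
                   c("resolved", "unresolved_ADO", "conflict")))),
            class = "pgt_phase")
}

#' @export
print.pgt_phase <- function(x, ...) {
  t <- x$status_tally
  cat(sprintf(
    "<pgt_phase> %d sites: %d resolved, %d unresolved (ADO), %d conflict; %d affected embryo(s) used\n",
    nrow(x$panel), t[["resolved"]], t[["unresolved_ADO"]], t[["conflict"]],
    x$n_affected_used))
  print(x$counts)
  invisible(x)
}

#' Brute-force phasing oracle (test support)
#'
#' Independently of the per-site subtraction rule, enumerates for each
#' parent both assignments of their two true haplotypes to
#' disease/normal status, scores every assignment by the number of
#' affected-embryo genotype observations consistent with it (an
#' observation is consistent when its observed alleles are a subset of
#' the predicted affected genotype, allowing dropout), and returns the
#' top-scoring assignment per side. A tie is declared ambiguous. Needs
#' the simulator's true parental diplotypes, so it serves only as a
#' verification oracle in tests.
#'
#' @param truth The `truth` element of a [simulate_family()] result.
#' @param panel Informative panel from [select_informative()].
#' @param affected Affected embryo labels.
#' @param observations Long allele-depth table.
#' @param ... Tuning for [genotype_calls()].
#' @return List with elements `maternal` and `paternal`, each
#'   `list(ambiguous, hap0)` where `hap0` is the implied disease
#'   haplotype allele per informative site of that side (named by
#'   position).
#' @export
phase_oracle <- function(truth, panel, affected, observations, ...) {
  if (length(affected) == 0)
    stop("phase_oracle: phasing reference unavailable")
  calls <- genotype_calls(
    observations[observations$sample %in% affected, ], ...)
  site_of <- match(panel$pos, truth$sites$pos)

  score_side <- function(side) {
    sub <- panel[panel$side == side, ]
    idx <- site_of[panel$side == side]
    haps <- if (side == "maternal") truth$maternal_haps else
      truth$paternal_haps
    scores <- vapply(1:2, function(h) {
      total <- 0L
      for (k in seq_len(nrow(sub))) {
        predicted <- c(haps[h, idx[k]], sub$hom_allele[k])
        rows <- calls[calls$pos == sub$pos[k] & calls$called, , drop = FALSE]
        if (nrow(rows) == 0) next
        obs_ok <- rows$allele1 %in% predicted & rows$allele2 %in% predicted
        total <- total + sum(obs_ok)
      }
      total
    }, integer(1))
    if (scores[1] == scores[2])
      list(ambiguous = TRUE, hap0 = NULL)
    else {
      best <- which.max(scores)
      list(ambiguous = FALSE,
           hap0 = stats::setNames(haps[best, idx], sub$pos))
    }
  }
  list(maternal = score_side("maternal"), paternal = score_side("paternal"))
}
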