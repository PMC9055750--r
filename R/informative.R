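split_gt <- function(gt) strsplit(gt, "/", fixed = TRUE)

#' Select informative SNPs for single-side linkage phasing
#'
#' An informative SNP is heterozygous in exactly one parent and
#' homozygous in the other, so the transmitted allele of the heterozygous
#' parent can be read off an embryo genotype after subtracting the
#' obligate allele of the homozygous parent. Sites heterozygous in both
#' parents, homozygous in both, outside the configured windows, with a
#' missing parental genotype, or carrying alleles beyond the site's
#' ref/alt pair (multi-allelic) are excluded; exclusion counts are
#' attached as the `"excluded"` attribute.
#'
#' @param parents Genotype table with columns `chrom`, `pos`, `ref`,
#'   `alt`, `mother`, `father` (genotypes as `"A/C"` strings; `NA` or
#'   `"./."` for missing).
#' @param locus A [mutation_locus()] on the same contig.
#' @param window_upstream_bp,window_downstream_bp Window widths below the
#'   region start / above the region end (forward-strand coordinates).
#' @return Data frame of class `informative_panel`: `chrom`, `pos`,
#'   `ref`, `alt`, `side` (`"maternal"`/`"paternal"`), `het_a1`,
#'   `het_a2` (the heterozygous parent's alleles), `hom_allele` (the
#'   other parent's obligate allele), `location` (`"upstream"`,
#'   `"downstream"`, `"intragenic"`).
#' @export
select_informative <- function(parents, locus,
                               window_upstream_bp = 1e6,
                               window_downstream_bp = 2e6) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "mother", "father") %in%
                  names(parents)))
  if (nrow(parents) > 0 && !all(parents$chrom == locus$chrom))
    stop("select_informative: sites must be on the locus contig ",
         locus$chrom)
  m <- split_gt(parents$mother)
  f <- split_gt(parents$father)
  ok_pair <- function(g) lengths(g) == 2L & !vapply(g, anyNA, TRUE)
  missing <- is.na(parents$mother) | is.na(parents$father) |
    !ok_pair(m) | !ok_pair(f) |
    vapply(m, function(x) any(x == "."), TRUE) |
    vapply(f, function(x) any(x == "."), TRUE)
  site_alleles <- Map(c, parents$ref, parents$alt)
  multi <- !missing & !mapply(function(gm, gf, al) all(c(gm, gf) %in% al),
                              m, f, site_alleles)
  a1 <- function(g) vapply(g, `[`, "", 1L)
  a2 <- function(g) vapply(g, `[`, "", 2L)
  m_het <- a1(m) != a2(m)
  f_het <- a1(f) != a2(f)
  loc <- locus_location(parents$pos, locus)
  in_window <- (loc == "upstream" &
                  parents$pos >= locus$start - window_upstream_bp) |
    (loc == "downstream" & parents$pos <= locus$end + window_downstream_bp) |
    loc == "intragenic"
  informative <- !missing & !multi & xor(m_het, f_het) & in_window
  out_window <- !missing & !multi & xor(m_het, f_het) & !in_window

  idx <- which(informative)
  side <- ifelse(m_het[idx], "maternal", "paternal")
  het <- as.character(ifelse(m_het[idx], parents$mother[idx],
                             parents$father[idx]))
  hom <- as.character(ifelse(m_het[idx], parents$father[idx],
                             parents$mother[idx]))
  hg <- split_gt(het)
  out <- data.frame(
    chrom = parents$chrom[idx], pos = parents$pos[idx],
    ref = parents$ref[idx], alt = parents$alt[idx],
    side = side, het_a1 = a1(hg), het_a2 = a2(hg),
    hom_allele = a1(split_gt(hom)), location = loc[idx],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- c(missing = sum(missing),
                             multiallelic = sum(multi),
                             uninformative = sum(!missing & !multi &
                                                   !xor(m_het, f_het)),
                             outside_window = sum(out_window))
  class(out) <- c("informative_panel", "data.frame")
  out
}

#' Tally informative SNPs by side and location
#'
#' @param panel An `informative_panel` from [select_informative()].
#' @return Integer table `{maternal, paternal}` x
#'   `{upstream, downstream, intragenic}`; cells sum to `nrow(panel)`.
#' @export
count_by_side_and_location <- function(panel) {
  table(side = factor(panel$side, c("maternal", "paternal")),
        location = factor(panel$location,
                          c("upstream", "downstream", "intragenic")))
}
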