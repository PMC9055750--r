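depth_call <- function(genotype, in_depth = NA_real_, flank_depth = NA_real_,
                       ratio = NA_real_, confidence = "pass") {
  structure(list(genotype = genotype, in_region_mean_depth = in_depth,
                 flank_mean_depth = flank_depth, ratio = ratio,
                 confidence = confidence),
            class = "depth_call")
}

#' @export
print.depth_call <- function(x, ...) {
  cat(sprintf("<depth_call> %s disease allele(s), ratio %.3f (%s)\n",
              ifelse(is.na(x$genotype), "?", x$genotype),
              x$ratio, x$confidence))
  invisible(x)
}

#' Genotype a large deletion from read-depth collapse
#'
#' A homozygous SEA-type deletion fails to amplify, so the mean depth
#' over the deleted region collapses relative to the flanking baseline.
#' The in-region / flank depth ratio is banded into copy states:
#' below `t_hom` two disease alleles, within `t_het` one, above `t_wt`
#' none; ratios between bands are `ambiguous`. The bands are this
#' module's reconstruction ("very low read counts" is the only published
#' guidance) and are configurable.
#'
#' @param mutation_obs Depth-profile table with columns `sample`, `pos`,
#'   `location` (`"region"`/`"flank"`), `ref_depth`, `alt_depth`.
#' @param embryo Sample label to call.
#' @param locus A [mutation_locus()] of kind `"large_deletion"`.
#' @param t_hom Ratio below which the embryo is called homozygous for
#'   the deletion (default 0.10).
#' @param t_het Length-2 heterozygote band (default 0.30-0.70).
#' @param t_wt Ratio above which the embryo is called deletion-free.
#' @param min_flank_depth Flank mean below which confidence is
#'   `low_depth` (default 30, the panel's design depth).
#' @return A `depth_call`: `genotype` (0/1/2 disease alleles, `NA` when
#'   ambiguous), depths, `ratio`, `confidence`
#'   (`pass`/`low_depth`/`ambiguous`).
#' @export
call_deletion_state <- function(mutation_obs, embryo, locus,
                                t_hom = 0.10, t_het = c(0.30, 0.70),
                                t_wt = 0.80, min_flank_depth = 30) {
  if (locus$kind != "large_deletion")
    stop("call_deletion_state: locus '", locus$name,
         "' is not a large deletion")
  rows <- mutation_obs[mutation_obs$sample == embryo, ]
  depth <- rows$ref_depth + rows$alt_depth
  in_d <- depth[rows$location == "region"]
  fl_d <- depth[rows$location == "flank"]
  if (length(in_d) == 0 || length(fl_d) == 0)
    stop("call_deletion_state: no region or flank sites for locus '",
         locus$name, "'")
  if (length(fl_d) < 5)
    stop("call_deletion_state: need >= 5 flank sites for locus '",
         locus$name, "'")
  in_mean <- mean(in_d)
  fl_mean <- mean(fl_d)
  ratio <- if (fl_mean > 0) in_mean / fl_mean else NA_real_
  if (is.na(ratio) || fl_mean < min_flank_depth)
    return(depth_call(NA_integer_, in_mean, fl_mean, ratio, "low_depth"))
  g <- if (ratio < t_hom) 2L
  else if (ratio >= t_het[1] && ratio <= t_het[2]) 1L
  else if (ratio > t_wt) 0L
  else NA_integer_
  depth_call(g, in_mean, fl_mean, ratio,
             if (is.na(g)) "ambiguous" else "pass")
}

#' Genotype a small indel from allele read counts
#'
#' The mutant-allele read fraction at the variant site is banded into
#' genotypes: at least `hom_frac` mutant reads is homozygous (2 disease
#' alleles), within `het_band` heterozygous, at most `1 - hom_frac`
#' deletion-free; fractions between bands are `ambiguous`, and sites
#' under `min_depth` total reads are `low_depth`.
#'
#' @param mutation_obs Depth table as in [call_deletion_state()]; the
#'   `"region"` row for the embryo carries `ref_depth` (reference
#'   allele) and `alt_depth` (deletion allele) at the mutation site.
#' @param embryo Sample label to call.
#' @param locus A [mutation_locus()] of kind `"small_indel"`.
#' @param min_depth Minimum total reads (default 30, the panel design
#'   depth).
#' @param het_band Heterozygote band on the mutant fraction.
#' @param hom_frac Homozygote threshold on the mutant fraction.
#' @return A `depth_call` (ratio slot holds the mutant read fraction).
#' @export
call_indel_genotype <- function(mutation_obs, embryo, locus,
                                min_depth = 30, het_band = c(0.25, 0.75),
                                hom_frac = 0.90) {
  if (locus$kind != "small_indel")
    stop("call_indel_genotype: locus '", locus$name,
         "' is not a small indel")
  row <- mutation_obs[mutation_obs$sample == embryo &
                        mutation_obs$location == "region", ]
  if (nrow(row) == 0)
    stop("call_indel_genotype: no allele counts at locus '", locus$name,
         "' for embryo ", embryo)
  ref_d <- sum(row$ref_depth)
  alt_d <- sum(row$alt_depth)
  total <- ref_d + alt_d
  if (total < min_depth)
    return(depth_call(NA_integer_, total, NA_real_, NA_real_, "low_depth"))
  frac <- alt_d / total
  g <- if (frac >= hom_frac) 2L
  else if (frac >= het_band[1] && frac <= het_band[2]) 1L
  else if (frac <= 1 - hom_frac) 0L
  else NA_integer_
  depth_call(g, total, NA_real_, frac, if (is.na(g)) "ambiguous" else "pass")
}

#' Direct mutation call for every embryo of a family
#'
#' Dispatches on the locus kind ([call_deletion_state()] or
#' [call_indel_genotype()]).
#'
#' @param mutation_obs Family depth-profile table.
#' @param locus A [mutation_locus()].
#' @param embryos Embryo labels; default, all samples in the table.
#' @param ... Passed to the kind-specific caller.
#' @return Named list of `depth_call`s.
#' @export
call_mutation_all <- function(mutation_obs, locus, embryos = NULL, ...) {
  if (is.null(embryos)) embryos <- unique(mutation_obs$sample)
  fn <- if (locus$kind == "large_deletion") call_deletion_state
  else call_indel_genotype
  stats::setNames(lapply(embryos, function(e)
    fn(mutation_obs, e, locus, ...)), embryos)
}

#' Identify the affected embryos used as the phasing reference
#'
#' @param calls Named list of `depth_call`s (one per embryo).
#' @return Character vector of embryo labels called homozygous for the
#'   disease allele with passing confidence; may be empty.
#' @export
identify_affected_embryos <- function(calls) {
  hit <- vapply(calls, function(cl)
    !is.na(cl$genotype) && cl$genotype == 2L && cl$confidence == "pass",
    TRUE)
  names(calls)[hit]
}
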