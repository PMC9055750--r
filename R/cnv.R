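hg19_autosome_lengths <- c(
  chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
  chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
  chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
  chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
  chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
  chr21 = 48129895, chr22 = 51304566)

#' Genome bins for copy-number screening
#'
#' Tiles the 22 hg19 autosomes into fixed-width bins.
#'
#' @param bin_size Bin width in bp (default 1 Mb).
#' @return Data frame: `chrom`, `start` (1-based), `end`, `length`.
#' @export
cnv_bins <- function(bin_size = 1e6) {
  out <- lapply(names(hg19_autosome_lengths), function(ch) {
    len <- hg19_autosome_lengths[[ch]]
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    data.frame(chrom = ch, start = starts, end = ends,
               length = ends - starts + 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a binned read-count profile for one embryo biopsy
#'
#' Fragments are allocated to bins by a multinomial whose probabilities
#' are proportional to bin length times local copy state; a mosaic
#' karyotype mixes two and the aberrant copy number at the stated cell
#' fraction. This emulates the ~1.5 million sequenced fragments per
#' trophectoderm biopsy used for aneuploidy screening.
#'
#' @param karyotype List with `state`
#'   (`"euploid"`, `"gain"`, `"loss"`, `"mosaic_gain"`, `"mosaic_loss"`),
#'   `chrom` (affected chromosome, `NA` for euploid) and `fraction`
#'   (aberrant cell fraction; ignored unless mosaic).
#' @param n_fragments Total fragments to allocate (> 0).
#' @param bin_size Bin width in bp.
#' @return [cnv_bins()] data frame with an integer `count` column.
#' @export
simulate_cnv_profile <- function(karyotype, n_fragments = 1.5e6,
                                 bin_size = 1e6) {
  if (n_fragments <= 0)
    stop("simulate_cnv_profile: n_fragments must be > 0")
  bins <- cnv_bins(bin_size)
  copies <- rep(2, nrow(bins))
  if (karyotype$state != "euploid") {
    delta <- if (grepl("gain", karyotype$state)) 1 else -1
    frac <- if (grepl("mosaic", karyotype$state)) karyotype$fraction else 1
    hit <- bins$chrom == karyotype$chrom
    copies[hit] <- 2 + delta * frac
  }
  w <- bins$length * copies
  bins$count <- as.integer(stats::rmultinom(1, n_fragments, w / sum(w)))
  bins
}

#' Expected euploid reference profile
#'
#' Deterministic stand-in for the clinical reference dataset: expected
#' bin counts of a euploid genome, proportional to bin length.
#'
#' @param bin_size Bin width in bp.
#' @param n_fragments Nominal total count.
#' @return [cnv_bins()] data frame with a numeric `count` column.
#' @export
reference_profile <- function(bin_size = 1e6, n_fragments = 1.5e6) {
  bins <- cnv_bins(bin_size)
  bins$count <- n_fragments * bins$length / sum(bins$length)
  bins
}

#' Normalise binned counts against a reference profile
#'
#' Each bin's count share is divided by the reference share and the
#' ratios are rescaled so the genome-wide median is 1; the result is
#' invariant to the overall sequencing depth. Bins with a zero reference
#' count are masked (`NA`) and counted in the `"masked"` attribute.
#'
#' @param profile Binned counts (`chrom`, `start`, `end`, `count`).
#' @param reference Reference profile on the same binning.
#' @return `profile` with a `ratio` column.
#' @export
normalize_bins <- function(profile, reference) {
  if (nrow(profile) != nrow(reference) ||
      !all(profile$start == reference$start & profile$chrom == reference$chrom))
    stop("normalize_bins: profile and reference binnings differ")
  if (sum(profile$count) <= 0)
    stop("normalize_bins: profile has no reads")
  mask <- reference$count <= 0
  ratio <- rep(NA_real_, nrow(profile))
  ratio[!mask] <- (profile$count[!mask] / sum(profile$count)) /
    (reference$count[!mask] / sum(reference$count))
  ratio <- ratio / stats::median(ratio, na.rm = TRUE)
  profile$ratio <- ratio
  attr(profile, "masked") <- sum(mask)
  profile
}

#' Default copy-number ratio bands
#'
#' Euploid `[0.9, 1.1]`; mosaic gain `(1.15, 1.35]`; full gain
#' `> 1.35`; losses mirrored. Ratios in the gaps are assigned to the
#' nearest category and flagged borderline. These bands follow common
#' PGT-A practice; the study's clinical thresholds are unpublished.
#'
#' @return Named list of band edges.
#' @export
cnv_bands <- function() {
  list(euploid = c(0.9, 1.1),
       mosaic_gain = c(1.15, 1.35),
       mosaic_loss = c(0.65, 0.85))
}

#' Call the copy state of one chromosome from its normalised ratio
#'
#' @param ratio Median normalised ratio of the chromosome (> 0).
#' @param bands Band edges as from [cnv_bands()].
#' @return List: `call` (`euploid`, `gain`, `loss`, `mosaic_gain`,
#'   `mosaic_loss`), `mosaic_fraction` (`2 * |ratio - 1|` clipped to
#'   `[0, 1]`; 0 for euploid), `borderline` (ratio fell in a gap zone).
#' @export
call_chromosome <- function(ratio, bands = cnv_bands()) {
  if (is.na(ratio) || ratio <= 0)
    stop("call_chromosome: ratio must be positive")
  b <- bands
  call <- NULL; borderline <- FALSE
  if (ratio >= b$euploid[1] && ratio <= b$euploid[2]) call <- "euploid"
  else if (ratio > b$mosaic_gain[1] && ratio <= b$mosaic_gain[2])
    call <- "mosaic_gain"
  else if (ratio > b$mosaic_gain[2]) call <- "gain"
  else if (ratio >= b$mosaic_loss[1] && ratio < b$mosaic_loss[2])
    call <- "mosaic_loss"
  else if (ratio < b$mosaic_loss[1]) call <- "loss"
  else {
    # gap zone: nearest category by distance to the band edges
    borderline <- TRUE
    call <- if (ratio > 1) {
      if (ratio - b$euploid[2] <= b$mosaic_gain[1] - ratio) "euploid"
      else "mosaic_gain"
    } else {
      if (b$euploid[1] - ratio <= ratio - b$mosaic_loss[2]) "euploid"
      else "mosaic_loss"
    }
  }
  frac <- if (call == "euploid") 0 else min(1, max(0, 2 * abs(ratio - 1)))
  list(call = call, mosaic_fraction = frac, borderline = borderline)
}

#' Screen an embryo profile for aneuploidy and mosaicism
#'
#' Normalises the binned counts, takes the median ratio per chromosome,
#' and bands each chromosome into a copy-state call. The embryo-level
#' call is `euploid` only when every chromosome is; otherwise the most
#' severe abnormality (full gain/loss over mosaic) is reported.
#'
#' @param profile Binned counts for one embryo.
#' @param reference Reference profile ([reference_profile()] or
#'   measured).
#' @param bands Band edges ([cnv_bands()]).
#' @return Object of class `cnv_screen`: `chromosomes` (per-chromosome
#'   ratio, call, mosaic fraction, borderline flag), `call`,
#'   `mosaic_fraction_estimate`, `bins` (normalised bins).
#' @export
cnv_screen <- function(profile, reference = reference_profile(),
                       bands = cnv_bands()) {
  norm <- normalize_bins(profile, reference)
  ratios <- tapply(norm$ratio, norm$chrom, stats::median, na.rm = TRUE)
  chroms <- names(hg19_autosome_lengths)
  ratios <- ratios[chroms]
  calls <- lapply(ratios, call_chromosome, bands = bands)
  tab <- data.frame(
    chrom = chroms,
    ratio = as.numeric(ratios),
    call = vapply(calls, `[[`, "", "call"),
    mosaic_fraction = vapply(calls, `[[`, 0, "mosaic_fraction"),
    borderline = vapply(calls, `[[`, TRUE, "borderline"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  severity <- c(euploid = 0, mosaic_loss = 1, mosaic_gain = 1,
                loss = 2, gain = 2)
  worst <- tab[which.max(severity[tab$call]), ]
  overall <- if (all(tab$call == "euploid")) "euploid" else worst$call
  structure(list(chromosomes = tab, call = overall,
                 mosaic_fraction_estimate =
                   if (overall == "euploid") 0 else worst$mosaic_fraction,
                 bins = norm),
            class = "cnv_screen")
}

#' @export
print.cnv_screen <- function(x, ...) {
  cat(sprintf("<cnv_screen> %s", x$call))
  if (x$call != "euploid") {
    bad <- x$chromosomes[x$chromosomes$call != "euploid", ]
    cat(": ", paste(sprintf("%s %s (ratio %.2f)", bad$chrom, bad$call,
                            bad$ratio), collapse = ", "))
  }
  cat("\n")
  invisible(x)
}
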