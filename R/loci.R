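#' Disease-locus definition
#'
#' A `mutation_locus` describes the mutation interval that is genotyped
#' directly in every embryo, plus two flanking baseline intervals used to
#' normalise read depth for large-deletion calls. Coordinates are 1-based
#' inclusive on hg19.
#'
#' @param name Locus label, e.g. `"SEA"` or `"CD41-42delAAAG"`.
#' @param kind `"large_deletion"` (genotyped by depth collapse over the
#'   region) or `"small_indel"` (genotyped by allele counts at
#'   `mutation_pos`).
#' @param chrom Contig name (hg19 style, e.g. `"chr16"`).
#' @param start,end 1-based inclusive interval of the mutation region.
#' @param flank_left,flank_right Length-2 integer vectors giving the two
#'   depth-baseline intervals; they must not overlap the region.
#' @param mutation_pos For small indels, the representative coordinate of
#'   the variant inside the region.
#' @return An object of class `mutation_locus`.
#' @export
mutation_locus <- function(name, kind = c("large_deletion", "small_indel"),
                           chrom, start, end,
                           flank_left = NULL, flank_right = NULL,
                           mutation_pos = NULL) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start) stop("mutation_locus: region length must be > 0")
  if (is.null(flank_left))  flank_left  <- c(start - 50000L, start - 1L)
  if (is.null(flank_right)) flank_right <- c(end + 1L, end + 50000L)
  if (flank_left[2] >= start || flank_right[1] <= end)
    stop("mutation_locus: flanks must not overlap the region")
  if (!is.null(mutation_pos)) {
    mutation_pos <- suppressWarnings(as.integer(mutation_pos))
    if (is.na(mutation_pos)) mutation_pos <- NULL
  }
  if (kind == "small_indel" && is.null(mutation_pos))
    mutation_pos <- as.integer(round((start + end) / 2))
  structure(list(name = name, kind = kind, chrom = chrom,
                 start = start, end = end,
                 flank_left = as.integer(flank_left),
                 flank_right = as.integer(flank_right),
                 mutation_pos = if (is.null(mutation_pos)) NA_integer_
                                else as.integer(mutation_pos)),
            class = "mutation_locus")
}

#' @export
print.mutation_locus <- function(x, ...) {
  cat(sprintf("<mutation_locus> %s (%s) %s:%d-%d\n",
              x$name, x$kind, x$chrom, x$start, x$end))
  invisible(x)
}

#' Southeast-Asian alpha-globin deletion locus (hg19)
#'
#' The ~20 kb SEA deletion removing HBA1 and HBA2
#' (chr16:215,400-234,700). Homozygous embryos fail to amplify inside the
#' region, so the locus is genotyped from the in-region / flank depth
#' ratio.
#'
#' @return A [mutation_locus()] of kind `"large_deletion"`.
#' @export
locus_sea_hba <- function() {
  mutation_locus("SEA", "large_deletion", "chr16", 215400L, 234700L)
}

#' HBB codon 41-42 (-AAAG) locus (hg19)
#'
#' The 4-bp deletion in HBB codons 41/42 causing beta-thalassemia; the
#' gene interval is chr11:5,246,696-5,248,301. The variant is genotyped
#' from reference / deletion allele read counts at a representative
#' coordinate inside the gene.
#'
#' @return A [mutation_locus()] of kind `"small_indel"`.
#' @export
locus_hbb_cd41_42 <- function() {
  mutation_locus("CD41-42delAAAG", "small_indel", "chr11",
                 5246696L, 5248301L, mutation_pos = 5248000L)
}

#' Read a disease locus from BED + JSON sidecar
#'
#' The BED line (0-based half-open) gives the region; the JSON sidecar
#' carries `kind`, the two flank intervals and, for indels,
#' `mutation_pos`.
#'
#' @param bed_path Path to a single-interval BED file.
#' @param json_path Path to the JSON sidecar.
#' @return A [mutation_locus()].
#' @export
read_locus <- function(bed_path, json_path) {
  bed <- utils::read.table(bed_path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  mutation_locus(name = if (ncol(bed) >= 4) bed[1, 4] else meta$name,
                 kind = meta$kind, chrom = bed[1, 1],
                 start = bed[1, 2] + 1L, end = bed[1, 3],
                 flank_left = unlist(meta$flank_left),
                 flank_right = unlist(meta$flank_right),
                 mutation_pos = meta$mutation_pos)
}

#' Write a disease locus as BED + JSON sidecar
#'
#' @param locus A [mutation_locus()].
#' @param bed_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_locus <- function(locus, bed_path, json_path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", locus$chrom, locus$start - 1L,
                     locus$end, locus$name), bed_path)
  jsonlite::write_json(list(name = locus$name, kind = locus$kind,
                            flank_left = locus$flank_left,
                            flank_right = locus$flank_right,
                            mutation_pos = locus$mutation_pos),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bed_path, json_path))
}

#' Locate a position relative to a locus
#'
#' @param pos Integer vector of 1-based positions.
#' @param locus A [mutation_locus()].
#' @return Character vector: `"upstream"` (below region start),
#'   `"intragenic"`, or `"downstream"` (above region end). Upstream and
#'   downstream follow forward-strand genomic coordinates.
#' @export
locus_location <- function(pos, locus) {
  ifelse(pos < locus$start, "upstream",
         ifelse(pos > locus$end, "downstream", "intragenic"))
}
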