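TSV_VERSION <- "# embryophase tsv v1"

#' Write a data frame as a versioned TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param name Format name recorded on the header comment line.
#' @return Invisibly, `path`.
#' @export
write_tsv_versioned <- function(df, path, name = "table") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# embryophase %s v1", name), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a versioned TSV
#'
#' Columns holding allele letters or labels are kept as character (a
#' column of "T" alleles must not become logical); everything else is
#' type-converted.
#'
#' @param path Path written by [write_tsv_versioned()].
#' @return Data frame.
#' @export
read_tsv_versioned <- function(path) {
  if (!file.exists(path)) stop("read_tsv_versioned: no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#", colClasses = "character")
  char_cols <- c("chrom", "ref", "alt", "mother", "father", "sample",
                 "side", "location", "status", "het_a1", "het_a2",
                 "hom_allele", "hap0_allele", "hap1_allele", "embryo",
                 "family", "call", "state", "flags",
                 "maternal_assignment", "paternal_assignment",
                 "direct_confidence")
  for (nm in setdiff(names(df), char_cols))
    df[[nm]] <- utils::type.convert(df[[nm]], as.is = TRUE)
  df
}

#' Write parental genotypes as a two-sample VCF
#'
#' Emits a minimal plain-text VCF 4.2 with `MOTHER` and `FATHER` sample
#' columns and hg19-style contig headers; genotypes are unphased GT
#' calls against the site's ref/alt alleles.
#'
#' @param parents Genotype table (`chrom`, `pos`, `ref`, `alt`,
#'   `mother`, `father` with genotypes like `"A/C"`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_parental_vcf <- function(parents, path) {
  gt_index <- function(gt, ref, alt) {
    al <- split_gt(gt)
    vapply(seq_along(al), function(i) {
      idx <- match(al[[i]], c(ref[i], alt[i])) - 1L
      if (anyNA(idx)) "./." else paste(sort(idx), collapse = "/")
    }, "")
  }
  contigs <- unique(parents$chrom)
  known <- hg19_autosome_lengths[contigs]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=embryophase_v1",
    "##reference=hg19",
    sprintf("##contig=<ID=%s%s>", contigs,
            ifelse(is.na(known), "", sprintf(",length=%d", known))),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "MOTHER", "FATHER", sep = "\t"))
  body <- paste(parents$chrom, parents$pos, ".", parents$ref, parents$alt,
                ".", "PASS", ".", "GT",
                gt_index(parents$mother, parents$ref, parents$alt),
                gt_index(parents$father, parents$ref, parents$alt),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read parental genotypes from a VCF
#'
#' Parses a two-sample VCF with vcfR and returns the genotype-table
#' layout used throughout the package. Samples named `MOTHER`/`FATHER`
#' are matched by name; otherwise the first sample is taken as the
#' mother and the second as the father.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return Genotype table: `chrom`, `pos`, `ref`, `alt`, `mother`,
#'   `father` (allele-string genotypes, `NA` when missing).
#' @export
read_parental_vcf <- function(path) {
  if (!file.exists(path))
    stop("read_parental_vcf: no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  mi <- if ("MOTHER" %in% samples) "MOTHER" else samples[1]
  fi <- if ("FATHER" %in% samples) "FATHER" else samples[2]
  decode <- function(g, ref, alt) {
    vapply(seq_along(g), function(i) {
      if (is.na(g[i])) return(NA_character_)
      idx <- suppressWarnings(
        as.integer(strsplit(g[i], "[/|]")[[1]]))
      if (length(idx) != 2 || anyNA(idx)) return(NA_character_)
      al <- c(ref[i], alt[i])[idx + 1L]
      if (anyNA(al)) return(NA_character_)
      paste(sort(al), collapse = "/")
    }, "")
  }
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    mother = decode(gt[, mi], fix[, "REF"], fix[, "ALT"]),
    father = decode(gt[, fi], fix[, "REF"], fix[, "ALT"]),
    stringsAsFactors = FALSE)
}

#' Serialise a phased haplotype set as TSV
#'
#' Machine-readable analogue of the haplotype figure: one row per
#' informative site with the disease (hap0) and normal (hap1) alleles
#' and the site status.
#'
#' @param phase A `pgt_phase` from [build_haplotypes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_phase_tsv <- function(phase, path) {
  write_tsv_versioned(phase$panel, path, "phased_haplotypes")
}

#' Read a phased haplotype set from TSV
#'
#' @param path Path written by [write_phase_tsv()].
#' @return A `pgt_phase` object.
#' @export
read_phase_tsv <- function(path) {
  panel <- read_tsv_versioned(path)
  res <- panel[panel$status == "resolved", ]
  structure(list(
    panel = panel,
    n_affected_used = NA_integer_,
    counts = table(side = factor(res$side, c("maternal", "paternal")),
                   location = factor(res$location,
                                     c("upstream", "downstream"))),
    status_tally = table(factor(panel$status,
      c("resolved", "unresolved_ADO", "conflict")))),
    class = "pgt_phase")
}

#' Write simulation ground truth as JSON
#'
#' @param truth The `truth` element of a [simulate_family()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(
    sites = truth$sites,
    maternal_haps = truth$maternal_haps,
    paternal_haps = truth$paternal_haps,
    maternal_labels = truth$maternal_labels,
    paternal_labels = truth$paternal_labels,
    maternal_at_locus = as.list(truth$maternal_at_locus),
    paternal_at_locus = as.list(truth$paternal_at_locus),
    mutation_genotype = as.list(truth$mutation_genotype)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
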