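#' Write genotypes to a GT-only VCF 4.2 (and optionally the pedigree)
#'
#' Dosage 0/1/2 is written as `0/0`, `0/1`, `1/1`; missing calls as `./.`.
#' REF/ALT are placeholder bases (`A`/`C`) for the two array alleles. The
#' header is fixed (no timestamps), so output is byte-stable for a given
#' matrix.
#'
#' @param gm A [genotype_matrix()].
#' @param vcf_path Output VCF path.
#' @param pedigree_path Optional path for a tab-delimited pedigree
#'   (`family_id`, `offspring_id`, `dam_id`, `sire_id`).
#' @param contig_lengths Optional named vector of chromosome lengths (bp) to
#'   emit as `##contig` header lines.
#' @return `vcf_path`, invisibly.
#' @export
write_genotypes <- function(gm, vcf_path, pedigree_path = NULL,
                            contig_lengths = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$geno) == 0) stop("empty genotype matrix")
  header <- c("##fileformat=VCFv4.2",
              "##source=acromap",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths)) {
    header <- append(header, sprintf("##contig=<ID=%s,length=%d>",
                                     names(contig_lengths),
                                     as.integer(contig_lengths)),
                     after = 2L)
  }
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(gm$geno), ncol(gm$geno))
  ok <- !is.na(gm$geno)
  gt[ok] <- gt_code[gm$geno[ok] + 1L]
  body <- paste(gm$markers$chrom, gm$markers$pos, gm$markers$marker,
                "A", "C", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  col_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", colnames(gm$geno)), collapse = "\t")
  con <- file(vcf_path, "wb")
  on.exit(close(con))
  writeLines(c(header, col_line, body), con, sep = "\n")
  if (!is.null(pedigree_path))
    utils::write.table(gm$pedigree, pedigree_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(vcf_path)
}

#' Read genotypes from a VCF and pedigree file
#'
#' The inverse of [write_genotypes()]: parses GT fields into B-allele dosage
#' (heterozygous = 1, homozygous ALT = 2, `./.` = `NA`) via `vcfR`.
#'
#' @param vcf_path VCF file (plain or gzipped).
#' @param pedigree Either a pedigree data.frame or a path to the tab-delimited
#'   pedigree file.
#' @return A [genotype_matrix()]. Individuals named in the pedigree as parents
#'   (dam/sire) are labelled as parents.
#' @export
read_genotypes <- function(vcf_path, pedigree) {
  if (is.character(pedigree))
    pedigree <- utils::read.delim(pedigree, stringsAsFactors = FALSE,
                                  colClasses = "character")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # tolerate phased separators
  dosage <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dosage[clean == "0/0"] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean == "1/1"] <- 2L
  fix <- vcfR::getFIX(v)
  markers <- data.frame(marker = fix[, "ID"], chrom = fix[, "CHROM"],
                        pos = as.numeric(fix[, "POS"]),
                        stringsAsFactors = FALSE)
  rownames(dosage) <- markers$marker
  parent_ids <- intersect(unique(c(pedigree$dam_id, pedigree$sire_id)),
                          colnames(dosage))
  genotype_matrix(dosage, markers, pedigree, parent_ids = parent_ids)
}

#' Write / read simulation ground truth as JSON
#'
#' Serializes crossover records, true map lengths and parental haplotypes so a
#' simulated dataset can be regenerated-free audited. Gamete origins and
#' pre-noise genotypes are omitted from the JSON (they are derivable from the
#' crossovers and haplotypes).
#'
#' @param truth A `sim_truth` object from [simulate_family()].
#' @param path JSON file path.
#' @export
write_sim_truth <- function(truth, path) {
  out <- list(crossovers = truth$crossovers,
              map_lengths = truth$map_lengths,
              parent_haplotypes = lapply(truth$parent_haplotypes, function(h)
                list(hap1 = h[, 1], hap2 = h[, 2])))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$parent_haplotypes <- lapply(raw$parent_haplotypes, function(h)
    cbind(h$hap1, h$hap2))
  structure(raw, class = "sim_truth")
}

#' Write / read a linkage map as tab-separated text
#'
#' One row per marker: `marker`, `chrom`, `pos` (bp), `female_cm`,
#' `male_cm`, `avg_cm`.
#'
#' @param map A `sex_map` data.frame (see [estimate_map_positions()]).
#' @param path Output path.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  attr(out, "lengths") <- list(female = max(out$female_cm),
                               male = max(out$male_cm),
                               avg = max(out$avg_cm))
  class(out) <- c("sex_map", "data.frame")
  out
}
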