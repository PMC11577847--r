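# shared fixtures: small chromosome models and hand-built genotype matrices

toy_models <- function(n = 2, length_bp = 10e6, female = 100, male = 40) {
  lapply(seq_len(n), function(i)
    chromosome_model(paste0("chr", i), length_bp, female, male))
}

# a genotype_matrix built directly from parental dosages and offspring calls;
# offspring is a markers x n matrix of dosages
toy_family <- function(sire_gt, dam_gt, offspring, chrom = "chr1",
                       pos = NULL) {
  n_mark <- length(sire_gt)
  if (is.null(pos)) pos <- seq_len(n_mark) * 1000
  ids <- sprintf("off%03d", seq_len(ncol(offspring)))
  geno <- cbind(offspring, sire = sire_gt, dam = dam_gt)
  colnames(geno) <- c(ids, "sire", "dam")
  markers <- data.frame(marker = paste0("m", seq_len(n_mark)),
                        chrom = chrom, pos = pos,
                        stringsAsFactors = FALSE)
  rownames(geno) <- markers$marker
  ped <- data.frame(family_id = "F1", offspring_id = ids,
                    dam_id = "dam", sire_id = "sire",
                    stringsAsFactors = FALSE)
  genotype_matrix(geno, markers, ped, parent_ids = c("sire", "dam"))
}

# sire-informative (AB x AA) marker pair whose second marker shows exactly
# `k` recombinant gametes out of `n`
toy_pair_counts <- function(k, n) {
  off <- rbind(rep(0L, n),
               c(rep(1L, k), rep(0L, n - k)))
  toy_family(sire_gt = c(1L, 1L), dam_gt = c(0L, 0L), offspring = off)
}
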