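#' Classify marker informativeness from the two parental genotypes
#'
#' A marker reveals recombination only in a parent that is heterozygous.
#' Codes follow the usual convention for outbred full-sib families:
#' 0 = uninformative (neither parent heterozygous, or a parent missing),
#' 1 = informative in the father (sire) only, 2 = in the mother (dam) only,
#' 3 = in both (AB x AB).
#'
#' @param sire_gt,dam_gt Parental B-allele dosages (0/1/2, `NA` = missing);
#'   vectors are processed elementwise.
#' @return Integer vector of codes in `{0, 1, 2, 3}`.
#' @export
classify_informativeness <- function(sire_gt, dam_gt) {
  code <- (sire_gt == 1L) + 2L * (dam_gt == 1L)
  code[is.na(sire_gt) | is.na(dam_gt)] <- 0L
  as.integer(code)
}

# allowed[s+1, d+1, o+1]: is offspring dosage o possible under cross s x d?
.mendel_allowed <- local({
  transmissible <- list(`0` = 0L, `1` = 0:1, `2` = 1L)
  arr <- array(FALSE, c(3, 3, 3))
  for (s in 0:2) for (d in 0:2) {
    off <- unique(outer(transmissible[[s + 1]], transmissible[[d + 1]], `+`))
    arr[s + 1, d + 1, off + 1] <- TRUE
  }
  arr
})

#' Flag offspring genotypes impossible under the parental cross
#'
#' @param offspring_calls Vector (or markers x offspring matrix) of offspring
#'   dosages for one marker (vector) or several markers (matrix, with
#'   `sire_gt`/`dam_gt` recycled per row).
#' @param sire_gt,dam_gt Parental dosages (scalar for a vector of calls,
#'   per-marker vectors for a matrix).
#' @return Logical vector/matrix of violation flags (`NA` calls are not
#'   violations). Markers with a missing parent yield `NA` flags with a
#'   warning: the check is skipped there.
#' @export
mendel_check <- function(offspring_calls, sire_gt, dam_gt) {
  off <- as.matrix(offspring_calls)
  if (length(sire_gt) == 1) sire_gt <- rep(sire_gt, nrow(off))
  if (length(dam_gt) == 1) dam_gt <- rep(dam_gt, nrow(off))
  stopifnot(length(sire_gt) == nrow(off), length(dam_gt) == nrow(off))
  bad_parent <- is.na(sire_gt) | is.na(dam_gt)
  if (any(bad_parent))
    warning(sum(bad_parent), " marker(s) skipped in Mendel check: missing parental genotype")
  k <- ncol(off)
  flags <- matrix(NA, nrow(off), k, dimnames = dimnames(off))
  idx <- !bad_parent
  if (any(idx)) {
    o <- off[idx, , drop = FALSE]
    res <- !.mendel_allowed[cbind(rep(sire_gt[idx] + 1L, k),
                                  rep(dam_gt[idx] + 1L, k),
                                  as.vector(o) + 1L)]
    res[is.na(as.vector(o))] <- FALSE
    flags[idx, ] <- res
  }
  if (is.vector(offspring_calls)) flags <- flags[, 1]
  flags
}

#' Chi-square segregation-distortion test for one marker
#'
#' Goodness of fit of the non-missing, non-violating offspring calls against
#' the Mendelian expectation of the cross type: 1:1 for a single-heterozygote
#' cross, 1:2:1 for AB x AB.
#'
#' @param offspring_calls Offspring dosages at the marker.
#' @param sire_gt,dam_gt Parental dosages.
#' @param alpha Distortion p-value floor below which the marker is dropped.
#' @param min_calls Minimum usable calls; fewer drops the marker with reason
#'   `"insufficient data"`.
#' @return List with `keep`, `p_value`, `statistic` and `reason`.
#' @export
segregation_filter <- function(offspring_calls, sire_gt, dam_gt,
                               alpha = 1e-4, min_calls = 10) {
  code <- classify_informativeness(sire_gt, dam_gt)
  if (code == 0L)
    return(list(keep = TRUE, p_value = NA_real_, statistic = NA_real_,
                reason = "uninformative"))
  viol <- mendel_check(offspring_calls, sire_gt, dam_gt)
  usable <- offspring_calls[!is.na(offspring_calls) & !viol]
  if (code == 3L) {
    obs <- tabulate(usable + 1L, 3L)
    expd <- sum(obs) * c(0.25, 0.5, 0.25)
  } else {
    hom <- if (code == 1L) dam_gt else sire_gt
    classes <- if (hom == 0L) c(0L, 1L) else c(1L, 2L)
    obs <- c(sum(usable == classes[1]), sum(usable == classes[2]))
    expd <- sum(obs) * c(0.5, 0.5)
  }
  n <- sum(obs)
  if (n < min_calls)
    return(list(keep = FALSE, p_value = NA_real_, statistic = NA_real_,
                reason = "insufficient data"))
  stat <- sum((obs - expd)^2 / expd)
  p <- stats::pchisq(stat, df = length(obs) - 1L, lower.tail = FALSE)
  list(keep = p >= alpha, p_value = p, statistic = stat,
       reason = if (p >= alpha) "pass" else "segregation distortion")
}

#' Retain markers whose informativeness code is in a mask
#'
#' Mirrors the informativeness mask of array linkage pipelines: mask
#' `c(1, 2, 3)` keeps every informative marker, `c(1, 2)` additionally
#' excludes AB x AB (both-parent heterozygous) markers; a marker is retained
#' if its code in at least one family is in the mask.
#'
#' @param codes Integer vector (single family) or markers x families matrix of
#'   informativeness codes.
#' @param mask Non-empty subset of `c(1, 2, 3)`.
#' @return Logical keep vector. Errors if the mask is empty or no marker
#'   survives.
#' @export
apply_mask <- function(codes, mask = c(1, 2, 3)) {
  mask <- as.integer(mask)
  if (length(mask) == 0) stop("empty informativeness mask")
  if (!all(mask %in% 1:3)) stop("mask must be a subset of {1,2,3}")
  codes <- as.matrix(codes)
  keep <- rowSums(matrix(codes %in% mask, nrow(codes))) > 0
  if (!any(keep)) stop("no informative markers retained by the mask")
  keep
}

#' Marker quality control for a full-sib genotype matrix
#'
#' The array-QC stage of the mapping pipeline: classifies per-family marker
#' informativeness, masks Mendelian-inconsistent offspring calls (dropping a
#' marker outright when a family's violation rate exceeds
#' `max_violation_rate`, which indicates systematic marker failure rather than
#' isolated miscalls), tests segregation distortion per informative family,
#' filters on missingness, and applies the informativeness mask.
#'
#' @param gm A [genotype_matrix()] containing genotyped parents.
#' @param mask Informativeness mask, see [apply_mask()].
#' @param alpha Segregation-distortion p-value floor (per family).
#' @param max_missing Maximum missing fraction per marker across offspring.
#' @param max_violation_rate Maximum tolerated per-family Mendelian violation
#'   rate before the marker is dropped.
#' @param min_calls Passed to [segregation_filter()].
#' @return List with `report` (one row per input marker: informativeness,
#'   Mendelian error count, distortion p-value, missing fraction, pass flag,
#'   reason), `geno` (filtered [genotype_matrix()] with violating calls set to
#'   missing) and `codes` (markers x families informativeness matrix).
#' @export
qc_markers <- function(gm, mask = c(1, 2, 3), alpha = 1e-4,
                       max_missing = 0.25, max_violation_rate = 0.05,
                       min_calls = 10) {
  stopifnot(inherits(gm, "genotype_matrix"))
  fams <- unique(gm$pedigree[, c("family_id", "dam_id", "sire_id")])
  n_mark <- nrow(gm$geno)
  codes <- matrix(0L, n_mark, nrow(fams),
                  dimnames = list(gm$markers$marker, fams$family_id))
  mendel_n <- integer(n_mark)
  seg_p <- rep(NA_real_, n_mark)
  seg_fail <- logical(n_mark)
  seg_thin <- logical(n_mark)
  viol_drop <- logical(n_mark)
  G <- gm$geno

  for (f in seq_len(nrow(fams))) {
    fam <- fams[f, ]
    kids <- gm$pedigree$offspring_id[gm$pedigree$family_id == fam$family_id]
    S <- G[, fam$sire_id]
    D <- G[, fam$dam_id]
    codes[, f] <- classify_informativeness(S, D)
    O <- G[, kids, drop = FALSE]
    flags <- suppressWarnings(mendel_check(O, S, D))
    nv <- rowSums(flags, na.rm = TRUE)
    mendel_n <- mendel_n + nv
    viol_drop <- viol_drop | (nv / length(kids) > max_violation_rate)
    O[!is.na(flags) & flags] <- NA_integer_
    G[, kids] <- O

    # per-family segregation test, vectorized over markers
    n0 <- rowSums(O == 0L, na.rm = TRUE)
    n1 <- rowSums(O == 1L, na.rm = TRUE)
    n2 <- rowSums(O == 2L, na.rm = TRUE)
    code <- codes[, f]
    stat <- rep(NA_real_, n_mark)
    df <- rep(NA_integer_, n_mark)
    ntot <- rep(NA_real_, n_mark)
    i3 <- code == 3L
    if (any(i3)) {
      n <- n0[i3] + n1[i3] + n2[i3]
      stat[i3] <- (n0[i3] - n / 4)^2 / (n / 4) + (n1[i3] - n / 2)^2 / (n / 2) +
        (n2[i3] - n / 4)^2 / (n / 4)
      df[i3] <- 2L; ntot[i3] <- n
    }
    for (cc in 1:2) {
      ic <- code == cc
      if (!any(ic)) next
      hom <- if (cc == 1L) D[ic] else S[ic]
      a <- ifelse(hom == 0L, n0[ic], n1[ic])
      b <- ifelse(hom == 0L, n1[ic], n2[ic])
      n <- a + b
      stat[ic] <- ifelse(n > 0, (a - b)^2 / n, NA)
      df[ic] <- 1L; ntot[ic] <- n
    }
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    thin <- !is.na(ntot) & ntot < min_calls
    seg_thin <- seg_thin | (code > 0L & thin)
    fail <- !thin & !is.na(p) & p < alpha
    seg_fail <- seg_fail | fail
    seg_p <- pmin(seg_p, p, na.rm = TRUE)
  }

  kid_cols <- gm$pedigree$offspring_id
  missing_frac <- rowMeans(is.na(G[, kid_cols, drop = FALSE]))
  in_mask <- tryCatch(apply_mask(codes, mask),
                      error = function(e) rep(FALSE, n_mark))

  reason <- rep("pass", n_mark)
  reason[missing_frac > max_missing] <- "missing data"
  reason[seg_thin] <- "insufficient data"
  reason[seg_fail] <- "segregation distortion"
  reason[viol_drop] <- "mendelian errors"
  reason[!in_mask] <- "masked"
  pass <- reason == "pass"
  if (!any(pass)) stop("no informative markers pass QC")

  report <- data.frame(marker = gm$markers$marker, chrom = gm$markers$chrom,
                       pos = gm$markers$pos,
                       info_code = apply(codes, 1, max),
                       mendel_error_count = mendel_n,
                       segregation_p_value = ifelse(is.finite(seg_p), seg_p, NA),
                       missing_fraction = missing_frac,
                       pass_flag = pass, reason = reason,
                       stringsAsFactors = FALSE)
  keep <- which(pass)
  filtered <- genotype_matrix(G[keep, , drop = FALSE],
                              gm$markers[keep, , drop = FALSE],
                              gm$pedigree, gm$parent_ids)
  list(report = report, geno = filtered, codes = codes)
}
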