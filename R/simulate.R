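#' Noise model for simulated array genotypes
#'
#' Residual array noise after cluster QC: uniformly random missing calls and
#' symmetric call swaps (a miscalled genotype is replaced by one of the other
#' two genotype classes with equal probability).
#'
#' @param missing_rate Probability that a call is set to missing.
#' @param error_rate Probability that a call is swapped before missingness.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(missing_rate = 0, error_rate = 0) {
  stopifnot(missing_rate >= 0, missing_rate <= 1,
            error_rate >= 0, error_rate <= 1)
  structure(list(missing_rate = missing_rate, error_rate = error_rate,
                 error_kind = "symmetric-call-swap"),
            class = "noise_model")
}

#' Family design for a full-sib cross
#'
#' @param family_id Family label.
#' @param dam_id Parent acting as egg donor (female meiosis role).
#' @param sire_id Parent acting as sperm donor (male meiosis role). Must differ
#'   from `dam_id`; the same parent label may appear in several families and in
#'   different roles (half-sib designs).
#' @param n_offspring Number of full-sib offspring (>= 1).
#' @return A one-row data.frame; rbind several to describe a multi-family design.
#' @export
family_design <- function(family_id, dam_id, sire_id, n_offspring) {
  stopifnot(n_offspring >= 1)
  if (dam_id == sire_id) stop("dam and sire must be distinct parents")
  data.frame(family_id = as.character(family_id), dam_id = as.character(dam_id),
             sire_id = as.character(sire_id),
             n_offspring = as.integer(n_offspring),
             stringsAsFactors = FALSE)
}

# allele matrices are n_markers x 2 (haplotype 1, haplotype 2), alleles 0/1

#' Simulate a pair of phased array parents
#'
#' Places `n_markers_per_chrom` biallelic markers at sorted random physical
#' positions on each chromosome and assigns each marker one of three
#' segregation configurations: heterozygous in the sire only (paternal-only
#' informative, e.g. AB x AA), in the dam only (maternal-only), or in both
#' parents (AB x AB). The homozygous parent of a single-het marker carries AA
#' or BB with equal probability; heterozygous parents are phased at random.
#'
#' @param n_markers_per_chrom Markers per chromosome (>= 2).
#' @param chrom_models List of [chromosome_model()] objects.
#' @param seg_type_fractions Length-3 proportions of
#'   (paternal-only, maternal-only, both-informative) markers; must sum to 1.
#' @param seed Integer seed; all downstream randomness flows from it.
#' @param sire_id,dam_id Parent labels.
#' @return An object of class `cross_parents`: a marker table (`markers`:
#'   marker, chrom, pos, seg_type) and a named list `haps` of phased allele
#'   matrices (markers x 2).
#' @export
simulate_parents <- function(n_markers_per_chrom, chrom_models,
                             seg_type_fractions = c(1, 1, 1) / 3,
                             seed = 1L, sire_id = "sire", dam_id = "dam") {
  stopifnot(length(seg_type_fractions) == 3, all(seg_type_fractions >= 0))
  if (abs(sum(seg_type_fractions) - 1) > 1e-8)
    stop("seg_type_fractions must sum to 1")
  if (any(n_markers_per_chrom < 2))
    stop("need at least 2 markers per chromosome")
  n_per <- rep_len(n_markers_per_chrom, length(chrom_models))
  set.seed(seed)
  markers <- do.call(rbind, lapply(seq_along(chrom_models), function(i) {
    m <- chrom_models[[i]]
    n <- n_per[i]
    pos <- sort(sample.int(m$physical_length, n))
    data.frame(chrom = m$name, pos = pos,
               seg_type = sample(1:3, n, replace = TRUE,
                                 prob = seg_type_fractions),
               stringsAsFactors = FALSE)
  }))
  markers$marker <- sprintf("%s_%d", markers$chrom, markers$pos)
  markers <- markers[, c("marker", "chrom", "pos", "seg_type")]
  n <- nrow(markers)

  random_het <- function(n) {
    a <- stats::rbinom(n, 1, 0.5)
    cbind(a, 1L - a)
  }
  random_hom <- function(n) {
    a <- stats::rbinom(n, 1, 0.5)
    cbind(a, a)
  }
  sire <- matrix(0L, n, 2)
  dam <- matrix(0L, n, 2)
  het_sire <- markers$seg_type %in% c(1L, 3L)
  het_dam <- markers$seg_type %in% c(2L, 3L)
  sire[het_sire, ] <- random_het(sum(het_sire))
  sire[!het_sire, ] <- random_hom(sum(!het_sire))
  dam[het_dam, ] <- random_het(sum(het_dam))
  dam[!het_dam, ] <- random_hom(sum(!het_dam))
  haps <- list(sire, dam)
  names(haps) <- c(sire_id, dam_id)
  structure(list(markers = markers, haps = haps), class = "cross_parents")
}

#' Simulate a pool of unrelated phased parents under Hardy-Weinberg genotypes
#'
#' For multi-family (half-sib) designs. Marker positions are placed as in
#' [simulate_parents()]; each marker draws an allele frequency uniformly from
#' `maf_range` and every parent two independent alleles, so marker
#' informativeness varies across families.
#'
#' @inheritParams simulate_parents
#' @param parent_ids Labels of the parents to simulate.
#' @param maf_range Range of per-marker allele frequencies.
#' @return A `cross_parents` object with one haplotype matrix per parent.
#' @export
simulate_parent_pool <- function(parent_ids, n_markers_per_chrom, chrom_models,
                                 maf_range = c(0.2, 0.8), seed = 1L) {
  stopifnot(length(parent_ids) >= 2)
  base <- simulate_parents(n_markers_per_chrom, chrom_models, seed = seed)
  markers <- base$markers
  markers$seg_type <- NULL
  n <- nrow(markers)
  p <- stats::runif(n, maf_range[1], maf_range[2])
  haps <- lapply(parent_ids, function(id) {
    cbind(stats::rbinom(n, 1, p), stats::rbinom(n, 1, p))
  })
  names(haps) <- parent_ids
  structure(list(markers = markers, haps = haps), class = "cross_parents")
}

#' Simulate one meiosis on one chromosome
#'
#' The crossover count is Poisson with mean `map length / 100` (Morgan
#' definition of the centimorgan; no crossover interference), crossover
#' positions are uniform on the genetic map and converted to physical
#' coordinates through the inverse Marey profile of the parental role, and the
#' gamete alternates between the two parental haplotypes at each crossover.
#'
#' @param haps Phased allele matrix of the parent restricted to this
#'   chromosome's markers (markers x 2).
#' @param pos Physical marker positions (bp) matching `haps` rows.
#' @param chrom_model A [chromosome_model()].
#' @param role `"female"` (egg) or `"male"` (sperm) meiosis.
#' @param obligate_chiasma If `TRUE`, resample until at least one crossover
#'   (off by default; the expected-crossover calibration assumes it off).
#' @return List with `gamete` (allele vector), `crossovers` (bp positions) and
#'   `origin` (1/2 haplotype of origin per marker). Uses the current RNG state.
#' @export
simulate_meiosis <- function(haps, pos, chrom_model, role = c("female", "male"),
                             obligate_chiasma = FALSE) {
  role <- match.arg(role)
  L <- map_length(chrom_model, role)
  n_xo <- stats::rpois(1, L / 100)
  if (obligate_chiasma && L > 0) {
    while (n_xo == 0) n_xo <- stats::rpois(1, L / 100)
  }
  xo_bp <- numeric(0)
  if (n_xo > 0) {
    xo_cm <- sort(stats::runif(n_xo, 0, L))
    xo_bp <- marey_inverse(chrom_model, xo_cm, role)
  }
  start <- sample(1:2, 1)
  # haplotype of origin flips at each crossover
  origin <- 1L + (start - 1L + findInterval(pos, xo_bp)) %% 2L
  gamete <- haps[cbind(seq_along(pos), origin)]
  list(gamete = gamete, crossovers = xo_bp, origin = origin)
}

#' Simulate a full-sib family
#'
#' Each offspring combines one dam gamete (female meiosis) and one sire gamete
#' (male meiosis) per chromosome, simulated with [simulate_meiosis()].
#' Genotypes are then corrupted by the noise model; the returned truth records
#' everything pre-noise.
#'
#' @param design One-row data.frame from [family_design()].
#' @param parents A `cross_parents` object containing both parents.
#' @param chrom_models List of [chromosome_model()] objects covering all
#'   marker chromosomes.
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @return List with `geno` (a [genotype_matrix()]) and `truth` (class
#'   `sim_truth`: crossover records, parental haplotypes, gamete origins and
#'   true per-chromosome per-sex map lengths).
#' @export
simulate_family <- function(design, parents, chrom_models,
                            noise = noise_model(), seed = 1L) {
  stopifnot(nrow(design) == 1)
  if (!all(c(design$dam_id, design$sire_id) %in% names(parents$haps)))
    stop("both parents of the design must exist in `parents`")
  set.seed(seed)
  sim <- simulate_cross_core(design, parents, chrom_models, noise)
  sim
}

#' Simulate a (possibly multi-family) cross
#'
#' Families are simulated independently with deterministic per-family
#' sub-seeds derived from `seed`; parents shared across families share
#' haplotypes, so half-sib designs are supported.
#'
#' @param designs data.frame of stacked [family_design()] rows.
#' @inheritParams simulate_family
#' @return As [simulate_family()], with offspring of all families combined.
#' @export
simulate_cross <- function(designs, parents, chrom_models,
                           noise = noise_model(), seed = 1L) {
  set.seed(seed)
  simulate_cross_core(designs, parents, chrom_models, noise)
}

simulate_cross_core <- function(designs, parents, chrom_models, noise) {
  markers <- parents$markers
  model_of <- stats::setNames(chrom_models,
                              vapply(chrom_models, `[[`, "", "name"))
  if (!all(markers$chrom %in% names(model_of)))
    stop("chromosome models missing for some marker chromosomes")
  chrom_idx <- split(seq_len(nrow(markers)), markers$chrom)

  offs <- list()
  ped <- list()
  xo_rec <- list()
  origins <- list()
  for (f in seq_len(nrow(designs))) {
    d <- designs[f, ]
    ids <- sprintf("%s_off%03d", d$family_id, seq_len(d$n_offspring))
    ped[[f]] <- data.frame(family_id = d$family_id, offspring_id = ids,
                           dam_id = d$dam_id, sire_id = d$sire_id,
                           stringsAsFactors = FALSE)
    G <- matrix(NA_integer_, nrow(markers), d$n_offspring,
                dimnames = list(markers$marker, ids))
    ori_dam <- matrix(NA_integer_, nrow(markers), d$n_offspring)
    ori_sire <- matrix(NA_integer_, nrow(markers), d$n_offspring)
    for (k in seq_len(d$n_offspring)) {
      g <- integer(nrow(markers))
      for (chrom in names(chrom_idx)) {
        idx <- chrom_idx[[chrom]]
        cmod <- model_of[[chrom]]
        mg <- simulate_meiosis(parents$haps[[d$dam_id]][idx, , drop = FALSE],
                               markers$pos[idx], cmod, "female")
        pg <- simulate_meiosis(parents$haps[[d$sire_id]][idx, , drop = FALSE],
                               markers$pos[idx], cmod, "male")
        g[idx] <- mg$gamete + pg$gamete
        ori_dam[idx, k] <- mg$origin
        ori_sire[idx, k] <- pg$origin
        if (length(mg$crossovers))
          xo_rec[[length(xo_rec) + 1L]] <-
            data.frame(offspring_id = ids[k], role = "female", chrom = chrom,
                       pos = mg$crossovers, stringsAsFactors = FALSE)
        if (length(pg$crossovers))
          xo_rec[[length(xo_rec) + 1L]] <-
            data.frame(offspring_id = ids[k], role = "male", chrom = chrom,
                       pos = pg$crossovers, stringsAsFactors = FALSE)
      }
      G[, k] <- g
    }
    offs[[f]] <- G
    origins[[f]] <- list(dam = ori_dam, sire = ori_sire)
  }
  G <- do.call(cbind, offs)
  pedigree <- do.call(rbind, ped)
  truth_geno <- G

  # noise: symmetric call swaps, then missingness
  if (noise$error_rate > 0) {
    swap <- which(stats::runif(length(G)) < noise$error_rate)
    if (length(swap)) {
      other <- vapply(G[swap], function(g) sample(setdiff(0:2, g), 1), 0L)
      G[swap] <- other
    }
  }
  if (noise$missing_rate > 0) {
    G[stats::runif(length(G)) < noise$missing_rate] <- NA_integer_
  }

  parent_ids <- unique(c(designs$dam_id, designs$sire_id))
  P <- vapply(parent_ids, function(id) rowSums(parents$haps[[id]]),
              numeric(nrow(markers)))
  geno <- genotype_matrix(cbind(G, P), parents$markers, pedigree,
                          parent_ids = parent_ids)

  truth <- structure(list(
    crossovers = if (length(xo_rec)) do.call(rbind, xo_rec) else
      data.frame(offspring_id = character(), role = character(),
                 chrom = character(), pos = numeric()),
    parent_haplotypes = parents$haps[parent_ids],
    gamete_origins = origins,
    genotypes_pre_noise = truth_geno,
    map_lengths = do.call(rbind, lapply(model_of, function(m)
      data.frame(chrom = m$name, female_cm = m$female_map_length,
                 male_cm = m$male_map_length,
                 length_bp = m$physical_length, stringsAsFactors = FALSE)))
  ), class = "sim_truth")
  rownames(truth$map_lengths) <- NULL
  list(geno = geno, truth = truth)
}

#' Genotype matrix container
#'
#' Biallelic calls coded as B-allele dosage 0/1/2 (`NA` = missing), markers in
#' rows and individuals (offspring and genotyped parents) in columns, together
#' with the marker table and the pedigree.
#'
#' @param geno Integer matrix (markers x individuals) with dimnames.
#' @param markers data.frame with `marker`, `chrom`, `pos` (bp).
#' @param pedigree data.frame with `family_id`, `offspring_id`, `dam_id`,
#'   `sire_id`.
#' @param parent_ids Columns of `geno` that are parents, not offspring.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, markers, pedigree, parent_ids = character()) {
  stopifnot(nrow(geno) == nrow(markers),
            all(c("marker", "chrom", "pos") %in% names(markers)),
            all(c("family_id", "offspring_id", "dam_id", "sire_id") %in%
                  names(pedigree)))
  if (is.null(rownames(geno))) rownames(geno) <- markers$marker
  miss <- setdiff(c(pedigree$offspring_id, parent_ids), colnames(geno))
  if (length(miss))
    stop("individuals missing from genotype columns: ",
         paste(miss, collapse = ", "))
  structure(list(geno = geno, markers = markers, pedigree = pedigree,
                 parent_ids = parent_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d markers x %d individuals (%d offspring, %d parents, %d families)\n",
    nrow(x$geno), ncol(x$geno), nrow(x$pedigree), length(x$parent_ids),
    length(unique(x$pedigree$family_id))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

offspring_ids <- function(gm) gm$pedigree$offspring_id
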