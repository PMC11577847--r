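test_that("segregation-type fractions are realized by construction", {
  models <- toy_models(1)
  p1 <- simulate_parents(50, models, seg_type_fractions = c(1, 0, 0), seed = 1)
  sire <- rowSums(p1$haps$sire)
  dam <- rowSums(p1$haps$dam)
  expect_true(all(sire == 1L))       # sire heterozygous everywhere
  expect_true(all(dam %in% c(0L, 2L)))
  p3 <- simulate_parents(50, models, seg_type_fractions = c(0, 0, 1), seed = 2)
  expect_true(all(rowSums(p3$haps$sire) == 1L))
  expect_true(all(rowSums(p3$haps$dam) == 1L))  # AB x AB everywhere
  expect_error(simulate_parents(50, models, seg_type_fractions = c(0.5, 0.4, 0.2)),
               "sum to 1")
  expect_error(simulate_parents(1, models), "at least 2 markers")
})

test_that("marker placement: correct counts, strictly increasing bp per chromosome", {
  models <- toy_models(14, length_bp = 20e6)
  p <- simulate_parents(200, models, seed = 1)
  expect_equal(nrow(p$markers), 2800)
  for (ch in unique(p$markers$chrom)) {
    pos <- p$markers$pos[p$markers$chrom == ch]
    expect_length(pos, 200)
    expect_true(all(diff(pos) > 0))
  }
})

test_that("meiosis calibration: expected crossovers equal map length in Morgans", {
  cm0 <- chromosome_model("z", 1e6, female_map_length = 0, male_map_length = 0)
  haps <- cbind(rep(0L, 5), rep(1L, 5))
  pos <- seq(1e5, 9e5, length.out = 5)
  set.seed(1)
  g <- simulate_meiosis(haps, pos, cm0, "female")
  expect_length(g$crossovers, 0)
  expect_true(all(g$gamete == haps[, g$origin[1]]))

  cm100 <- chromosome_model("c", 1e6, female_map_length = 100,
                            male_map_length = 54.05)
  set.seed(42)
  n_xo <- replicate(10000, length(simulate_meiosis(haps, pos, cm100,
                                                   "female")$crossovers))
  expect_equal(mean(n_xo), 1.00, tolerance = 0.03)
})

test_that("sex-specific map lengths drive the female:male crossover ratio", {
  # chromosome 1 of the A. palmata map: female 148.29 cM vs male 54.05 cM
  cm <- chromosome_model("Chr1", 27.05e6, female_map_length = 148.29,
                         male_map_length = 54.05)
  haps <- cbind(rep(0L, 3), rep(1L, 3))
  pos <- c(1e6, 13e6, 26e6)
  set.seed(7)
  f <- replicate(8000, length(simulate_meiosis(haps, pos, cm, "female")$crossovers))
  m <- replicate(8000, length(simulate_meiosis(haps, pos, cm, "male")$crossovers))
  expect_equal(mean(f) / mean(m), 148.29 / 54.05, tolerance = 0.08)
})

test_that("zero-noise families are Mendelian-consistent and traceable to haplotypes", {
  models <- toy_models(2)
  parents <- simulate_parents(40, models, seed = 3)
  fam <- simulate_family(family_design("F1", "dam", "sire", 30),
                         parents, models, seed = 4)
  gm <- fam$geno
  kids <- gm$pedigree$offspring_id
  flags <- mendel_check(gm$geno[, kids], gm$geno[, "sire"], gm$geno[, "dam"])
  expect_equal(sum(flags), 0)
  # every offspring allele is the sum of the recorded parental-haplotype picks
  tr <- fam$truth
  rebuilt <- matrix(NA_integer_, nrow(gm$geno), length(kids))
  dam_h <- tr$parent_haplotypes$dam
  sire_h <- tr$parent_haplotypes$sire
  ori <- tr$gamete_origins[[1]]
  for (k in seq_along(kids)) {
    rebuilt[, k] <- dam_h[cbind(seq_len(nrow(dam_h)), ori$dam[, k])] +
      sire_h[cbind(seq_len(nrow(sire_h)), ori$sire[, k])]
  }
  expect_equal(unname(rebuilt), unname(tr$genotypes_pre_noise[, kids]))
  # crossover positions inside the chromosome
  expect_true(all(tr$crossovers$pos > 0))
  expect_true(all(tr$crossovers$pos < 10e6))
})

test_that("noise model injects missingness and call swaps at the requested rates", {
  models <- toy_models(1, length_bp = 50e6)
  parents <- simulate_parents(1000, models, seed = 5)
  fam <- simulate_family(family_design("F1", "dam", "sire", 100),
                         parents, models,
                         noise = noise_model(missing_rate = 0.05), seed = 6)
  kids <- fam$geno$pedigree$offspring_id
  expect_lt(abs(mean(is.na(fam$geno$geno[, kids])) - 0.05), 0.01)

  fam2 <- simulate_family(family_design("F1", "dam", "sire", 100),
                          parents, models,
                          noise = noise_model(error_rate = 0.02), seed = 6)
  diff_frac <- mean(fam2$geno$geno[, kids] !=
                      fam2$truth$genotypes_pre_noise[, kids])
  expect_lt(abs(diff_frac - 0.02), 0.005)
})

test_that("multi-family designs share parental haplotypes across families", {
  models <- toy_models(1)
  pool <- simulate_parent_pool(c("A", "B", "C"), 30, models, seed = 9)
  designs <- rbind(family_design("f1", "A", "B", 8),
                   family_design("f2", "A", "C", 8),  # A is dam twice
                   family_design("f3", "B", "C", 8))
  sim <- simulate_cross(designs, pool, models, seed = 10)
  expect_equal(nrow(sim$geno$pedigree), 24)
  expect_equal(length(unique(sim$geno$pedigree$family_id)), 3)
  # parent A's genotype column is one consistent dosage vector
  expect_equal(sim$geno$geno[, "A"], rowSums(pool$haps$A),
               ignore_attr = TRUE)
  expect_error(family_design("f", "A", "A", 5), "distinct")
})

test_that("VCF output round-trips and encodes missing calls as ./.", {
  models <- toy_models(1)
  parents <- simulate_parents(25, models, seed = 11)
  fam <- simulate_family(family_design("F1", "dam", "sire", 12),
                         parents, models,
                         noise = noise_model(missing_rate = 0.1), seed = 12)
  vcf <- tempfile(fileext = ".vcf")
  ped <- tempfile(fileext = ".tsv")
  write_genotypes(fam$geno, vcf, ped)
  lines <- readLines(vcf)
  expect_true(any(grepl("\\./\\.", lines)))
  back <- read_genotypes(vcf, ped)
  expect_equal(back$geno, fam$geno$geno)
  expect_equal(back$markers$pos, fam$geno$markers$pos)
  expect_equal(back$pedigree$offspring_id, fam$geno$pedigree$offspring_id)
})

test_that("toy VCF output is byte-stable under the fixed header", {
  off <- matrix(c(0L, 1L, 2L, NA, 1L, 0L), nrow = 3)
  gm <- toy_family(sire_gt = c(1L, 1L, 0L), dam_gt = c(0L, 1L, 1L),
                   offspring = off, pos = c(100, 200, 300))
  vcf <- tempfile(fileext = ".vcf")
  write_genotypes(gm, vcf)
  expect_identical(readLines(vcf), c(
    "##fileformat=VCFv4.2",
    "##source=acromap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\toff001\toff002\tsire\tdam",
    "chr1\t100\tm1\tA\tC\t.\t.\t.\tGT\t0/0\t./.\t0/1\t0/0",
    "chr1\t200\tm2\tA\tC\t.\t.\t.\tGT\t0/1\t0/1\t0/1\t0/1",
    "chr1\t300\tm3\tA\tC\t.\t.\t.\tGT\t1/1\t0/0\t0/0\t0/1"))
})

test_that("simulation truth serializes to JSON and back", {
  models <- toy_models(1)
  parents <- simulate_parents(10, models, seed = 13)
  fam <- simulate_family(family_design("F1", "dam", "sire", 5),
                         parents, models, seed = 14)
  path <- tempfile(fileext = ".json")
  write_sim_truth(fam$truth, path)
  back <- read_sim_truth(path)
  expect_equal(back$map_lengths$female_cm, fam$truth$map_lengths$female_cm)
  expect_equal(back$parent_haplotypes$dam[, 1],
               fam$truth$parent_haplotypes$dam[, 1], ignore_attr = TRUE)
  expect_equal(nrow(back$crossovers), nrow(fam$truth$crossovers))
})

test_that("chromosome tables and models read back consistently", {
  models <- toy_models(3)
  path <- tempfile(fileext = ".tsv")
  write_chrom_table(models, path)
  tab <- read_chrom_table(path)
  expect_equal(tab$chromosome, c("chr1", "chr2", "chr3"))
  expect_equal(tab$length_bp, rep(10e6, 3))
  # published tables load and agree with the shipped marker totals
  pal <- acropora_map_summary("palmata")
  expect_equal(sum(pal$n_markers), 2114)
  cer <- acropora_map_summary("cervicornis")
  expect_equal(sum(cer$n_markers), 4859)
  m <- acropora_chromosome_models("palmata")
  expect_equal(m$Chr1$female_map_length, 148.29)
  expect_equal(m$Chr1$male_map_length, 54.05)
})

test_that("Marey profiles are monotone and invert correctly", {
  cm <- chromosome_model("c", 2e6, 80, 30)
  bp <- seq(0, 2e6, length.out = 101)
  g <- marey_position(cm, bp, "female")
  expect_true(all(diff(g) >= 0))
  expect_equal(g[1], 0)
  expect_equal(g[101], 80)
  mid <- marey_inverse(cm, c(0, 40, 80), "female")
  expect_equal(marey_position(cm, mid, "female"), c(0, 40, 80),
               tolerance = 1e-8)
  expect_error(chromosome_model("c", 1e6, 10, 10,
                                profile_x = c(0, 0.5, 0.75, 1),
                                profile_y = c(0, 0.8, 0.7, 1)),
               "non-decreasing")
})
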