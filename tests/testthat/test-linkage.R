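test_that("Kosambi map function: values, bijection, domain errors", {
  expect_equal(kosambi(0), 0)
  expect_equal(kosambi(0.1), 25 * log(1.5))
  expect_equal(kosambi(0.1), 10.137, tolerance = 1e-4)
  expect_error(kosambi(0.5), "0.5")
  expect_error(kosambi(-0.01), ">= 0")
  expect_error(kosambi_inv(-1), ">= 0")
  expect_true(is.finite(kosambi(0.4999)))
  r <- seq(0, 0.4999, length.out = 200)
  expect_equal(kosambi_inv(kosambi(r)), r, tolerance = 1e-10)
  d <- seq(0, 200, length.out = 100)
  expect_equal(kosambi(kosambi_inv(d)), d, tolerance = 1e-10)
})

test_that("two-point LOD matches the closed form for phase-known counts", {
  res <- pairwise_rf_lod(marker_transmissions(toy_pair_counts(10, 100)),
                         "m1", "m2")
  expect_equal(res$rf_joint, 0.10, tolerance = 1e-6)
  expect_equal(res$rf_male, 0.10)
  expect_true(is.na(res$rf_female))
  expect_equal(res$lod, 100 * log10(2) + 10 * log10(0.1) + 90 * log10(0.9),
               tolerance = 1e-6)
  expect_equal(res$n_informative_meioses, 100)

  res0 <- pairwise_rf_lod(marker_transmissions(toy_pair_counts(0, 100)),
                          "m1", "m2")
  expect_equal(res0$rf_joint, 0)
  expect_equal(res0$lod, 100 * log10(2), tolerance = 1e-6)

  res5 <- pairwise_rf_lod(marker_transmissions(toy_pair_counts(50, 100)),
                          "m1", "m2")
  expect_equal(res5$rf_joint, 0.5)
  expect_equal(res5$lod, 0, tolerance = 1e-6)
})

test_that("pairwise_rf_lod equals a brute-force likelihood grid search", {
  cases <- list(list(codes = 1, r = 0.15, seed = 1),
                list(codes = 2, r = 0.30, seed = 2),
                list(codes = 3, r = 0.10, seed = 3),   # EM over double hets
                list(codes = 3, r = 0.35, seed = 4),
                list(codes = c(1, 2), r = 0.20, seed = 5),
                list(codes = c(3, 1), r = 0.05, seed = 6),
                list(codes = c(3, 3), r = 0.25, seed = 7))
  for (cs in cases) {
    gm <- random_pair_gm(cs$codes, n_off = 25, r_true = cs$r, seed = cs$seed)
    got <- pairwise_rf_lod(marker_transmissions(gm), "m1", "m2")
    want <- oracle_two_point(gm, 1, 2)
    expect_lt(abs(got$rf_joint - want$rf), 1e-3)
    expect_lt(abs(got$lod - want$lod), 1e-2)
  }
})

test_that("linkage groups form by single-linkage closure and respect min_size", {
  pairs <- data.frame(marker_i = c("a", "b", "x"),
                      marker_j = c("b", "c", "y"),
                      lod = c(20, 20, 1))
  g <- group_markers(pairs, lod_threshold = 10, min_size = 3,
                     markers = c("a", "b", "c", "x", "y"))
  expect_length(g$groups, 1)
  expect_setequal(g$groups$LG1, c("a", "b", "c"))
  expect_setequal(g$unassigned, c("x", "y"))
  # 4-marker cluster dissolved at the default minimal size of 5
  nm <- c(paste0("c", 1:4), paste0("k", 1:6))
  lod <- matrix(0, 10, 10, dimnames = list(nm, nm))
  lod[1:4, 1:4] <- 30
  lod[5:10, 5:10] <- 30
  g2 <- group_markers(lod, lod_threshold = 11, min_size = 5)
  expect_length(g2$groups, 1)
  expect_setequal(g2$groups$LG1, paste0("k", 1:6))
  expect_setequal(g2$unassigned, paste0("c", 1:4))
})

test_that("simulated chromosomes separate into their own linkage groups", {
  models <- toy_models(2)
  parents <- simulate_parents(60, models, seed = 51)
  fam <- simulate_family(family_design("F1", "dam", "sire", 70),
                         parents, models, seed = 52)
  tr <- marker_transmissions(fam$geno)
  pairs <- pairwise_lod_matrix(tr)
  g <- group_markers(pairs$lod, lod_threshold = 8, min_size = 5)
  expect_length(g$groups, 2)
  chroms <- lapply(g$groups, function(m)
    unique(fam$geno$markers$chrom[match(m, fam$geno$markers$marker)]))
  expect_true(all(lengths(chroms) == 1))
  # grouping is invariant under marker input order
  perm <- sample(nrow(fam$geno$geno))
  gm2 <- genotype_matrix(fam$geno$geno[perm, ], fam$geno$markers[perm, ],
                         fam$geno$pedigree, fam$geno$parent_ids)
  g2 <- group_markers(pairwise_lod_matrix(marker_transmissions(gm2))$lod,
                      lod_threshold = 8, min_size = 5)
  canon <- function(gr) sort(vapply(gr, function(m)
    paste(sort(m), collapse = ","), ""))
  expect_equal(unname(canon(g$groups)), unname(canon(g2$groups)))
})

test_that("unassigned markers join groups under the LOD limit and difference rules", {
  nm <- c("g1a", "g1b", "g2a", "g2b", "u1", "u2", "u3")
  lod <- matrix(0, 7, 7, dimnames = list(nm, nm))
  groups <- list(LG1 = c("g1a", "g1b"), LG2 = c("g2a", "g2b"))
  lod["u1", c("g1a", "g2a")] <- c(3, 0.5)   # joined: 3 >= 2, diff 2.5 >= 2
  lod["u2", c("g1a", "g2a")] <- c(3, 2)     # stays: difference 1 < 2
  lod["u3", c("g1a", "g2a")] <- c(1.5, 0)   # stays: below limit
  lod <- pmax(lod, t(lod))
  r <- rescue_unassigned(groups, c("u1", "u2", "u3"), lod)
  expect_true("u1" %in% r$groups$LG1)
  expect_setequal(r$unassigned, c("u2", "u3"))
  r0 <- rescue_unassigned(groups, character(0), lod)
  expect_identical(r0$groups, groups)
})

test_that("ordering recovers the metric order and matches the exhaustive oracle", {
  # three markers: rf(1,2) = rf(2,3) = 0.05, rf(1,3) = 0.10 -> order 1-2-3
  nm <- paste0("m", 1:3)
  rf <- matrix(c(0, .05, .10, .05, 0, .05, .10, .05, 0), 3,
               dimnames = list(nm, nm))
  mk <- data.frame(marker = nm, pos = c(10, 20, 30))
  ord <- order_markers(mk, pairs_from_rf(rf))
  expect_equal(ord$order, nm)
  # already-optimal physical order is unchanged
  expect_equal(order_markers(mk, pairs_from_rf(rf), use_physical = TRUE)$order,
               nm)

  # exhaustive-permutation oracle on 6 markers with scrambled physical order
  set.seed(61)
  for (rep in 1:5) {
    true_pos <- cumsum(runif(6, 2, 10))                   # cM, gaps >= 2
    d_true <- abs(outer(true_pos, true_pos, `-`))
    rf6 <- kosambi_inv(d_true) + matrix(runif(36, 0, 0.01), 6)
    rf6 <- (rf6 + t(rf6)) / 2
    diag(rf6) <- 0
    nm6 <- paste0("x", 1:6)
    dimnames(rf6) <- list(nm6, nm6)
    shuffle <- sample(6)
    mk6 <- data.frame(marker = nm6, pos = shuffle * 1000)
    got <- order_markers(mk6, pairs_from_rf(rf6), use_physical = FALSE)
    # oracle: minimum total Kosambi length over all 720 permutations
    P <- acromap:::perms(6)
    lens <- apply(P, 1, function(o)
      sum(kosambi(pmin(rf6[cbind(o[-6], o[-1])], 0.4999))))
    best <- min(lens)
    got_len <- sum(kosambi(pmin(
      rf6[cbind(got$order[-6], got$order[-1])], 0.4999)))
    expect_equal(got_len, best, tolerance = 1e-9)
  }
})

test_that("markers under the identical limit collapse into one bin", {
  nm <- paste0("m", 1:4)
  rf <- matrix(0.2, 4, 4, dimnames = list(nm, nm))
  rf[1, 2] <- rf[2, 1] <- 0.001           # collapse m1/m2
  rf[3, 4] <- rf[4, 3] <- 0.3
  diag(rf) <- 0
  mk <- data.frame(marker = nm, pos = c(10, 11, 500, 900))
  ord <- order_markers(mk, pairs_from_rf(rf), identical_limit = 0.005)
  expect_equal(unname(ord$bin_of["m1"]), unname(ord$bin_of["m2"]))
  expect_false(ord$bin_of["m3"] == ord$bin_of["m4"])
  # a group collapsing entirely is a degenerate single-position map
  rf0 <- matrix(0.001, 3, 3, dimnames = list(nm[1:3], nm[1:3]))
  diag(rf0) <- 0
  expect_warning(
    ord0 <- order_markers(data.frame(marker = nm[1:3], pos = 1:3 * 10),
                          pairs_from_rf(rf0)),
    "single bin")
  expect_equal(ord0$total_length_cm, 0)
})

test_that("sex-specific positions follow role-resolved adjacent recombination", {
  # family 1: dam-informative pair with 5/50 recombinants (female rf 0.1);
  # family 2: sire-informative pair with 0/50 recombinants (male rf 0)
  off1 <- rbind(rep(0L, 50), c(rep(1L, 5), rep(0L, 45)))
  off2 <- rbind(rep(0L, 50), rep(0L, 50))
  ids1 <- sprintf("a%02d", 1:50)
  ids2 <- sprintf("b%02d", 1:50)
  colnames(off1) <- ids1
  colnames(off2) <- ids2
  geno <- cbind(off1, off2, s1 = c(0L, 0L), d1 = c(1L, 1L),
                s2 = c(1L, 1L), d2 = c(0L, 0L))
  markers <- data.frame(marker = c("m1", "m2"), chrom = "c",
                        pos = c(1e5, 2e5), stringsAsFactors = FALSE)
  rownames(geno) <- markers$marker
  ped <- rbind(data.frame(family_id = "f1", offspring_id = ids1,
                          dam_id = "d1", sire_id = "s1"),
               data.frame(family_id = "f2", offspring_id = ids2,
                          dam_id = "d2", sire_id = "s2"))
  gm <- genotype_matrix(geno, markers, ped,
                        parent_ids = c("s1", "d1", "s2", "d2"))
  tr <- marker_transmissions(gm)
  m <- estimate_map_positions(c("m1", "m2"), tr)
  expect_equal(m$female_cm, c(0, kosambi(0.1)), tolerance = 1e-9)
  expect_equal(m$female_cm[2], 10.137, tolerance = 1e-3)
  expect_equal(m$male_cm, c(0, 0))
  expect_equal(m$avg_cm[2], kosambi(5 / 100), tolerance = 1e-9)

  # map length is invariant under order reversal
  mr <- estimate_map_positions(c("m2", "m1"), tr)
  expect_equal(attr(mr, "lengths"), attr(m, "lengths"))
})

test_that("zero recombinants everywhere yield maps of length zero", {
  models <- toy_models(1, female = 0, male = 0)
  parents <- simulate_parents(20, models, seed = 71)
  fam <- simulate_family(family_design("F1", "dam", "sire", 40),
                         parents, models, seed = 72)
  tr <- marker_transmissions(fam$geno)
  mk <- fam$geno$markers
  m <- estimate_map_positions(mk$marker[order(mk$pos)], tr)
  l <- attr(m, "lengths")
  expect_equal(l$female, 0)
  expect_equal(l$male, 0)
  expect_equal(l$avg, 0)
})
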