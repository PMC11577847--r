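# --- independent grid-search oracle for the two-point likelihood ---------

oracle_two_point <- function(gm, i, j, grid = seq(0, 0.5, by = 1e-4)) {
  ped <- unique(gm$pedigree[, c("family_id", "dam_id", "sire_id")])
  kids_of <- split(gm$pedigree$offspring_id, gm$pedigree$family_id)
  het <- function(g) !is.na(g) & g == 1L
  # transmitted allele (0/1/NA) of `parent` given its own and the other
  # parent's genotype and the offspring dosage
  decode <- function(off, pg, og) {
    if (!het(pg) || is.na(og)) return(rep(NA_integer_, length(off)))
    out <- rep(NA_integer_, length(off))
    if (og == 0L) { out[off == 0L] <- 0L; out[off == 1L] <- 1L }
    if (og == 2L) { out[off == 1L] <- 0L; out[off == 2L] <- 1L }
    if (og == 1L) { out[off == 0L] <- 0L; out[off == 2L] <- 1L }
    out
  }
  gamete_probs <- function(r, cfg) {
    # rows: haplotype (allele at i, allele at j); coupling = A-A / B-B
    p <- if (cfg == 1) c(`00` = (1 - r) / 2, `11` = (1 - r) / 2,
                         `01` = r / 2, `10` = r / 2)
    else c(`00` = r / 2, `11` = r / 2, `01` = (1 - r) / 2, `10` = (1 - r) / 2)
    p
  }
  loglik <- function(r) {
    ll <- 0
    for (f in seq_len(nrow(ped))) {
      kids <- kids_of[[ped$family_id[f]]]
      s <- gm$geno[, ped$sire_id[f]]
      d <- gm$geno[, ped$dam_id[f]]
      oi <- gm$geno[i, kids]; oj <- gm$geno[j, kids]
      if (het(s[i]) && het(s[j]) && het(d[i]) && het(d[j])) {
        ok <- !is.na(oi) & !is.na(oj)
        if (!any(ok)) next
        tab <- table(factor(oi[ok], 0:2), factor(oj[ok], 0:2))
        best <- -Inf
        haps <- list(`00` = c(0, 0), `01` = c(0, 1),
                     `10` = c(1, 0), `11` = c(1, 1))
        for (c1 in 1:2) for (c2 in 1:2) {
          P <- matrix(0, 3, 3)
          g1 <- gamete_probs(r, c1); g2 <- gamete_probs(r, c2)
          for (h1 in names(haps)) for (h2 in names(haps)) {
            di <- haps[[h1]][1] + haps[[h2]][1]
            dj <- haps[[h1]][2] + haps[[h2]][2]
            P[di + 1, dj + 1] <- P[di + 1, dj + 1] + g1[h1] * g2[h2]
          }
          lp <- sum(ifelse(tab > 0, tab * log(pmax(P, 1e-300)), 0))
          best <- max(best, lp)
        }
        ll <- ll + best
      } else {
        for (role in c("sire", "dam")) {
          pg <- if (role == "sire") s else d
          og <- if (role == "sire") d else s
          ti <- decode(oi, pg[i], og[i])
          tj <- decode(oj, pg[j], og[j])
          ok <- !is.na(ti) & !is.na(tj)
          n <- sum(ok)
          if (n == 0) next
          mis <- sum(ti[ok] != tj[ok])
          k <- min(mis, n - mis)  # likelihood-maximizing phase
          term <- function(a, b) (if (a > 0) a * log(b) else 0)
          ll <- ll + term(k, r) + term(n - k, 1 - r)
        }
      }
    }
    ll
  }
  lls <- vapply(grid, loglik, 0)
  best <- which.max(lls)
  list(rf = grid[best], lod = (lls[best] - loglik(0.5)) / log(10))
}

# random two-marker family with known cross configuration
random_pair_gm <- function(codes, n_off, r_true, seed) {
  set.seed(seed)
  n_fam <- length(codes)
  geno_cols <- list()
  ped <- list()
  markers <- data.frame(marker = c("m1", "m2"), chrom = "c",
                        pos = c(1000, 2000), stringsAsFactors = FALSE)
  parent_geno <- list()
  for (f in seq_len(n_fam)) {
    code <- codes[f]
    sire <- if (code %in% c(1, 3)) c(1L, 1L) else c(0L, 2L)
    dam <- if (code %in% c(2, 3)) c(1L, 1L) else c(2L, 0L)
    gam <- function(parent_gt) {
      if (all(parent_gt == 1L)) {
        phase <- sample(0:1, 1)            # 0 coupling, 1 repulsion
        a1 <- sample(0:1, n_off, replace = TRUE)
        rec <- rbinom(n_off, 1, r_true)
        a2 <- ifelse(rec, 1 - a1, a1)
        if (phase) a2 <- 1 - a2
        rbind(a1, a2)
      } else {
        rbind(rep(parent_gt[1] / 2, n_off), rep(parent_gt[2] / 2, n_off))
      }
    }
    gs <- gam(sire); gd <- gam(dam)
    off <- gs + gd
    storage.mode(off) <- "integer"
    ids <- sprintf("f%d_o%02d", f, seq_len(n_off))
    colnames(off) <- ids
    geno_cols[[f]] <- off
    parent_geno[[paste0("s", f)]] <- sire
    parent_geno[[paste0("d", f)]] <- dam
    ped[[f]] <- data.frame(family_id = paste0("f", f), offspring_id = ids,
                           dam_id = paste0("d", f), sire_id = paste0("s", f),
                           stringsAsFactors = FALSE)
  }
  geno <- do.call(cbind, c(geno_cols, list(do.call(cbind, parent_geno))))
  rownames(geno) <- markers$marker
  genotype_matrix(geno, markers, do.call(rbind, ped),
                  parent_ids = names(parent_geno))
}


# pairs structure for hand-specified recombination fractions
pairs_from_rf <- function(rf, n = 1000) {
  k <- rf * n
  nn <- matrix(n, nrow(rf), ncol(rf), dimnames = dimnames(rf))
  diag(nn) <- 0
  list(k = k, n = nn, rf = rf,
       lod = matrix(50, nrow(rf), ncol(rf), dimnames = dimnames(rf)))
}


# a sex_map-shaped data.frame with all three cM columns equal
make_map <- function(cm, pos = NULL) {
  n <- length(cm)
  if (is.null(pos)) pos <- seq_len(n) * 1e5
  out <- data.frame(marker = paste0("m", seq_len(n)), chrom = "c", pos = pos,
                    female_cm = cm, male_cm = cm, avg_cm = cm,
                    stringsAsFactors = FALSE)
  attr(out, "lengths") <- list(female = max(cm), male = max(cm),
                               avg = max(cm))
  class(out) <- c("sex_map", "data.frame")
  out
}

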