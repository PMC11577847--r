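#' Kosambi mapping function and its inverse
#'
#' Converts a recombination fraction to an additive map distance allowing for
#' partial crossover interference: d_cM = 25 * ln((1 + 2r) / (1 - 2r));
#' the inverse is r = tanh(d_cM / 50) / 2.
#'
#' @param rf Recombination fraction(s) in `[0, 0.5)`.
#' @return `kosambi`: map distance in centimorgans; `kosambi_inv`: the
#'   recombination fraction for a distance `d_cm >= 0`.
#' @examples
#' kosambi(0.1)          # 10.137 cM
#' kosambi_inv(kosambi(0.25))
#' @export
kosambi <- function(rf) {
  if (any(rf < 0, na.rm = TRUE)) stop("recombination fraction must be >= 0")
  if (any(rf >= 0.5, na.rm = TRUE))
    stop("recombination fraction must be < 0.5 (infinite map distance)")
  25 * log((1 + 2 * rf) / (1 - 2 * rf))
}

#' @rdname kosambi
#' @param d_cm Map distance(s) in centimorgans (>= 0).
#' @export
kosambi_inv <- function(d_cm) {
  if (any(d_cm < 0, na.rm = TRUE)) stop("map distance must be >= 0")
  tanh(d_cm / 50) / 2
}

#' Per-parent gamete transmissions of a full-sib genotype matrix
#'
#' For every (parent, meiotic role) pair in the pedigree, decodes which
#' parental allele each offspring received at every marker heterozygous in
#' that parent. Transmissions are coded +1/-1 for the two alleles and 0 when
#' undecidable (offspring missing, Mendelian-inconsistent, or an ambiguous
#' double heterozygote of an AB x AB marker). The parental phase is unknown at
#' this stage; pairwise methods resolve it by likelihood.
#'
#' @param gm A [genotype_matrix()] with genotyped parents.
#' @return An object of class `transmissions`: a list of per-(parent, role)
#'   streams, each holding the informative marker indices and the
#'   transmission matrix over that parent's meioses, plus a reference to `gm`.
#' @export
marker_transmissions <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ped <- gm$pedigree
  combos <- unique(rbind(
    data.frame(parent = ped$dam_id, role = "female", stringsAsFactors = FALSE),
    data.frame(parent = ped$sire_id, role = "male", stringsAsFactors = FALSE)))
  streams <- list()
  for (i in seq_len(nrow(combos))) {
    parent <- combos$parent[i]
    role <- combos$role[i]
    fams <- ped[if (role == "female") ped$dam_id == parent else
      ped$sire_id == parent, , drop = FALSE]
    pg <- gm$geno[, parent]
    inf <- which(!is.na(pg) & pg == 1L)
    if (!length(inf)) next
    blocks <- list()
    cols <- character(0)
    fam_of_col <- character(0)
    fids <- unique(fams$family_id)
    other_het <- matrix(FALSE, length(inf), length(fids),
                        dimnames = list(NULL, fids))
    for (fid in fids) {
      fr <- fams[fams$family_id == fid, ][1, ]
      other <- if (role == "female") fr$sire_id else fr$dam_id
      og <- gm$geno[inf, other]
      kids <- ped$offspring_id[ped$family_id == fid]
      O <- gm$geno[inf, kids, drop = FALSE]
      t <- matrix(0L, length(inf), length(kids))
      o0 <- !is.na(og) & og == 0L
      o1 <- !is.na(og) & og == 1L
      o2 <- !is.na(og) & og == 2L
      other_het[, fid] <- o1
      lo <- O[o0, , drop = FALSE]
      t[o0, ] <- (lo == 0L) * -1L + (lo == 1L) * 1L
      lo <- O[o1, , drop = FALSE]
      t[o1, ] <- (lo == 0L) * -1L + (lo == 2L) * 1L
      lo <- O[o2, , drop = FALSE]
      t[o2, ] <- (lo == 1L) * -1L + (lo == 2L) * 1L
      t[is.na(t)] <- 0L
      blocks[[fid]] <- t
      cols <- c(cols, kids)
      fam_of_col <- c(fam_of_col, rep(fid, length(kids)))
    }
    T <- do.call(cbind, blocks)
    colnames(T) <- cols
    streams[[length(streams) + 1L]] <-
      list(parent = parent, role = role, markers = inf, T = T,
           family = fam_of_col, other_het = other_het)
  }
  structure(list(streams = streams, gm = gm), class = "transmissions")
}

# two-point LOD from phase-resolved recombinant counts k out of n gametes
lod_from_counts <- function(k, n) {
  lod <- n * log10(2)
  pos <- n > 0 & k > 0
  r <- ifelse(n > 0, k / n, 0)
  lod[pos] <- lod[pos] + k[pos] * log10(r[pos]) +
    (n[pos] - k[pos]) * log10(1 - r[pos])
  lod[n == 0] <- 0
  lod
}

#' Two-point LOD / recombination-fraction matrices for all marker pairs
#'
#' Vectorized two-point analysis over all (parent, role) transmission streams:
#' for each pair the phase is resolved to the likelihood-maximizing
#' assignment (recombinants = `min(mismatches, matches)`) per stream, with
#' mismatch counts pooled across a parent's families before phase resolution
#' (one physical parent has one phase), and per-stream LOD scores are summed
#' across parents.
#'
#' For a pair where both markers are AB x AB within the same family, a
#' parent's transmissions are only known for offspring homozygous at both
#' markers, and that double conditioning is recombination-dependent (it
#' enriches or depletes recombinants depending on the parental phases). Such
#' contributions are therefore excluded from the recombination-fraction
#' counts (`k`/`n`/`rf`) used for binning, ordering and map distances; they
#' are retained in the LOD matrix, where linked pairs still produce valid
#' positive evidence and unlinked pairs stay near 0. The exact single-pair
#' likelihood (EM over the ambiguous double heterozygotes) is available in
#' [pairwise_rf_lod()].
#'
#' @param tr A [marker_transmissions()] object.
#' @return List of markers x markers matrices: `lod`, `k` (pooled recombinant
#'   gametes), `n` (pooled informative meioses) and `rf` (pooled `k/n`,
#'   `NA` where `n = 0`); dimnames are marker names, diagonals zeroed.
#' @export
pairwise_lod_matrix <- function(tr) {
  stopifnot(inherits(tr, "transmissions"))
  p <- nrow(tr$gm$geno)
  nm <- tr$gm$markers$marker
  LOD <- matrix(0, p, p, dimnames = list(nm, nm))
  K <- matrix(0, p, p, dimnames = list(nm, nm))
  N <- matrix(0, p, p, dimnames = list(nm, nm))
  for (s in tr$streams) {
    m <- length(s$markers)
    Nall <- matrix(0, m, m)
    Mall <- matrix(0, m, m)
    Nv <- matrix(0, m, m)
    Misv <- matrix(0, m, m)
    for (fid in colnames(s$other_het)) {
      Tf <- s$T[, s$family == fid, drop = FALSE]
      storage.mode(Tf) <- "double"
      A <- abs(Tf)
      Nf <- tcrossprod(A)
      Mf <- tcrossprod(Tf)
      Nall <- Nall + Nf
      Mall <- Mall + Mf
      Misf <- (Nf - Mf) / 2
      H <- s$other_het[, fid]
      if (any(H)) {
        Nf[H, H] <- 0
        Misf[H, H] <- 0
      }
      Nv <- Nv + Nf
      Misv <- Misv + Misf
    }
    idx <- s$markers
    LOD[idx, idx] <- LOD[idx, idx] +
      lod_from_counts((Nall - abs(Mall)) / 2, Nall)
    K[idx, idx] <- K[idx, idx] + pmin(Misv, Nv - Misv)
    N[idx, idx] <- N[idx, idx] + Nv
  }
  diag(LOD) <- 0
  rf <- K / N
  rf[N == 0] <- NA
  diag(rf) <- 0
  list(lod = LOD, k = K, n = N, rf = rf)
}

# offspring dosage-pair class probabilities for an AB x AB / AB x AB pair.
# cfg (per parent): 1 = coupling (haplotypes A-A / B-B), 2 = repulsion.
# gametes are rows of (allele1, allele2, P(gamete), recombinant flag)
f2_gametes <- function(r, cfg) {
  pr <- if (cfg == 1) c((1 - r) / 2, (1 - r) / 2, r / 2, r / 2)
  else c(r / 2, r / 2, (1 - r) / 2, (1 - r) / 2)
  cbind(a1 = c(0, 1, 0, 1), a2 = c(0, 1, 1, 0), p = pr,
        rec = if (cfg == 1) c(0, 0, 1, 1) else c(1, 1, 0, 0))
}

f2_class_probs <- function(r, cfg1, cfg2) {
  g1 <- f2_gametes(r, cfg1)
  g2 <- f2_gametes(r, cfg2)
  P <- matrix(0, 3, 3)
  E <- matrix(0, 3, 3)  # expected recombinant gametes x P(class)
  for (i in 1:4) for (j in 1:4) {
    d1 <- g1[i, "a1"] + g2[j, "a1"]
    d2 <- g1[i, "a2"] + g2[j, "a2"]
    pij <- g1[i, "p"] * g2[j, "p"]
    P[d1 + 1, d2 + 1] <- P[d1 + 1, d2 + 1] + pij
    E[d1 + 1, d2 + 1] <- E[d1 + 1, d2 + 1] +
      pij * (g1[i, "rec"] + g2[j, "rec"])
  }
  list(P = P, E = E)
}

# full two-point log-likelihood at r for stream counts + F2 tables
pair_loglik <- function(r, streams, f2_tables) {
  ll <- 0
  for (s in streams) {
    if (s$n == 0) next
    k <- min(s$k, s$n - s$k)  # likelihood-maximizing phase
    ll <- ll + (if (k > 0) k * log(r) else 0) +
      (if (s$n - k > 0) (s$n - k) * log(1 - r) else 0)
  }
  for (tab in f2_tables) {
    best <- -Inf
    for (c1 in 1:2) for (c2 in 1:2) {
      P <- f2_class_probs(r, c1, c2)$P
      lp <- sum(tab[P > 0] * log(P[P > 0]))
      if (any(tab[P == 0] > 0)) lp <- -Inf
      best <- max(best, lp)
    }
    ll <- ll + best
  }
  ll
}

#' Exact two-point linkage estimate for one marker pair
#'
#' Maximum-likelihood recombination fraction and base-10 LOD score for a pair
#' of markers across all families. Families where both markers are AB x AB use
#' the full 3 x 3 offspring-class likelihood with EM over the ambiguous double
#' heterozygotes (start r = 0.25, stop at a log-likelihood change below 1e-8
#' or 200 iterations), maximizing over the four parental phase
#' configurations; other configurations contribute phase-resolved gamete
#' counts per parental role, and per-family log-likelihoods are summed (shared
#' parents contribute through their own meioses).
#'
#' @param tr A [marker_transmissions()] object.
#' @param marker_i,marker_j Marker names (or row indices).
#' @return List with `marker_i`, `marker_j`, `rf_female`, `rf_male` (pooled
#'   per-role estimates, `NA` without data), `rf_joint`, `lod` and
#'   `n_informative_meioses`. Errors when the pair shares no informative
#'   meiosis.
#' @export
pairwise_rf_lod <- function(tr, marker_i, marker_j) {
  stopifnot(inherits(tr, "transmissions"))
  gm <- tr$gm
  ix <- if (is.character(marker_i)) match(marker_i, gm$markers$marker) else marker_i
  jx <- if (is.character(marker_j)) match(marker_j, gm$markers$marker) else marker_j
  if (is.na(ix) || is.na(jx)) stop("unknown marker")
  ped <- gm$pedigree
  fams <- unique(ped[, c("family_id", "dam_id", "sire_id")])
  f2_fams <- character(0)
  for (f in seq_len(nrow(fams))) {
    ci <- classify_informativeness(gm$geno[ix, fams$sire_id[f]],
                                   gm$geno[ix, fams$dam_id[f]])
    cj <- classify_informativeness(gm$geno[jx, fams$sire_id[f]],
                                   gm$geno[jx, fams$dam_id[f]])
    if (ci == 3L && cj == 3L) f2_fams <- c(f2_fams, fams$family_id[f])
  }
  f2_tables <- lapply(f2_fams, function(fid) {
    kids <- ped$offspring_id[ped$family_id == fid]
    oi <- gm$geno[ix, kids]
    oj <- gm$geno[jx, kids]
    ok <- !is.na(oi) & !is.na(oj)
    tab <- matrix(0, 3, 3)
    if (any(ok)) {
      tt <- table(factor(oi[ok], 0:2), factor(oj[ok], 0:2))
      tab <- matrix(as.numeric(tt), 3, 3)
    }
    tab
  })
  f2_kids <- ped$offspring_id[ped$family_id %in% f2_fams]

  streams <- list()
  role_counts <- list(female = c(k = 0, n = 0), male = c(k = 0, n = 0))
  for (s in tr$streams) {
    pi <- match(ix, s$markers)
    pj <- match(jx, s$markers)
    if (is.na(pi) || is.na(pj)) next
    keep <- !(colnames(s$T) %in% f2_kids)
    ti <- s$T[pi, keep]
    tj <- s$T[pj, keep]
    ok <- ti != 0 & tj != 0
    n <- sum(ok)
    if (n == 0) next
    mis <- sum(ti[ok] != tj[ok])
    streams[[length(streams) + 1L]] <- list(k = mis, n = n)
    kk <- min(mis, n - mis)
    role_counts[[s$role]] <- role_counts[[s$role]] + c(k = kk, n = n)
  }

  n_f2 <- sum(vapply(f2_tables, sum, 0))
  n_gametes <- sum(vapply(streams, `[[`, 0, "n")) + 2 * n_f2
  if (n_gametes == 0) stop("no shared informative meioses for this pair")

  # EM (generalized: parental phase configurations re-maximized per iteration)
  r <- 0.25
  ll_old <- -Inf
  for (it in seq_len(200)) {
    rec <- 0
    for (s in streams) rec <- rec + min(s$k, s$n - s$k)
    for (tab in f2_tables) {
      if (sum(tab) == 0) next
      best_lp <- -Inf
      best_e <- 0
      for (c1 in 1:2) for (c2 in 1:2) {
        pe <- f2_class_probs(max(r, 1e-9), c1, c2)
        lp <- sum(tab[pe$P > 0] * log(pe$P[pe$P > 0]))
        if (any(tab[pe$P == 0] > 0)) lp <- -Inf
        if (lp > best_lp) {
          best_lp <- lp
          cond <- pe$E / pe$P
          cond[pe$P == 0] <- 0
          best_e <- sum(tab * cond)
        }
      }
      rec <- rec + best_e
    }
    r_new <- min(rec / n_gametes, 0.5)
    ll <- pair_loglik(max(r_new, 1e-12), streams, f2_tables)
    if (abs(ll - ll_old) < 1e-8) { r <- r_new; break }
    r <- r_new
    ll_old <- ll
  }
  r_hat <- r
  ll_hat <- pair_loglik(max(r_hat, 1e-12), streams, f2_tables)
  ll_null <- pair_loglik(0.5, streams, f2_tables)
  rc <- lapply(role_counts, function(x)
    if (x["n"] > 0) unname(x["k"] / x["n"]) else NA_real_)
  list(marker_i = gm$markers$marker[ix], marker_j = gm$markers$marker[jx],
       rf_female = rc$female, rf_male = rc$male,
       rf_joint = r_hat, lod = (ll_hat - ll_null) / log(10),
       n_informative_meioses = n_gametes)
}

#' Assign markers to linkage groups by single-linkage at a LOD threshold
#'
#' Markers joined by any pairwise LOD at or above the threshold fall into the
#' same group (transitive closure); groups below the minimal size are
#' dissolved back to the unassigned pool.
#'
#' @param lod A markers x markers LOD matrix (from [pairwise_lod_matrix()]) or
#'   a data.frame with columns `marker_i`, `marker_j`, `lod`.
#' @param lod_threshold Minimum LOD to link two markers (e.g. 11 for a single
#'   large family, 5 for multi-family data).
#' @param min_size Minimal group size retained (default 5).
#' @param markers Optional character vector of all marker names (needed when
#'   `lod` is a pair table that omits isolated markers).
#' @return List with `groups` (named list of marker-name vectors, largest
#'   first, labelled LG1, LG2, ...) and `unassigned`.
#' @export
group_markers <- function(lod, lod_threshold, min_size = 5, markers = NULL) {
  if (is.data.frame(lod)) {
    if (is.null(markers))
      markers <- unique(c(lod$marker_i, lod$marker_j))
    edges <- lod[lod$lod >= lod_threshold, c("marker_i", "marker_j")]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = markers))
  } else {
    markers <- rownames(lod)
    sel <- which(lod >= lod_threshold & upper.tri(lod), arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = markers[sel[, 1]], to = markers[sel[, 2]]),
      directed = FALSE, vertices = data.frame(name = markers))
  }
  comp <- igraph::components(g)
  member <- split(markers, comp$membership[markers])
  sizes <- lengths(member)
  big <- member[sizes >= min_size]
  big <- big[order(-lengths(big))]
  names(big) <- if (length(big)) paste0("LG", seq_along(big)) else character(0)
  list(groups = big,
       unassigned = unlist(member[sizes < min_size], use.names = FALSE))
}

#' Iteratively add unassigned markers to existing linkage groups
#'
#' A marker joins the group holding its best single-pair LOD when that LOD
#' reaches `lod_limit` and exceeds the best LOD to any other group by at least
#' `lod_difference`; assignment repeats until a fixed point.
#'
#' @param groups Named list of marker-name vectors (from [group_markers()]).
#' @param unassigned Character vector of unassigned markers.
#' @param lod markers x markers LOD matrix.
#' @param lod_limit,lod_difference Joining thresholds (defaults 2 and 2).
#' @return Updated list as in [group_markers()].
#' @export
rescue_unassigned <- function(groups, unassigned, lod,
                              lod_limit = 2, lod_difference = 2) {
  repeat {
    if (!length(unassigned) || !length(groups)) break
    moved <- FALSE
    for (m in unassigned) {
      best <- vapply(groups, function(g) max(lod[m, g]), 0)
      o <- order(-best)
      second <- if (length(best) > 1) best[o[2]] else 0
      if (best[o[1]] >= lod_limit && best[o[1]] - second >= lod_difference) {
        groups[[o[1]]] <- c(groups[[o[1]]], m)
        unassigned <- setdiff(unassigned, m)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(groups = groups, unassigned = unassigned)
}

# all permutations of 1..n (n small)
perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

#' Order markers within a linkage group
#'
#' Markers closer than `identical_limit` in recombination fraction are
#' collapsed into bins; bins are seeded in physical order (`use_physical`) and
#' refined by permutation search minimizing the total Kosambi map length over
#' adjacent bins plus a physical-order prior: each adjacent bin pair placed
#' against the physical coordinate order costs `phys_penalty_cm`, so the
#' search only deviates from the assembly order where the linkage evidence
#' outweighs the prior (the role played by the small usePhysical weight in
#' array mapping pipelines; two-point distances at array densities are too
#' noisy to resolve local order unaided). Groups of up to 6 bins are solved
#' exhaustively; larger groups use a sliding-window (size 4) local
#' permutation search iterated to a fixed point, deterministic given the
#' seed.
#'
#' @param markers data.frame with `marker` and `pos` (bp) for the group.
#' @param pairs Output of [pairwise_lod_matrix()] (uses `k`, `n`).
#' @param identical_limit Recombination fraction below which markers collapse
#'   into one bin (default 0.005).
#' @param use_physical Seed the search from physical order and apply the
#'   physical-order prior (default); `FALSE` starts from the input order with
#'   no prior (pure minimum-length ordering).
#' @param phys_penalty_cm Prior cost (cM) per physically discordant adjacent
#'   bin pair when `use_physical` is on.
#' @param seed,window,max_passes Search parameters.
#' @return List with `order` (marker names, bins expanded in physical order),
#'   `bin_of` (bin index per marker), `bin_order`, `total_length_cm` and `rf`
#'   (ordered bin-adjacent recombination fractions).
#' @export
order_markers <- function(markers, pairs, identical_limit = 0.005,
                          use_physical = TRUE, phys_penalty_cm = 5,
                          seed = 42L, window = 4L, max_passes = 30L) {
  stopifnot(nrow(markers) >= 2)
  ids <- markers$marker
  K <- pairs$k[ids, ids, drop = FALSE]
  N <- pairs$n[ids, ids, drop = FALSE]
  rf <- K / N
  rf[N == 0] <- NA

  # collapse near-identical markers into bins: walk the seed order and
  # extend the current bin while the candidate is closer than the identical
  # limit to every bin member (complete linkage over contiguous runs; single
  # linkage would percolate through sampling zeros at array densities, and
  # non-contiguous bins would interleave physically on expansion)
  walk <- if (use_physical) order(markers$pos) else seq_along(ids)
  bin_of <- integer(length(ids))
  members <- walk[1]
  b <- 1L
  bin_of[walk[1]] <- 1L
  for (i in walk[-1]) {
    rr <- rf[i, members]
    if (all(!is.na(rr) & rr < identical_limit)) {
      members <- c(members, i)
    } else {
      b <- b + 1L
      members <- i
    }
    bin_of[i] <- b
  }
  nb <- b
  if (nb == 1) {
    warning("all markers collapse into a single bin; degenerate map")
    ord <- ids[order(markers$pos)]
    return(list(order = ord, bin_of = stats::setNames(rep(1L, length(ids)), ids),
                bin_order = 1L, total_length_cm = 0,
                rf = numeric(0)))
  }
  # pooled counts between bins
  B <- matrix(0, length(ids), nb)
  B[cbind(seq_along(ids), bin_of)] <- 1
  Kb <- t(B) %*% K %*% B
  Nb <- t(B) %*% N %*% B
  rb <- Kb / Nb
  rb[Nb == 0] <- NA
  bin_pos <- vapply(seq_len(nb), function(b)
    stats::median(markers$pos[bin_of == b]), 0)

  cap <- 0.4999
  D <- kosambi(pmin(rb, cap))
  # pairs with no shared informative meioses (e.g. a sire-only next to a
  # dam-only marker) have unknown distance: fill by shortest paths through
  # markers linked to both, so the search is not biased against such
  # adjacencies; measured distances are kept as measured
  if (anyNA(D)) {
    Dm <- D
    Dm[is.na(Dm)] <- Inf
    diag(Dm) <- 0
    for (kk in seq_len(nb)) {
      via <- outer(Dm[, kk], Dm[kk, ], `+`)
      Dm <- pmin(Dm, via)
    }
    Dm[!is.finite(Dm)] <- kosambi(cap)
    D[is.na(D)] <- Dm[is.na(D)]
  }
  diag(D) <- 0
  # physical-order prior: directed penalty for bp-descending adjacencies
  if (use_physical && phys_penalty_cm > 0) {
    P <- (outer(bin_pos, bin_pos, `>`)) * phys_penalty_cm
    D <- D + P
  }
  tot <- function(o) sum(D[cbind(o[-length(o)], o[-1])])

  ord <- if (use_physical) order(bin_pos) else seq_len(nb)
  set.seed(seed)
  if (nb <= 6) {
    pp <- perms(nb)
    lens <- apply(pp, 1, tot)
    ord <- pp[which.min(lens), ]
  } else {
    w <- min(window, nb)
    pw <- perms(w)
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (s in seq_len(nb - w + 1)) {
        seg <- s:(s + w - 1)
        pre <- if (s > 1) ord[s - 1] else NA
        post <- if (s + w <= nb) ord[s + w] else NA
        seg_len <- function(v) {
          l <- sum(D[cbind(v[-length(v)], v[-1])])
          if (!is.na(pre)) l <- l + D[pre, v[1]]
          if (!is.na(post)) l <- l + D[v[length(v)], post]
          l
        }
        cur <- ord[seg]
        base_len <- seg_len(cur)
        cand <- apply(pw, 1, function(p) seg_len(cur[p]))
        b <- which.min(cand)
        if (cand[b] < base_len - 1e-12) {
          ord[seg] <- cur[pw[b, ]]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  # canonical orientation: positive correlation with physical position
  if (stats::cor(seq_len(nb), bin_pos[ord]) < 0) ord <- rev(ord)

  adj_rf <- rb[cbind(ord[-nb], ord[-1])]
  marker_order <- unlist(lapply(ord, function(b) {
    mm <- ids[bin_of == b]
    mm[order(markers$pos[match(mm, ids)])]
  }), use.names = FALSE)
  list(order = marker_order,
       bin_of = stats::setNames(bin_of, ids),
       bin_order = ord, total_length_cm = tot(ord), rf = adj_rf)
}

#' Sex-specific map positions along an ordered linkage group
#'
#' Adjacent recombination fractions are estimated separately from the
#' female-role (dam) and male-role (sire) meioses and accumulated as Kosambi
#' distances. Each sex's chain links consecutive markers informative for that
#' role through valid anchor pairs: a link is used only when it rests on at
#' least `min_meioses` gametes whose transmissions do not require conditioning
#' on homozygous offspring at both markers (double conditioning at AB x AB /
#' AB x AB pairs is recombination-dependent and would bias the estimate, see
#' [pairwise_lod_matrix()]). Phase is resolved per parent to minimize
#' crossovers, ties keeping the previous phase. Markers that cannot be
#' anchored, or are uninformative for a role, are interpolated between their
#' anchored neighbors. The sex-averaged position pools recombinant counts
#' across both roles per adjacent interval; intervals without a valid pooled
#' count fall back to the mean of the two sex-specific interval spans.
#' Intervals with no information anywhere contribute 0 cM with a warning.
#'
#' @param order Character vector of marker names in map order (e.g. from
#'   [order_markers()]).
#' @param tr A [marker_transmissions()] object.
#' @param min_meioses Minimum valid gametes for a chain link (default 10).
#' @return A data.frame of class `sex_map`: `marker`, `chrom`, `pos` (bp),
#'   `female_cm`, `male_cm`, `avg_cm`, with an attribute `lengths`
#'   (per-sex and averaged total lengths in cM).
#' @export
estimate_map_positions <- function(order, tr, min_meioses = 10) {
  stopifnot(inherits(tr, "transmissions"), length(order) >= 2)
  gm <- tr$gm
  gi <- match(order, gm$markers$marker)
  if (anyNA(gi)) stop("unknown markers in order")
  n <- length(order)

  # pooled valid adjacent counts between positions a and b of the order;
  # mismatches pooled per parent (phase shared across its families) before
  # phase resolution
  pair_counts <- function(a, b, roles) {
    k <- 0; nn <- 0
    for (s in tr$streams) {
      if (!(s$role %in% roles)) next
      pa <- match(gi[a], s$markers)
      pb <- match(gi[b], s$markers)
      if (is.na(pa) || is.na(pb)) next
      mis_s <- 0; n_s <- 0
      for (fid in colnames(s$other_het)) {
        if (s$other_het[pa, fid] && s$other_het[pb, fid]) next
        cols <- s$family == fid
        ta <- s$T[pa, cols]; tb <- s$T[pb, cols]
        ok <- ta != 0 & tb != 0
        m <- sum(ok)
        if (m == 0) next
        mis_s <- mis_s + sum(ta[ok] != tb[ok])
        n_s <- n_s + m
      }
      if (n_s == 0) next
      k <- k + min(mis_s, n_s - mis_s)
      nn <- nn + n_s
    }
    c(k = k, n = nn)
  }
  informative_for <- function(role) {
    inf <- rep(FALSE, n)
    for (s in tr$streams) {
      if (s$role != role) next
      pos <- match(gi, s$markers)
      has <- !is.na(pos)
      has[has] <- rowSums(s$T[pos[has], , drop = FALSE] != 0) > 0
      inf <- inf | has
    }
    inf
  }
  zero_info <- 0L
  role_positions <- function(role) {
    inf <- which(informative_for(role))
    pos <- rep(NA_real_, n)
    if (!length(inf)) return(list(pos = rep(0, n), inf = integer(0)))
    pos[inf[1]] <- 0
    anchor <- inf[1]
    for (i in inf[-1]) {
      cnt <- pair_counts(anchor, i, role)
      if (cnt["n"] >= min_meioses) {
        pos[i] <- pos[anchor] + kosambi(min(cnt["k"] / cnt["n"], 0.49))
        anchor <- i
      }
    }
    placed <- which(!is.na(pos))
    if (length(placed) == 1 && length(inf) > 1) zero_info <<- zero_info + 1L
    pos <- if (length(placed) < 2) rep(0, n) else
      stats::approx(placed, pos[placed], xout = seq_len(n), rule = 2,
                    ties = "ordered")$y
    list(pos = pos, inf = inf)
  }
  fem <- role_positions("female")
  mal <- role_positions("male")

  avg <- numeric(n)
  for (i in seq_len(n - 1)) {
    cnt <- pair_counts(i, i + 1, c("female", "male"))
    d <- if (cnt["n"] >= min_meioses)
      kosambi(min(cnt["k"] / cnt["n"], 0.49))
    else
      mean(c(fem$pos[i + 1] - fem$pos[i], mal$pos[i + 1] - mal$pos[i]))
    avg[i + 1] <- avg[i] + d
  }
  if (zero_info > 0)
    warning(zero_info,
            " map(s) with a single anchored marker; remaining intervals contributed 0 cM")

  out <- data.frame(marker = order,
                    chrom = gm$markers$chrom[gi],
                    pos = gm$markers$pos[gi],
                    female_cm = fem$pos, male_cm = mal$pos, avg_cm = avg,
                    stringsAsFactors = FALSE)
  attr(out, "lengths") <- list(female = max(fem$pos), male = max(mal$pos),
                               avg = max(avg))
  class(out) <- c("sex_map", "data.frame")
  out
}
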