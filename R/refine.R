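#' Trim distal markers separated by large terminal gaps
#'
#' Inflated map ends are a common artifact of residual genotyping error: a
#' handful of terminal markers sit far beyond the rest of the map. Within each
#' terminal window of `ceiling(edge_fraction * n)` markers, consecutive-marker
#' gaps strictly larger than `gap_fraction` of the total cM span are located
#' and every marker distal to the innermost offending gap is removed. After
#' trimming, callers should re-order and re-estimate positions (the pipeline
#' does).
#'
#' @param map A `sex_map` data.frame (see [estimate_map_positions()]).
#' @param edge_fraction Fraction of markers forming each terminal window
#'   (default 0.10).
#' @param gap_fraction Gap threshold as a fraction of the map span
#'   (default 0.05; strictly "more than").
#' @param ends Process `"both"` map ends (default), or only the `"last"` /
#'   `"first"` end.
#' @param column cM column used for gaps (default the sex-averaged map).
#' @return List with `map` (trimmed, cM columns re-zeroed) and `removed`
#'   (marker names). Errors when the map has fewer than 10 markers or
#'   trimming would empty it.
#' @export
trim_edges <- function(map, edge_fraction = 0.10, gap_fraction = 0.05,
                       ends = c("both", "last", "first"),
                       column = "avg_cm") {
  ends <- match.arg(ends)
  n <- nrow(map)
  if (n < 10) stop("edge trimming needs at least 10 markers")
  cm <- map[[column]]
  span <- max(cm) - min(cm)
  w <- ceiling(edge_fraction * n)
  gaps <- diff(cm)  # gaps[i] between marker i and i+1
  thr <- gap_fraction * span
  drop <- logical(n)
  if (ends %in% c("both", "last")) {
    idx <- which(gaps > thr & seq_len(n - 1) >= n - w)  # outer member in window
    if (length(idx)) drop[(min(idx) + 1):n] <- TRUE
  }
  if (ends %in% c("both", "first")) {
    idx <- which(gaps > thr & seq_len(n - 1) <= w)
    if (length(idx)) drop[1:max(idx)] <- TRUE
  }
  if (all(drop)) stop("edge trimming would remove every marker")
  removed <- map$marker[drop]
  out <- map[!drop, , drop = FALSE]
  for (col in c("female_cm", "male_cm", "avg_cm"))
    out[[col]] <- out[[col]] - min(out[[col]])
  rownames(out) <- NULL
  attr(out, "lengths") <- list(female = max(out$female_cm),
                               male = max(out$male_cm),
                               avg = max(out$avg_cm))
  class(out) <- class(map)
  list(map = out, removed = removed)
}

#' Orient a linkage group along its physical coordinates
#'
#' Map orientation is arbitrary after ordering; when 0 cM corresponds to the
#' physical end of the chromosome (negative correlation of genetic with
#' physical position), the marker order is reversed and positions re-zeroed.
#'
#' @param map A `sex_map` data.frame.
#' @return The (possibly flipped) map, with attribute `flipped`.
#' @export
orient_map <- function(map) {
  r <- suppressWarnings(stats::cor(map$avg_cm, map$pos))
  flipped <- isTRUE(!is.na(r) && r < 0)
  if (flipped) {
    out <- map[rev(seq_len(nrow(map))), , drop = FALSE]
    for (col in c("female_cm", "male_cm", "avg_cm"))
      out[[col]] <- max(out[[col]]) - out[[col]]
    rownames(out) <- NULL
    attr(out, "lengths") <- attr(map, "lengths")
    class(out) <- class(map)
    map <- out
  }
  attr(map, "flipped") <- flipped
  map
}

# weighted local polynomial fit (tricube, fraction-of-points neighborhoods);
# returns fitted value and first derivative at each x0. With loo = TRUE
# (x0 must be the data positions) each point is predicted from its
# neighbors only, which is what outlier screening needs: otherwise a
# gross outlier anchors its own fit and hides behind it
local_poly <- function(x, y, x0, span = 0.25, degree = 2, loo = FALSE) {
  n <- length(x)
  if (n < degree + 2 + loo)
    stop("need at least degree + 2 points for a local fit")
  q <- max(degree + 2, ceiling(span * n))
  fit <- deriv <- numeric(length(x0))
  for (i in seq_along(x0)) {
    d <- abs(x - x0[i])
    if (loo) d[i] <- Inf
    nb <- order(d)[seq_len(min(q, n - loo))]
    dmax <- max(d[nb])
    w <- if (dmax == 0) rep(1, length(nb)) else
      (1 - pmin(d[nb] / (dmax * (1 + 1e-9)), 1)^3)^3
    dx <- x[nb] - x0[i]
    X <- stats::poly(dx, degree = degree, raw = TRUE, simple = TRUE)
    X <- cbind(1, X)
    co <- tryCatch(stats::lm.wfit(X, y[nb], w)$coefficients,
                   error = function(e) rep(NA_real_, degree + 1))
    co[is.na(co)] <- 0
    fit[i] <- co[1]
    deriv[i] <- if (degree >= 1) co[2] else 0
  }
  list(fit = fit, deriv = deriv)
}

#' Remove aberrant markers from a Marey track
#'
#' Iteratively fits the LOESS curve (local quadratic, tricube weights) and
#' removes markers whose absolute residual exceeds `threshold_sd` robust
#' standard deviations (MAD) of the residuals, until none remain or
#' `max_iter` iterations.
#'
#' @param track data.frame with `pos` (bp) and a genetic position column.
#' @param column Genetic position column (default `"avg_cm"`, falling back to
#'   `"cm"` if absent).
#' @param threshold_sd Residual threshold in robust SDs (default 3).
#' @param max_iter Maximum cleaning iterations (default 10).
#' @param span,degree LOESS parameters, see [loess_recomb()].
#' @return List with `track` (kept markers), `removed` (row indices into the
#'   input) and `iterations`.
#' @export
clean_marey <- function(track, column = "avg_cm", threshold_sd = 3,
                        max_iter = 10, span = 0.25, degree = 2) {
  if (!column %in% names(track) && "cm" %in% names(track)) column <- "cm"
  if (nrow(track) < 10) stop("Marey cleaning needs at least 10 markers")
  if (stats::sd(track$pos) == 0) {
    warning("all markers at identical position; track returned unchanged")
    return(list(track = track, removed = integer(0), iterations = 0L))
  }
  keep <- seq_len(nrow(track))
  removed <- integer(0)
  it <- 0L
  while (it < max_iter && length(keep) >= degree + 2) {
    it <- it + 1L
    x <- track$pos[keep]
    y <- track[[column]][keep]
    res <- y - local_poly(x, y, x, span, degree, loo = TRUE)$fit
    s <- stats::mad(res)
    if (s == 0) s <- stats::sd(res)
    if (is.na(s)) break
    # an absolute floor keeps floating-point noise on numerically clean
    # tracks from masquerading as aberrance when the robust SD degenerates
    floor_abs <- 1e-8 * max(abs(y), 1)
    bad <- abs(res) > pmax(threshold_sd * s, floor_abs)
    if (!any(bad)) break
    removed <- c(removed, keep[bad])
    keep <- keep[!bad]
  }
  list(track = track[keep, , drop = FALSE], removed = sort(removed),
       iterations = it)
}

#' LOESS-smoothed Marey curve and local recombination rate
#'
#' Local quadratic (degree-2 polynomial) regression of genetic position on
#' physical position with tricube weights over the `span` fraction of nearest
#' markers, evaluated on a physical grid plus the marker positions. The local
#' recombination rate is the analytic first derivative of each local fit,
#' converted to cM/Mb; negative derivatives are clamped to 0.
#'
#' @inheritParams clean_marey
#' @param span Fraction of markers in each local neighborhood (default 0.25).
#' @param degree Local polynomial degree (default 2).
#' @param grid_n Number of evaluation grid points across the chromosome.
#' @return List with `grid` (data.frame `pos`, `cm_fit`, `rate_cm_per_mb`)
#'   and `markers` (fit and residual at each input marker).
#' @export
loess_recomb <- function(track, column = "avg_cm", span = 0.25, degree = 2,
                         grid_n = 100) {
  if (!column %in% names(track) && "cm" %in% names(track)) column <- "cm"
  x <- track$pos
  y <- track[[column]]
  if (length(x) < degree + 2)
    stop("need at least degree + 2 markers for LOESS smoothing")
  grid <- sort(unique(c(seq(min(x), max(x), length.out = grid_n), x)))
  lp <- local_poly(x, y, grid, span, degree)
  rate <- pmax(lp$deriv, 0) * 1e6
  at_markers <- local_poly(x, y, x, span, degree)
  list(grid = data.frame(pos = grid, cm_fit = lp$fit,
                         rate_cm_per_mb = rate),
       markers = data.frame(pos = x, cm = y, fit = at_markers$fit,
                            residual = y - at_markers$fit))
}

#' Write a per-window track as BEDGRAPH
#'
#' @param df data.frame with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the fourth column).
#' @export
write_bedgraph <- function(df, path, value = names(df)[4]) {
  out <- df[, c("chrom", "start", "end", value)]
  utils::write.table(format(out, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
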