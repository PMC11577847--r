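#' Read pairwise alignments in PAF format
#'
#' Parses the 12 mandatory PAF columns plus the `cg:Z` CIGAR and `NM:i` tags
#' when present. Coordinates are 0-based half-open, as in the format.
#'
#' @param path PAF file.
#' @return data.frame with one row per alignment block.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  get_tag <- function(f, tag) {
    hit <- grep(paste0("^", tag, ":"), f[-(1:12)], value = TRUE)
    if (length(hit)) sub("^[^:]+:[^:]+:", "", hit[1]) else NA_character_
  }
  out <- data.frame(
    qname = vapply(fields, `[[`, "", 1),
    qlen = as.numeric(vapply(fields, `[[`, "", 2)),
    qstart = as.numeric(vapply(fields, `[[`, "", 3)),
    qend = as.numeric(vapply(fields, `[[`, "", 4)),
    strand = vapply(fields, `[[`, "", 5),
    tname = vapply(fields, `[[`, "", 6),
    tlen = as.numeric(vapply(fields, `[[`, "", 7)),
    tstart = as.numeric(vapply(fields, `[[`, "", 8)),
    tend = as.numeric(vapply(fields, `[[`, "", 9)),
    nmatch = as.numeric(vapply(fields, `[[`, "", 10)),
    alen = as.numeric(vapply(fields, `[[`, "", 11)),
    mapq = as.numeric(vapply(fields, `[[`, "", 12)),
    cigar = vapply(fields, get_tag, "", "cg"),
    nm = as.numeric(vapply(fields, get_tag, "", "NM")),
    stringsAsFactors = FALSE)
  out
}

#' Read gene intervals from BED or GFF3
#'
#' BED input is used as-is (0-based half-open); GFF3 `gene` features are
#' converted to the same convention. Intervals are returned on the target
#' genome coordinate system used by [split_alignments_at_genes()].
#'
#' @param path BED (>= 4 columns: chrom, start, end, name) or GFF3 file.
#' @return data.frame with `gene`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_gene_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  if (!is.null(gr$type) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  name <- gr$name %||% gr$ID %||% gr$gene_id %||%
    paste0("gene", seq_along(gr))
  data.frame(gene = as.character(name),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

parse_cigar <- function(cigar) {
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1) stop("unparsable CIGAR string")
  tok <- regmatches(cigar, gregexpr("(\\d+)([MIDNSHP=X])", cigar))[[1]]
  list(len = as.numeric(sub("[A-Z=]$", "", tok)),
       op = sub("^\\d+", "", tok))
}

#' Split alignment blocks at gene coordinates and tally matches/mismatches
#'
#' Walks each block's CIGAR over target-genome coordinates and accrues `=`
#' (match) and `X` (mismatch) bases to every overlapping gene; a gene spanning
#' several blocks aggregates across them. Blocks whose CIGAR uses plain `M`
#' are handled through the `NM` tag by distributing the block's substitution
#' count proportionally over its aligned bases (an approximation, exact when
#' a gene covers the whole block); blocks with neither `=`/`X` nor `NM` raise
#' an error.
#'
#' @param paf data.frame from [read_paf()].
#' @param genes data.frame from [read_gene_intervals()] (target coordinates,
#'   0-based half-open).
#' @return data.frame with `gene`, `aligned`, `matches`, `mismatches`;
#'   genes overlapping no block have zero aligned bases (identity missing).
#' @export
split_alignments_at_genes <- function(paf, genes) {
  matches <- stats::setNames(numeric(nrow(genes)), genes$gene)
  mism <- stats::setNames(numeric(nrow(genes)), genes$gene)
  aligned <- stats::setNames(numeric(nrow(genes)), genes$gene)
  gene_ir <- split(IRanges::IRanges(start = genes$start + 1L,
                                    end = genes$end,
                                    names = genes$gene),
                   genes$chrom)
  for (b in seq_len(nrow(paf))) {
    if (!paf$tname[b] %in% names(gene_ir)) next
    gir <- gene_ir[[paf$tname[b]]]
    if (is.na(paf$cigar[b])) {
      if (is.na(paf$nm[b]))
        stop("identity not computable: no cg:Z CIGAR and no NM tag")
      ops <- list(len = paf$tend[b] - paf$tstart[b], op = "M")
    } else {
      ops <- parse_cigar(paf$cigar[b])
    }
    if (!any(ops$op %in% c("=", "X")) && any(ops$op == "M") &&
        is.na(paf$nm[b]))
      stop("identity not computable: CIGAR lacks =/X and no NM tag")
    consumes_t <- ops$op %in% c("M", "=", "X", "D", "N")
    t_end <- paf$tstart[b] + cumsum(ifelse(consumes_t, ops$len, 0))
    t_start <- t_end - ifelse(consumes_t, ops$len, 0)
    use_nm <- any(ops$op == "M")
    if (use_nm) {
      mm_total <- paf$nm[b] - sum(ops$len[ops$op %in% c("I", "D", "N")])
      mm_total <- max(mm_total, 0)
      m_bases <- sum(ops$len[ops$op == "M"])
      mm_frac <- if (m_bases > 0) mm_total / m_bases else 0
    }
    sub_ops <- which(ops$op %in% c("=", "X", "M") & ops$len > 0)
    if (!length(sub_ops)) next
    op_ir <- IRanges::IRanges(start = t_start[sub_ops] + 1L,
                              end = t_end[sub_ops])
    hits <- IRanges::findOverlaps(op_ir, gir)
    if (!length(hits)) next
    ov <- IRanges::width(IRanges::pintersect(
      op_ir[S4Vectors::queryHits(hits)], gir[S4Vectors::subjectHits(hits)]))
    gene_name <- names(gir)[S4Vectors::subjectHits(hits)]
    op_type <- ops$op[sub_ops][S4Vectors::queryHits(hits)]
    add <- function(vec, idx, val) {
      agg <- rowsum(val, idx)
      vec[rownames(agg)] <- vec[rownames(agg)] + agg[, 1]
      vec
    }
    aligned <- add(aligned, gene_name, ov)
    is_eq <- op_type == "="
    is_x <- op_type == "X"
    is_m <- op_type == "M"
    if (any(is_eq)) matches <- add(matches, gene_name[is_eq], ov[is_eq])
    if (any(is_x)) mism <- add(mism, gene_name[is_x], ov[is_x])
    if (any(is_m)) {
      matches <- add(matches, gene_name[is_m], ov[is_m] * (1 - mm_frac))
      mism <- add(mism, gene_name[is_m], ov[is_m] * mm_frac)
    }
  }
  data.frame(gene = genes$gene, aligned = unname(aligned[genes$gene]),
             matches = unname(matches[genes$gene]),
             mismatches = unname(mism[genes$gene]),
             stringsAsFactors = FALSE)
}

#' Gene-level percent identity from match/mismatch tallies
#'
#' `100 * matches / (matches + mismatches)`; alignment gaps are excluded from
#' the denominator. Genes with no aligned substitution columns get `NA`.
#'
#' @param tally data.frame from [split_alignments_at_genes()].
#' @return The input with a `percent_identity` column appended.
#' @export
percent_identity <- function(tally) {
  denom <- tally$matches + tally$mismatches
  tally$percent_identity <- ifelse(denom > 0,
                                   100 * tally$matches / denom, NA_real_)
  tally
}

#' Flag low-identity outlier genes by the Q1 - 3 IQR rule
#'
#' Quartiles use linear interpolation (R's default type-7 quantiles); values
#' strictly below `Q1 - 3 * (Q3 - Q1)` are flagged. With identical values the
#' IQR is 0 and nothing is flagged (strict inequality).
#'
#' @param identities Numeric vector (NAs ignored; at least 4 non-missing
#'   values required).
#' @return List with `is_outlier` (logical, NA-preserving), `threshold`,
#'   `q1`, `q3`.
#' @export
iqr_outliers <- function(identities) {
  x <- identities[!is.na(identities)]
  if (length(x) < 4) stop("need at least 4 values for quartile estimation")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  thr <- q[1] - 3 * (q[2] - q[1])
  list(is_outlier = identities < thr, threshold = thr, q1 = q[1], q3 = q[2])
}

#' Convert Kimura substitution level to Jukes-Cantor distance
#'
#' `JC = -3/4 * log(1 - 4 d / 3)` (natural log); defined for `0 <= d < 0.75`
#' and saturating at 0.75. `jc_to_kimura` is the inverse,
#' `d = 3/4 * (1 - exp(-4 jc / 3))`.
#'
#' @param d Kimura distances in `[0, 0.75)`.
#' @return Jukes-Cantor distances (`kimura_to_jc`) or Kimura distances
#'   (`jc_to_kimura`).
#' @export
kimura_to_jc <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be >= 0")
  if (any(d >= 0.75, na.rm = TRUE))
    stop("Jukes-Cantor correction saturates at d = 0.75")
  -0.75 * log(1 - 4 * d / 3)
}

#' @rdname kimura_to_jc
#' @param jc Jukes-Cantor distances (>= 0).
#' @export
jc_to_kimura <- function(jc) {
  if (any(jc < 0, na.rm = TRUE)) stop("distance must be >= 0")
  0.75 * (1 - exp(-4 * jc / 3))
}

#' Repeat landscape: genome coverage per class per divergence bin
#'
#' Assigns each repeat copy's base-pair span to the Jukes-Cantor distance bin
#' of its divergence and reports the percent of the genome covered per repeat
#' class per bin, plus the low-divergence subset used for recent-insertion
#' insets.
#'
#' @param elements data.frame with `class`, `span_bp` and `jc` (Jukes-Cantor
#'   distance) columns; alternatively `start`/`end` in place of `span_bp`.
#' @param genome_length Genome length in bp (> 0).
#' @param bin_width Divergence bin width (default 0.01).
#' @param focus_max Upper divergence bound of the inset subset (default 0.05).
#' @return List with `full` and `focus` data.frames (`class`, `jc_bin` lower
#'   edge, `pct` of genome).
#' @export
landscape_histogram <- function(elements, genome_length, bin_width = 0.01,
                                focus_max = 0.05) {
  stopifnot(genome_length > 0)
  if (!"span_bp" %in% names(elements))
    elements$span_bp <- elements$end - elements$start
  if (nrow(elements) == 0)
    return(list(full = data.frame(class = character(), jc_bin = numeric(),
                                  pct = numeric()),
                focus = data.frame(class = character(), jc_bin = numeric(),
                                   pct = numeric())))
  bin <- floor(elements$jc / bin_width) * bin_width
  agg <- stats::aggregate(span_bp ~ class + bin,
                          data = data.frame(class = elements$class,
                                            bin = bin,
                                            span_bp = elements$span_bp),
                          FUN = sum)
  full <- data.frame(class = agg$class, jc_bin = agg$bin,
                     pct = 100 * agg$span_bp / genome_length,
                     stringsAsFactors = FALSE)
  full <- full[order(full$class, full$jc_bin), ]
  rownames(full) <- NULL
  list(full = full,
       focus = full[full$jc_bin < focus_max, , drop = FALSE])
}

#' Per-class repeat coverage in sliding windows
#'
#' Coverage fraction of each repeat class in sliding windows along one
#' chromosome; overlapping copies of the same class are merged before
#' counting, so bases are never double counted, and a trailing window
#' truncated by the chromosome end is normalized by its actual width.
#'
#' @param elements data.frame with `class`, `start`, `end` (0-based
#'   half-open) on one chromosome (an optional `chrom` column must be
#'   constant).
#' @param chrom_length Chromosome length in bp.
#' @param window,step Window and step sizes in bp (default 500 kb / 5 kb);
#'   `window >= step > 0`.
#' @return data.frame with `class`, `start`, `end`, `fraction`.
#' @export
windowed_repeat_content <- function(elements, chrom_length,
                                    window = 500000, step = 5000) {
  stopifnot(window >= step, step > 0, chrom_length > 0)
  if ("chrom" %in% names(elements) &&
      length(unique(elements$chrom)) > 1)
    stop("windowed_repeat_content works on one chromosome at a time")
  starts <- seq(0, max(0, chrom_length - window), by = step)
  if (utils::tail(starts, 1) + window < chrom_length)
    starts <- c(starts, utils::tail(starts, 1) + step)
  ends <- pmin(starts + window, chrom_length)
  win_ir <- IRanges::IRanges(start = starts + 1L, end = ends)
  out <- lapply(unique(elements$class), function(cl) {
    e <- elements[elements$class == cl, , drop = FALSE]
    merged <- IRanges::reduce(IRanges::IRanges(start = e$start + 1L,
                                               end = pmin(e$end, chrom_length)))
    cov <- numeric(length(win_ir))
    hits <- IRanges::findOverlaps(win_ir, merged)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        win_ir[S4Vectors::queryHits(hits)],
        merged[S4Vectors::subjectHits(hits)]))
      agg <- rowsum(ov, S4Vectors::queryHits(hits))
      cov[as.integer(rownames(agg))] <- agg[, 1]
    }
    data.frame(class = cl, start = starts, end = ends,
               fraction = cov / (ends - starts), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a simplified RepeatMasker-style repeat table
#'
#' Tab-delimited with columns `class`, `chrom`, `start`, `end` (0-based
#' half-open) and `divergence` (the CpG-corrected Kimura substitution level).
#'
#' @param path File path.
#' @param to_jc Append a `jc` column via [kimura_to_jc()] (default `TRUE`).
#' @return data.frame of repeat elements.
#' @export
read_repeat_table <- function(path, to_jc = TRUE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("class", "chrom", "start", "end", "divergence")
  if (!all(need %in% names(tab)))
    stop("repeat table must have columns: ", paste(need, collapse = ", "))
  if (to_jc) tab$jc <- kimura_to_jc(tab$divergence)
  tab$span_bp <- tab$end - tab$start
  tab
}
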