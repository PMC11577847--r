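# presentation rounding: half-up at `digits`, as in the published tables
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-chromosome map summary
#'
#' Map lengths and average recombination rates (map length divided by physical
#' length in Mb) per sex for one chromosome / linkage group. Values are kept
#' at full precision; round only for presentation.
#'
#' @param map A `sex_map` data.frame (from [estimate_map_positions()]), or
#'   `NULL` when lengths are given directly.
#' @param physical_length_mb Physical chromosome length in megabases (> 0).
#' @param chromosome Chromosome label (defaults to the modal marker
#'   chromosome of `map`).
#' @param male_cm,female_cm,avg_cm,n_markers Direct inputs used when `map` is
#'   `NULL` (e.g. rows of a published summary table).
#' @return One-row data.frame with lengths, rates and marker count.
#' @export
chromosome_summary <- function(map = NULL, physical_length_mb,
                               chromosome = NULL, male_cm = NULL,
                               female_cm = NULL, avg_cm = NULL,
                               n_markers = NULL) {
  if (physical_length_mb <= 0) stop("physical length must be positive")
  if (!is.null(map)) {
    len <- attr(map, "lengths")
    male_cm <- len$male
    female_cm <- len$female
    avg_cm <- len$avg
    n_markers <- nrow(map)
    if (is.null(chromosome))
      chromosome <- names(sort(-table(map$chrom)))[1]
  }
  stopifnot(!is.null(male_cm), !is.null(female_cm), !is.null(avg_cm))
  data.frame(chromosome = chromosome %||% NA_character_,
             length_mb = physical_length_mb,
             n_markers = n_markers %||% NA_integer_,
             male_cm = male_cm, female_cm = female_cm, avg_cm = avg_cm,
             male_rate = male_cm / physical_length_mb,
             female_rate = female_cm / physical_length_mb,
             avg_rate = avg_cm / physical_length_mb,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome-wide map summary and heterochiasmy ratio
#'
#' Sums per-chromosome map lengths and physical lengths, and reports
#' genome-wide recombination rates per sex under both denominator
#' conventions: the sum of mapped chromosome lengths, and (when supplied) the
#' total assembly length. The female:male ratio and the average marker
#' spacing (consensus map length / marker count) are included.
#'
#' @param summaries data.frame of stacked [chromosome_summary()] rows.
#' @param assembly_length_mb Optional total assembly length (Mb) for the
#'   assembly-denominator rates.
#' @param total_markers Total marker count (defaults to the summed
#'   `n_markers` column).
#' @return An object of class `genome_summary` (a list).
#' @export
genome_summary <- function(summaries, assembly_length_mb = NULL,
                           total_markers = NULL) {
  stopifnot(nrow(summaries) >= 1)
  total_markers <- total_markers %||% sum(summaries$n_markers)
  tot_mb <- sum(summaries$length_mb)
  tot <- c(male = sum(summaries$male_cm), female = sum(summaries$female_cm),
           avg = sum(summaries$avg_cm))
  rate_chrom <- tot / tot_mb
  rate_assembly <- if (!is.null(assembly_length_mb)) tot / assembly_length_mb
  ratio <- if (tot[["male"]] > 0) tot[["female"]] / tot[["male"]] else NA_real_
  structure(list(
    n_chromosomes = nrow(summaries),
    total_length_mb = tot_mb,
    total_markers = total_markers,
    map_length_cm = as.list(tot),
    rate_sum_of_chromosomes = as.list(rate_chrom),
    rate_assembly = if (is.null(rate_assembly)) NULL else as.list(rate_assembly),
    assembly_length_mb = assembly_length_mb,
    female_male_ratio = ratio,
    avg_marker_distance_cm =
      if (is.finite(total_markers) && total_markers > 0)
        tot[["avg"]] / total_markers else NA_real_
  ), class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat(sprintf("<genome_summary> %d chromosomes, %.2f Mb, %s markers\n",
              x$n_chromosomes, x$total_length_mb,
              format(x$total_markers)))
  cat(sprintf("  map lengths (cM): female %.2f, male %.2f, sex-averaged %.2f\n",
              x$map_length_cm$female, x$map_length_cm$male,
              x$map_length_cm$avg))
  r <- x$rate_sum_of_chromosomes
  cat(sprintf("  rates, sum-of-chromosomes (cM/Mb): female %.2f, male %.2f, avg %.2f\n",
              r$female, r$male, r$avg))
  if (!is.null(x$rate_assembly))
    cat(sprintf("  rates, assembly length %.1f Mb (cM/Mb): female %.2f, male %.2f, avg %.2f\n",
                x$assembly_length_mb, x$rate_assembly$female,
                x$rate_assembly$male, x$rate_assembly$avg))
  cat(sprintf("  female:male ratio %.2f, average marker distance %.2f cM\n",
              x$female_male_ratio, x$avg_marker_distance_cm))
  invisible(x)
}

#' Genome summary of a published per-chromosome map table
#'
#' Convenience wrapper: runs [chromosome_summary()] over the rows of a table
#' in the format of [acropora_map_summary()] and summarizes genome-wide.
#'
#' @param tab data.frame with `chromosome`, `length_mb`, `n_markers`,
#'   `male_cm`, `female_cm`, `avg_cm`.
#' @inheritParams genome_summary
#' @return List with `chromosomes` (recomputed per-chromosome summaries) and
#'   `genome` (a `genome_summary`).
#' @export
summarize_map_table <- function(tab, assembly_length_mb = NULL) {
  rows <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    chromosome_summary(physical_length_mb = tab$length_mb[i],
                       chromosome = tab$chromosome[i],
                       male_cm = tab$male_cm[i], female_cm = tab$female_cm[i],
                       avg_cm = tab$avg_cm[i], n_markers = tab$n_markers[i])))
  list(chromosomes = rows,
       genome = genome_summary(rows, assembly_length_mb = assembly_length_mb))
}

#' Recovery metrics of estimated maps against simulation truth
#'
#' For each estimated linkage group: the modal true chromosome of its
#' markers, group purity (fraction of markers from that chromosome), order
#' accuracy as the absolute Kendall tau between map order and physical
#' position (orientation-aligned, so a fully reversed map scores 1), and
#' per-sex map length bias / relative error against the simulated truth.
#'
#' @param maps Named list of `sex_map` data.frames.
#' @param truth A `sim_truth` object (uses its `map_lengths`).
#' @return data.frame with one row per linkage group.
#' @export
recovery_report <- function(maps, truth) {
  tl <- truth$map_lengths
  rows <- lapply(names(maps), function(g) {
    m <- maps[[g]]
    chrom <- names(sort(-table(m$chrom)))[1]
    purity <- mean(m$chrom == chrom)
    sub <- m[m$chrom == chrom, ]
    tau <- if (nrow(sub) >= 2)
      abs(stats::cor(seq_len(nrow(sub)), sub$pos, method = "kendall")) else NA
    len <- attr(m, "lengths")
    tr <- tl[tl$chrom == chrom, ]
    data.frame(group = g, chromosome = chrom, n_markers = nrow(m),
               purity = purity, order_tau = tau,
               female_cm = len$female, true_female_cm = tr$female_cm,
               female_bias = len$female - tr$female_cm,
               female_rel_error = (len$female - tr$female_cm) / tr$female_cm,
               male_cm = len$male, true_male_cm = tr$male_cm,
               male_bias = len$male - tr$male_cm,
               male_rel_error = (len$male - tr$male_cm) / tr$male_cm,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
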