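#' Chromosome model with sex-specific Marey profiles
#'
#' A chromosome model couples a physical length (bp) with a genetic map length
#' per parental role ("female" = egg donor / dam meioses, "male" = sperm donor /
#' sire meioses; both parents of a hermaphroditic coral cross can take either
#' role) and a normalized, monotone Marey profile mapping relative physical
#' position to relative genetic position. The default profile is a
#' piecewise-linear sigmoid with suppressed recombination over the central 20%
#' of the chromosome, emulating a metacentric centromere.
#'
#' @param name Chromosome label.
#' @param physical_length Physical length in base pairs (> 0).
#' @param female_map_length,male_map_length Map lengths in centimorgans (>= 0).
#' @param profile_x,profile_y Control points of the normalized Marey profile;
#'   both must start at 0, end at 1 and be non-decreasing. The same profile
#'   shape is used for both sexes and scaled by the sex's map length.
#' @return An object of class `chromosome_model`.
#' @examples
#' cm <- chromosome_model("Chr1", 27.05e6, 148.29, 54.05)
#' marey_position(cm, c(0, 13.5e6, 27.05e6), "female")
#' @export
chromosome_model <- function(name, physical_length,
                             female_map_length, male_map_length,
                             profile_x = c(0, 0.4, 0.6, 1),
                             profile_y = c(0, 0.45, 0.55, 1)) {
  stopifnot(length(physical_length) == 1, physical_length > 0,
            female_map_length >= 0, male_map_length >= 0,
            length(profile_x) == length(profile_y), length(profile_x) >= 2)
  if (profile_x[1] != 0 || profile_y[1] != 0 ||
      profile_x[length(profile_x)] != 1 || profile_y[length(profile_y)] != 1)
    stop("marey profile control points must run from (0,0) to (1,1)")
  if (any(diff(profile_x) < 0) || any(diff(profile_y) < 0))
    stop("marey profile must be non-decreasing")
  structure(list(name = as.character(name),
                 physical_length = as.numeric(physical_length),
                 female_map_length = as.numeric(female_map_length),
                 male_map_length = as.numeric(male_map_length),
                 profile_x = as.numeric(profile_x),
                 profile_y = as.numeric(profile_y)),
            class = "chromosome_model")
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf("<chromosome_model> %s: %.2f Mb, female %.2f cM, male %.2f cM\n",
              x$name, x$physical_length / 1e6,
              x$female_map_length, x$male_map_length))
  invisible(x)
}

map_length <- function(model, role) {
  switch(match.arg(role, c("female", "male")),
         female = model$female_map_length,
         male = model$male_map_length)
}

#' Genetic position of physical coordinates under a chromosome model
#'
#' @param model A [chromosome_model()].
#' @param bp Physical positions in base pairs.
#' @param role `"female"` or `"male"`.
#' @return Genetic positions in cM, from 0 to the role's map length.
#' @export
marey_position <- function(model, bp, role = c("female", "male")) {
  role <- match.arg(role)
  L <- map_length(model, role)
  x <- pmin(pmax(bp / model$physical_length, 0), 1)
  stats::approx(model$profile_x, model$profile_y, xout = x, ties = "ordered")$y * L
}

#' Physical position at which a genetic position is reached (inverse Marey map)
#'
#' @inheritParams marey_position
#' @param cm Genetic positions in cM within `[0, map length]`.
#' @return Physical positions in bp.
#' @export
marey_inverse <- function(model, cm, role = c("female", "male")) {
  role <- match.arg(role)
  L <- map_length(model, role)
  if (L <= 0) stop("inverse Marey map undefined for a 0 cM chromosome")
  y <- pmin(pmax(cm / L, 0), 1)
  # flat profile segments are inverted to their left edge (ties = min)
  stats::approx(model$profile_y, model$profile_x, xout = y,
                ties = min)$y * model$physical_length
}

#' Published Atlantic Acropora map summaries (per-chromosome)
#'
#' Reads the per-chromosome physical lengths, marker counts, sex-specific map
#' lengths and average recombination rates published for the two Atlantic
#' acroporid linkage maps, shipped with the package as tab-separated text.
#'
#' @param species `"palmata"` or `"cervicornis"`.
#' @return A data.frame with columns `chromosome`, `length_mb`, `n_markers`,
#'   `male_cm`, `female_cm`, `avg_cm`, `male_rate`, `female_rate`, `avg_rate`.
#' @export
acropora_map_summary <- function(species = c("palmata", "cervicornis")) {
  species <- match.arg(species)
  path <- system.file("extdata",
                      sprintf("acropora_%s_map_summary.tsv", species),
                      package = "acromap", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Chromosome models built from the published Atlantic Acropora map tables
#'
#' @inheritParams acropora_map_summary
#' @param ... Passed to [chromosome_model()] (e.g. custom Marey profile
#'   control points).
#' @return A named list of [chromosome_model()] objects, one per chromosome,
#'   with physical lengths and sex-specific map lengths taken from the
#'   published tables.
#' @export
acropora_chromosome_models <- function(species = c("palmata", "cervicornis"),
                                       ...) {
  tab <- acropora_map_summary(species)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    chromosome_model(tab$chromosome[i], tab$length_mb[i] * 1e6,
                     female_map_length = tab$female_cm[i],
                     male_map_length = tab$male_cm[i], ...)
  })
  names(models) <- tab$chromosome
  models
}

#' Write / read a two-column chromosome length table
#'
#' @param models List of [chromosome_model()] objects (or a data.frame with
#'   `chromosome` and `length_bp` columns).
#' @param path File path for the tab-delimited table.
#' @return `read_chrom_table` returns a data.frame with `chromosome` and
#'   `length_bp`.
#' @export
write_chrom_table <- function(models, path) {
  if (is.data.frame(models)) {
    tab <- models[, c("chromosome", "length_bp")]
  } else {
    tab <- data.frame(chromosome = vapply(models, `[[`, "", "name"),
                      length_bp = vapply(models, `[[`, 0, "physical_length"))
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_table
#' @export
read_chrom_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
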