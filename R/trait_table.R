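#' @importFrom stats sd median var cor aov anova lm pf pchisq qchisq rnorm
#'   runif rexp optim optimize setNames complete.cases cov2cor kruskal.test
#'   cor.test p.adjust pt rpois dpois quantile residuals
#' @importFrom utils read.csv write.csv combn head
NULL

## ---- trait vocabulary -------------------------------------------------------

#' Trait vocabulary for the Silene floral dataset
#'
#' Names, units and categorical levels of the traits analysed throughout the
#' package: six continuous traits recorded as min/median/max ranges, three
#' ordinal floral traits, the three-state floral color, and ploidy.
#'
#' @return A list with elements `continuous` (named character vector of units),
#'   `categorical` (named list of ordered level vectors), `color_levels`, and
#'   `ploidy_levels`.
#' @export
silene_traits <- function() {
  list(
    continuous = c(
      stem_length = "cm", leaves_per_node = "count", leaf_length = "mm",
      calyx_height = "mm", calyx_width = "mm", petal_limb = "mm"
    ),
    categorical = list(
      inflorescence = c("one", "few", "many"),
      tube_extension = c("below", "equal", "above"),
      organ_exsertion = c("below", "equal", "above/equal", "above")
    ),
    color_levels = c("white", "pink", "red"),
    ploidy_levels = c("diploid", "diploid/polyploid", "polyploid")
  )
}

#' Default ordinal encoding for categorical floral traits
#'
#' Ordinal categories are converted to representative numbers for the
#' correlation and morphospace analyses: `below = -1`, `equal = 0`,
#' `above = +1` for tube extension and reproductive organ exsertion (the
#' intermediate `above/equal` level takes `+0.5`, preserving order), and
#' `one = 1`, `few = 2`, `many = 3` for inflorescence class.
#'
#' @return Named list of named numeric vectors, one per categorical trait.
#' @export
default_encoding <- function() {
  list(
    inflorescence = c(one = 1, few = 2, many = 3),
    tube_extension = c(below = -1, equal = 0, above = 1),
    organ_exsertion = c(below = -1, equal = 0, `above/equal` = 0.5, above = 1)
  )
}

range_cols <- function() {
  traits <- names(silene_traits()$continuous)
  as.vector(vapply(traits, function(tr)
    paste(tr, c("min", "median", "max"), sep = "_"), character(3)))
}

trait_table_cols <- function() {
  c("species", range_cols(),
    names(silene_traits()$categorical), "color", "ploidy")
}

## ---- construction & validation ---------------------------------------------

#' Construct and validate a species trait table
#'
#' Validates a data frame of per-species floral/vegetative trait records:
#' unique species ids, `min <= median <= max` for every continuous trait range,
#' and categorical values drawn from their declared level sets. Species names
#' keep any subspecies tokens (subspecies are treated as separate records).
#'
#' @param df Data frame with columns `species`, `<trait>_min`, `<trait>_median`,
#'   `<trait>_max` for each continuous trait, the categorical traits
#'   `inflorescence`, `tube_extension`, `organ_exsertion`, plus `color`
#'   (raw description, binned via [bin_floral_color()]) and `ploidy`.
#' @param encoding Ordinal encoding map, see [default_encoding()].
#' @return An object of class `trait_table` (a validated data frame carrying
#'   its encoding map as an attribute).
#' @export
trait_table <- function(df, encoding = default_encoding()) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(trait_table_cols(), names(df))
  if (length(missing_cols))
    stop("trait table schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, trait_table_cols()]
  df$species <- trimws(as.character(df$species))
  if (anyDuplicated(df$species))
    stop("duplicate species_id: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)

  voc <- silene_traits()
  for (tr in names(voc$continuous)) {
    cols <- paste(tr, c("min", "median", "max"), sep = "_")
    m <- as.matrix(df[, cols])
    storage.mode(m) <- "double"
    bad_order <- which(stats::complete.cases(m) &
                         !(m[, 1] <= m[, 2] & m[, 2] <= m[, 3]))
    if (length(bad_order))
      stop("trait range validation error: min <= median <= max violated for ",
           tr, " in species ",
           paste(df$species[bad_order], collapse = ", "), call. = FALSE)
    nonfinite <- which(apply(m, 1, function(r)
      any(!is.na(r) & !is.finite(r))))
    if (length(nonfinite))
      stop("non-finite ", tr, " range for species ",
           paste(df$species[nonfinite], collapse = ", "), call. = FALSE)
    df[, cols] <- m
  }

  df$color <- bin_floral_color(df$color)
  for (tr in names(voc$categorical)) {
    vals <- as.character(df[[tr]])
    bad <- which(!is.na(vals) & !(vals %in% voc$categorical[[tr]]))
    if (length(bad))
      stop("invalid ", tr, " value(s) ",
           paste(unique(vals[bad]), collapse = ", "), " for species ",
           paste(df$species[bad], collapse = ", "),
           "; allowed: ", paste(voc$categorical[[tr]], collapse = ", "),
           call. = FALSE)
    if (anyNA(vals))
      stop("missing ", tr, " (only continuous traits may be missing) for ",
           paste(df$species[is.na(vals)], collapse = ", "), call. = FALSE)
    df[[tr]] <- vals
  }
  bad_ploidy <- which(!df$ploidy %in% voc$ploidy_levels)
  if (length(bad_ploidy))
    stop("invalid ploidy for species ",
         paste(df$species[bad_ploidy], collapse = ", "), call. = FALSE)

  for (tr in names(encoding)) {
    lev <- voc$categorical[[tr]]
    if (!all(lev %in% names(encoding[[tr]])))
      stop("encoding map does not cover all levels of ", tr, call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, encoding = encoding, class = c("trait_table", "data.frame"))
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Silene trait table: ", nrow(x), " species\n", sep = "")
  cat("  colors: ",
      paste(names(table(x$color)), table(x$color), sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  continuous traits: ",
      paste(names(silene_traits()$continuous), collapse = ", "), "\n", sep = "")
  invisible(x)
}

## ---- I/O --------------------------------------------------------------------

#' Read a species trait table from CSV
#'
#' @param path CSV file (UTF-8, header row).
#' @param schema Optional named character vector mapping the canonical column
#'   names (names of the vector) to the column names used in the file.
#' @param encoding Ordinal encoding map.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(path, schema = NULL,
                             encoding = default_encoding()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(df))
        stop("trait table schema error: column ", schema[[canon]],
             " (for ", canon, ") not in file", call. = FALSE)
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  trait_table(df, encoding = encoding)
}

#' Write a trait table to CSV with its encoding map
#'
#' The encoding map is serialized as JSON next to the CSV so encoded analyses
#' are reproducible from the written artefacts alone.
#'
#' @param tt A `trait_table`.
#' @param path Output CSV path.
#' @param encoding_path JSON path for the encoding map (default
#'   `<path>.encoding.json`).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(tt, path,
                              encoding_path = paste0(path, ".encoding.json")) {
  stopifnot(inherits(tt, "trait_table"))
  utils::write.csv(as.data.frame(tt), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(attr(tt, "encoding"), encoding_path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

## ---- floral color binning ---------------------------------------------------

#' Bin raw floral color descriptions into white / pink / red
#'
#' Deterministic three-state binning of raw color descriptions:
#' white/pink polymorphic species are coded pink (they can produce petal
#' pigment), pale yellow is coded white (absence of anthocyanins), orange-pink
#' is coded pink, orange-red is coded red, and the plain terms map to
#' themselves. The mapping is idempotent and total over this vocabulary.
#'
#' @param x Character vector of raw descriptions.
#' @param overrides Optional named character vector of extra mappings
#'   (`c("lavender" = "pink")`), checked against the three bins.
#' @return Character vector with values in `white`, `pink`, `red`.
#' @export
bin_floral_color <- function(x, overrides = NULL) {
  map <- c(
    white = "white", pink = "pink", red = "red",
    "white/pink" = "pink", "pink/white" = "pink",
    "pale yellow" = "white", "orange-pink" = "pink", "orange-red" = "red"
  )
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || !all(overrides %in% silene_traits()$color_levels))
      stop("overrides must be a named vector with values in white/pink/red",
           call. = FALSE)
    map[names(overrides)] <- overrides
  }
  x <- tolower(trimws(as.character(x)))
  out <- unname(map[x])
  if (anyNA(out[!is.na(x)]))
    stop("color coding error: unrecognized description(s) ",
         paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", "),
         " (supply an override)", call. = FALSE)
  out[is.na(x)] <- NA_character_
  out
}

## ---- encoding ---------------------------------------------------------------

#' Encode a trait table as the numeric analysis matrix
#'
#' Builds the species-by-trait numeric matrix used by the correlation,
#' phylogenetic-signal and morphospace analyses: the six continuous trait
#' medians plus the three ordinal traits converted to representative integers
#' under `encoding`. Floral color is deliberately excluded (it is the grouping
#' variable, not a morphospace axis).
#'
#' @param tt A `trait_table`.
#' @param encoding Encoding map; defaults to the one stored in `tt`.
#' @param drop_incomplete Drop species with any missing continuous median
#'   (default `TRUE`); dropped species are reported via a message.
#' @return Numeric matrix, rownames = species ids, 9 columns.
#' @export
encode_traits <- function(tt, encoding = attr(tt, "encoding"),
                          drop_incomplete = TRUE) {
  stopifnot(inherits(tt, "trait_table"))
  voc <- silene_traits()
  cont <- vapply(names(voc$continuous), function(tr)
    as.numeric(tt[[paste0(tr, "_median")]]), numeric(nrow(tt)))
  cats <- vapply(names(voc$categorical), function(tr) {
    codes <- encoding[[tr]]
    vals <- as.character(tt[[tr]])
    bad <- setdiff(unique(vals), names(codes))
    if (length(bad))
      stop("coding error: level(s) ", paste(bad, collapse = ", "),
           " of ", tr, " absent from encoding map", call. = FALSE)
    unname(codes[vals])
  }, numeric(nrow(tt)))
  m <- cbind(cont, cats)
  rownames(m) <- tt$species
  if (drop_incomplete && anyNA(m)) {
    drop <- rownames(m)[!stats::complete.cases(m)]
    message("excluding species with missing analysis traits: ",
            paste(drop, collapse = ", "))
    m <- m[stats::complete.cases(m), , drop = FALSE]
  }
  m
}

## ---- summary statistics -----------------------------------------------------

#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x Numeric vector with at least two finite values and nonzero mean.
#' @return CV in percent. Scale-invariant: `cv(c * x) == cv(x)` for `c > 0`.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2)
    stop("insufficient data: CV needs at least 2 finite values", call. = FALSE)
  m <- mean(x)
  if (m == 0) stop("undefined CV: mean is zero", call. = FALSE)
  100 * stats::sd(x) / m
}

#' Summary statistics of traits by floral color group
#'
#' Per color group (and over all species): grand mean, SD, grand median of the
#' species trait medians, and CV for each continuous trait; and the proportion
#' of species in each level of each categorical trait and of ploidy.
#'
#' @param tt A `trait_table`.
#' @return An object of class `color_summary`: list with data frames
#'   `continuous` (group x trait statistics) and `categorical` (per-level
#'   proportions, each trait-by-group column summing to 1).
#' @export
summarize_by_color <- function(tt) {
  stopifnot(inherits(tt, "trait_table"))
  voc <- silene_traits()
  groups <- c(intersect(voc$color_levels, unique(tt$color)), "all")
  rows <- list()
  for (tr in names(voc$continuous)) {
    med <- tt[[paste0(tr, "_median")]]
    for (g in groups) {
      v <- if (g == "all") med else med[tt$color == g]
      v <- v[is.finite(v)]
      n <- length(v)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = tr, group = g, n = n,
        mean = if (n) mean(v) else NA_real_,
        sd = if (n > 1) stats::sd(v) else if (n == 1) 0 else NA_real_,
        median = if (n) stats::median(v) else NA_real_,
        cv = if (n > 1 && mean(v) != 0) 100 * stats::sd(v) / mean(v)
             else if (n > 1) NA_real_ else if (n == 1) 0 else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  cont <- do.call(rbind, rows)

  cat_traits <- c(names(voc$categorical), ploidy = "ploidy")
  levels_of <- c(voc$categorical, list(ploidy = voc$ploidy_levels))
  crows <- list()
  for (tr in names(levels_of)) {
    vals <- tt[[tr]]
    for (g in groups) {
      v <- if (g == "all") vals else vals[tt$color == g]
      if (!length(v)) next  # absent group: flagged by omission, not zeros
      tab <- table(factor(v, levels = levels_of[[tr]]))
      crows[[length(crows) + 1L]] <- data.frame(
        trait = tr, group = g, level = names(tab), n = length(v),
        proportion = as.numeric(tab) / length(v), stringsAsFactors = FALSE
      )
    }
  }
  categ <- do.call(rbind, crows)
  rownames(cont) <- rownames(categ) <- NULL
  structure(list(continuous = cont, categorical = categ,
                 groups = setdiff(groups, "all")),
            class = "color_summary")
}

#' @export
print.color_summary <- function(x, digits = 2, ...) {
  cat("Trait summaries by floral color (groups: ",
      paste(x$groups, collapse = ", "), ")\n", sep = "")
  print(format(x$continuous, digits = digits), ...)
  invisible(x)
}
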