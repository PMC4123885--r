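#' Specimen sets
#'
#' A `specimen_set` is the pipeline's container for museum individuals: a
#' data frame with one row per microwear measurement (a 0.04 mm2 counting
#' field), rows sharing a `specimen_id` belonging to the same tooth.  A
#' morphometrics-only specimen (no microwear) is a single row with `NA`
#' counts.  Specimen-level columns must be constant within a specimen.
#'
#' Columns:
#' \describe{
#'   \item{specimen_id}{opaque identifier, shared by a specimen's rows}
#'   \item{species, order}{taxon strings}
#'   \item{lineage}{`eutherian` or `metatherian`}
#'   \item{guild}{feeding guild, `NA` for unknowns awaiting classification}
#'   \item{body_mass_g}{species-mean body mass in grams (sexes averaged)}
#'   \item{length_mm, width_mm, crest_mm}{mesiodistal length, buccolingual
#'     width and summed 2-D shearing-crest length of the tooth; `NA` when
#'     not measured}
#'   \item{Sf, Sc, Ps, Pl}{fine scratches, coarse scratches, small pits,
#'     large pits counted in one field}
#'   \item{St, Pt}{derived totals, `Sf + Sc` and `Ps + Pl`}
#' }
#'
#' @param data data frame with the columns above (`St`/`Pt` are recomputed).
#' @param provenance free-text provenance string (source file or generator
#'   configuration hash).
#' @param field_area counting-field area in mm2 (default 0.04).
#' @return an object of class `specimen_set` (a validated data frame).
#' @seealso [read_specimen_table()], [limit_dataset()],
#'   [aggregate_observations()]
#' @export
specimen_set <- function(data, provenance = "unspecified", field_area = 0.04) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  required <- c("specimen_id", "species", "order", "lineage", "guild",
                "body_mass_g", "length_mm", "width_mm", "crest_mm",
                MICROWEAR_FEATURES)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("specimen table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  data$specimen_id <- as.character(data$specimen_id)
  data$species <- as.character(data$species)
  data$order <- as.character(data$order)
  data$lineage <- parse_lineage(data$lineage)
  data$guild <- parse_guild(data$guild)
  for (col in c("body_mass_g", "length_mm", "width_mm", "crest_mm")) {
    data[[col]] <- as.numeric(data[[col]])
  }
  data$St <- NULL
  data$Pt <- NULL
  for (f in MICROWEAR_FEATURES) data[[f]] <- .check_count(data[[f]], f)
  data$St <- data$Sf + data$Sc
  data$Pt <- data$Ps + data$Pl
  data <- data[c(required, "St", "Pt")]
  structure(data,
            class = c("specimen_set", "data.frame"),
            provenance = provenance,
            field_area = field_area) |>
    validate_specimen_set()
}

# counts must be non-negative integers (NA allowed: morphometrics-only rows)
.check_count <- function(x, name) {
  x <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & (x < 0 | x != round(x)))
  if (length(bad) > 0) {
    stop("column ", name, " must hold non-negative integer counts; ",
         "offending row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  }
  as.integer(round(x))
}

#' Validate a specimen set
#'
#' Checks the container invariants: count columns are non-negative integers
#' with `St = Sf + Sc` and `Pt = Ps + Pl`, body mass and tooth dimensions
#' are positive where present, a specimen's microwear counts are either all
#' present or all absent within a row, and specimen-level fields do not
#' conflict across the rows of one specimen.
#'
#' @param x a `specimen_set`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_specimen_set <- function(x) {
  stopifnot(inherits(x, "specimen_set"))
  if (nrow(x) == 0) return(x)
  if (any(!is.na(x$body_mass_g) & x$body_mass_g <= 0)) {
    stop("body_mass_g must be > 0 where present")
  }
  for (col in c("length_mm", "width_mm")) {
    if (any(!is.na(x[[col]]) & x[[col]] <= 0)) {
      stop(col, " must be > 0 where present")
    }
  }
  if (any(!is.na(x$crest_mm) & x$crest_mm < 0)) {
    stop("crest_mm must be >= 0 where present")
  }
  n_na <- rowSums(is.na(as.matrix(x[MICROWEAR_FEATURES])))
  if (any(n_na %in% c(1L, 2L, 3L))) {
    stop("microwear counts must be all present or all absent within a row")
  }
  per_spec <- c("species", "order", "lineage", "guild", "body_mass_g",
                "length_mm", "width_mm", "crest_mm")
  for (col in per_spec) {
    n_distinct <- tapply(x[[col]], x$specimen_id,
                         function(v) length(unique(v)))
    if (any(n_distinct > 1)) {
      stop("specimen-level column '", col, "' differs between rows of ",
           "specimen(s): ",
           paste(names(n_distinct)[n_distinct > 1], collapse = ", "))
    }
  }
  invisible(x)
}

#' @export
print.specimen_set <- function(x, ...) {
  ids <- unique(x$specimen_id)
  cat("specimen_set: ", length(ids), " specimens, ", nrow(x),
      " microwear rows\n", sep = "")
  gl <- guild_of_specimens(x)
  if (any(!is.na(gl))) {
    cat("  guilds: ", paste(names(table(gl)), table(gl),
                            sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  provenance: ", attr(x, "provenance"), "\n", sep = "")
  invisible(x)
}

# subsetting keeps the class and attributes
#' @export
`[.specimen_set` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && identical(names(out), names(x))) {
    attr(out, "provenance") <- attr(x, "provenance")
    attr(out, "field_area") <- attr(x, "field_area")
    class(out) <- class(x)
  }
  out
}

#' Per-specimen guild labels
#'
#' @param x a `specimen_set`.
#' @return named character vector, one guild per specimen, in order of first
#'   appearance.
#' @export
guild_of_specimens <- function(x) {
  ids <- unique(x$specimen_id)
  out <- x$guild[match(ids, x$specimen_id)]
  names(out) <- ids
  out
}

#' Restrict to well-sampled species
#'
#' Retains only specimens whose species is represented by at least
#' `min_individuals` specimens in `x` — the "limited data set" used as a
#' check on microwear variability from sparsely sampled species.  Row order
#' is preserved and the operation is idempotent.
#'
#' @param x a `specimen_set`.
#' @param min_individuals minimum number of specimens per species (>= 1).
#' @return the filtered `specimen_set`.
#' @export
limit_dataset <- function(x, min_individuals = 3L) {
  stopifnot(inherits(x, "specimen_set"), min_individuals >= 1)
  ids <- unique(x$specimen_id)
  sp <- x$species[match(ids, x$specimen_id)]
  n_per_species <- table(sp)
  keep_species <- names(n_per_species)[n_per_species >= min_individuals]
  x[x$species %in% keep_species, , drop = FALSE]
}

#' Collapse microwear measurements to one vector per specimen
#'
#' Summarises each specimen's per-field counts (up to four fields per tooth)
#' into a single feature vector, the statistical unit used by the
#' discriminant analyses and the guild workflow.  For `method = "mean"` the
#' derived totals satisfy `St = Sf + Sc` and `Pt = Ps + Pl` exactly, by
#' linearity.
#'
#' @param x a `specimen_set` in which every specimen has at least one
#'   microwear observation; specimens without microwear raise an error
#'   (they are never silently dropped).
#' @param method `"mean"` or `"median"` across a specimen's fields.
#' @return data frame with one row per specimen: `specimen_id`, `species`,
#'   `order`, `lineage`, `guild`, `body_mass_g`, tooth columns, `n_obs`, and
#'   real-valued `Sf`, `Sc`, `Ps`, `Pl`, `St`, `Pt`.
#' @export
aggregate_observations <- function(x, method = c("mean", "median")) {
  stopifnot(inherits(x, "specimen_set"))
  method <- match.arg(method)
  ids <- unique(x$specimen_id)
  has_obs <- tapply(!is.na(x$Sf), x$specimen_id, any)[ids]
  if (any(!has_obs)) {
    stop("specimen(s) without microwear observations: ",
         paste(ids[!has_obs], collapse = ", "),
         "; drop them explicitly before aggregating")
  }
  fun <- if (method == "mean") mean else stats::median
  first <- x[match(ids, x$specimen_id),
             c("specimen_id", "species", "order", "lineage", "guild",
               "body_mass_g", "length_mm", "width_mm", "crest_mm")]
  counts <- x[!is.na(x$Sf), ]
  agg <- function(col) {
    as.numeric(tapply(counts[[col]], counts$specimen_id, fun)[ids])
  }
  out <- as.data.frame(first)
  class(out) <- "data.frame"
  out$n_obs <- as.integer(table(counts$specimen_id)[ids])
  for (f in c(MICROWEAR_FEATURES, "St", "Pt")) out[[f]] <- agg(f)
  rownames(out) <- NULL
  out
}
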