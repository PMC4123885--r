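#' Molar crown area
#'
#' Crown area as the product of mesiodistal length and buccolingual width,
#' in mm2.  For carnivorans the measured tooth is the carnassial rather
#' than M2; the same length-by-width convention is applied.
#'
#' @param length_mm mesiodistal length, mm, > 0.
#' @param width_mm buccolingual width, mm, > 0.
#' @return numeric vector of areas in mm2.
#' @export
#' @examples
#' crown_area(4, 3)  # 12
crown_area <- function(length_mm, width_mm) {
  if (any(!is.na(length_mm) & length_mm <= 0) ||
      any(!is.na(width_mm) & width_mm <= 0)) {
    stop("tooth length and width must be strictly positive")
  }
  length_mm * width_mm
}

#' Shearing Crest Score
#'
#' The summed 2-D shearing-crest length divided by the square root of the
#' molar crown area (length x width).  Dividing by a linear size measure
#' that is independent of crown shape makes the score dimensionless and
#' invariant under isotropic scaling, so upper and lower molars of any size
#' are comparable.  Crest lengths digitised from occlusal images
#' underestimate the true 3-D crest length; no correction is applied.
#'
#' @param crest_mm summed shearing-crest length, mm, >= 0.
#' @inheritParams crown_area
#' @return numeric vector of dimensionless scores, >= 0.
#' @export
#' @examples
#' shearing_crest_score(8, 4, 4)   # 2
shearing_crest_score <- function(crest_mm, length_mm, width_mm) {
  if (any(!is.na(crest_mm) & crest_mm < 0)) {
    stop("crest length must be non-negative")
  }
  crest_mm / sqrt(crown_area(length_mm, width_mm))
}

#' Append a Shearing Crest Score column
#'
#' Computes the SCS from the tooth columns of a specimen set or a
#' per-specimen aggregate and appends it as column `scs` (`NA` where tooth
#' measurements are absent).
#'
#' @param x a `specimen_set` or the data frame returned by
#'   [aggregate_observations()].
#' @return `x` with an `scs` column.
#' @export
add_scs <- function(x) {
  x$scs <- shearing_crest_score(x$crest_mm, x$length_mm, x$width_mm)
  x
}
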