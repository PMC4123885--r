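#' Feeding-guild and lineage labels
#'
#' The five feeding guilds recognised by the pipeline and the two mammalian
#' lineages.  Guilds are dietary specialisations: `grazer` (grass and forbs),
#' `browser` (leaves of trees and shrubs), `hard_object` (fruits, nuts,
#' seeds), `insectivore` (cuticle-bearing invertebrates) and `carnivore`
#' (flesh and bone feeders pooled).  Lineages are `eutherian` (placental)
#' and `metatherian` (marsupial).
#'
#' @format Character vectors of the canonical labels.
#' @name guild_labels
NULL

#' @rdname guild_labels
#' @export
GUILDS <- c("grazer", "browser", "hard_object", "insectivore", "carnivore")

#' @rdname guild_labels
#' @export
LINEAGES <- c("eutherian", "metatherian")

#' Microwear feature names: fine scratches, coarse scratches, small pits,
#' large pits, counted per 0.04 mm2 field.
#' @rdname guild_labels
#' @export
MICROWEAR_FEATURES <- c("Sf", "Sc", "Ps", "Pl")

#' Parse guild labels
#'
#' Case-insensitive parse onto the canonical lower-case guild labels.
#' `"hard-object"`, `"hard object"` and `"hard_object"` are equivalent;
#' `NA` passes through (a specimen of unknown diet awaiting classification).
#'
#' @param x character vector of guild labels.
#' @return character vector using the canonical labels in [GUILDS].
#' @export
#' @examples
#' parse_guild(c("Grazer", "hard-object", NA))
parse_guild <- function(x) {
  out <- tolower(trimws(as.character(x)))
  out <- gsub("[ -]", "_", out)
  bad <- !is.na(out) & !(out %in% GUILDS)
  if (any(bad)) {
    stop("unknown guild label(s): ", paste(unique(out[bad]), collapse = ", "),
         "; expected one of ", paste(GUILDS, collapse = ", "))
  }
  out
}

#' Parse lineage labels
#'
#' @param x character vector; `eutherian`/`metatherian`, case-insensitive.
#' @return canonical lower-case lineage labels; `NA` passes through.
#' @export
parse_lineage <- function(x) {
  out <- tolower(trimws(as.character(x)))
  bad <- !is.na(out) & !(out %in% LINEAGES)
  if (any(bad)) {
    stop("unknown lineage label(s): ", paste(unique(out[bad]), collapse = ", "),
         "; expected one of ", paste(LINEAGES, collapse = ", "))
  }
  out
}
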