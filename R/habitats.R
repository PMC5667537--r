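#' The closed habitat vocabulary
#'
#' The 19 habitat types present in the current or proposed grounds layouts,
#' with their UK BAP broad-habitat class where one applies. All pipeline
#' inputs must use (or be aliased to) these labels; unknown labels are
#' rejected at parse time.
#'
#' @return A tibble with columns `habitat` (canonical label) and `bap_class`
#'   (UK BAP broad habitat, `NA` where none applies).
#' @export
#' @examples
#' habitat_types()
habitat_types <- function() {
  tibble::tibble(
    habitat = c(
      "hard-standing", "amenity grass/turf", "introduced shrubs",
      "neutral grassland", "broadleaved woodland", "short/perennial vegetation",
      "chalk grassland", "ponds", "marginal vegetation",
      "species-rich hedgerow", "species-poor hedgerow", "acid grassland",
      "fen", "green roof", "ferns and cycad planting", "agricultural plants",
      "cretaceous angiosperm shrubs", "paleogene asteraceae", "neogene grass"
    ),
    bap_class = c(
      NA, NA, NA,
      "Neutral grassland", "Broadleaved, mixed and yew woodland", NA,
      "Calcareous grassland", "Standing water and canals",
      "Standing water and canals",
      "Boundary and linear features", "Boundary and linear features",
      "Dwarf shrub heath", "Fen marsh and swamp",
      NA, NA, NA, NA, NA, NA
    )
  )
}

# Built-in aliases: descriptive variants seen in layout/extraction tables.
.habitat_aliases <- c(
  "acid grassland (heath)"          = "acid grassland",
  "fen (including reedbed)"         = "fen",
  "marginal vegetation (pond edge)" = "marginal vegetation",
  "pond"                            = "ponds",
  "cretaceous angiosperm shrubs"    = "cretaceous angiosperm shrubs",
  "hard standing"                   = "hard-standing"
)

#' Normalize habitat labels to the canonical vocabulary
#'
#' Lower-cases, trims and squishes whitespace, applies the built-in aliases
#' plus any user-supplied ones, then checks membership in the closed
#' 19-label vocabulary.
#'
#' @param x Character vector of habitat labels.
#' @param aliases Optional named character vector or two-column data frame
#'   (`alias`, `habitat`) mapping free-text labels to canonical ones.
#' @return Character vector of canonical labels.
#' @export
normalize_habitat <- function(x, aliases = NULL) {
  canon <- habitat_types()$habitat
  y <- tolower(trimws(gsub("[[:space:]]+", " ", as.character(x))))
  map <- .habitat_aliases
  if (!is.null(aliases)) {
    if (is.data.frame(aliases)) {
      stopifnot(all(c("alias", "habitat") %in% names(aliases)))
      extra <- stats::setNames(tolower(aliases$habitat), tolower(aliases$alias))
    } else {
      extra <- stats::setNames(tolower(aliases), tolower(names(aliases)))
    }
    map <- c(map, extra)
  }
  hit <- match(y, names(map))
  y[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  bad <- setdiff(unique(y), canon)
  if (length(bad) > 0) {
    rows <- which(y %in% bad)
    stop(
      "unknown habitat label(s): ", paste(sQuote(bad), collapse = ", "),
      " (row ", paste(utils::head(rows, 5L), collapse = ", "), ")",
      call. = FALSE
    )
  }
  y
}
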