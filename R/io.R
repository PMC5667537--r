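#' Read a literature-extraction study table
#'
#' Reads the collated meta-analysis table of sampled sites: one row per site
#' with its study identifier, taxon group, habitat, sampled area and observed
#' within-sample species richness. Richness may be fractional (values digitized
#' from figures); it is rounded only inside the model-fitting stage.
#'
#' @param path Path to a CSV file with columns `study_id`, `taxon_group`,
#'   `habitat`, `sampled_area_m2`, `richness`.
#' @param aliases Optional habitat alias map passed to [normalize_habitat()].
#' @return A tibble (the study table) with validated, normalized columns.
#' @export
read_literature_table <- function(path, aliases = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("study_id", "taxon_group", "habitat", "sampled_area_m2", "richness")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("literature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_study_table(
    tibble::tibble(
      study_id = as.character(df$study_id),
      taxon_group = tolower(as.character(df$taxon_group)),
      habitat = normalize_habitat(df$habitat, aliases),
      sampled_area_m2 = as.numeric(df$sampled_area_m2),
      richness = as.numeric(df$richness)
    )
  )
}

#' Validate a study table
#'
#' Checks the invariants of the literature-extraction table: positive sampled
#' areas, non-negative richness, known taxon groups and habitat labels.
#'
#' @param studies A data frame with the study-table columns.
#' @return The validated table as a tibble (invisibly unchanged).
#' @export
validate_study_table <- function(studies) {
  studies <- tibble::as_tibble(studies)
  bad_area <- which(!is.finite(studies$sampled_area_m2) | studies$sampled_area_m2 <= 0)
  if (length(bad_area) > 0) {
    stop("non-positive sampled_area_m2 at row ",
         paste(utils::head(bad_area, 5L), collapse = ", "), call. = FALSE)
  }
  bad_rich <- which(!is.finite(studies$richness) | studies$richness < 0)
  if (length(bad_rich) > 0) {
    stop("negative or missing richness at row ",
         paste(utils::head(bad_rich, 5L), collapse = ", "), call. = FALSE)
  }
  bad_tax <- setdiff(unique(studies$taxon_group), c("invertebrates", "plants"))
  if (length(bad_tax) > 0) {
    stop("unknown taxon_group: ", paste(sQuote(bad_tax), collapse = ", "),
         call. = FALSE)
  }
  studies$habitat <- normalize_habitat(studies$habitat)
  studies
}

#' Read a layout table of habitat areas
#'
#' A layout maps each habitat type to its total area under one scenario.
#' Habitats absent from the file default to area 0, so a layout always covers
#' the full 19-habitat vocabulary.
#'
#' @param path Path to a CSV file with columns `habitat`, `area_m2`.
#' @param scenario Name for the scenario (e.g. `"current"`).
#' @param aliases Optional habitat alias map.
#' @return A tibble with columns `scenario`, `habitat`, `area_m2`, one row per
#'   habitat in the vocabulary.
#' @export
read_layout_table <- function(path, scenario = "layout", aliases = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    return(layout_table(scenario = scenario))
  }
  miss <- setdiff(c("habitat", "area_m2"), names(df))
  if (length(miss) > 0) {
    stop("layout table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  layout_table(
    habitat = normalize_habitat(df$habitat, aliases),
    area_m2 = as.numeric(df$area_m2),
    scenario = scenario
  )
}

#' Construct a layout table from habitat/area vectors
#'
#' @param habitat Character vector of habitat labels (canonical or aliased).
#' @param area_m2 Numeric vector of areas, same length; all must be >= 0.
#' @param scenario Scenario name.
#' @return A complete 19-row layout tibble; unlisted habitats get area 0.
#' @export
layout_table <- function(habitat = character(), area_m2 = numeric(),
                         scenario = "layout") {
  stopifnot(length(habitat) == length(area_m2))
  if (length(area_m2) > 0 && any(!is.finite(area_m2) | area_m2 < 0)) {
    stop("negative area_m2 at row ",
         paste(utils::head(which(!is.finite(area_m2) | area_m2 < 0), 5L),
               collapse = ", "), call. = FALSE)
  }
  habitat <- normalize_habitat(habitat)
  if (anyDuplicated(habitat)) {
    agg <- tapply(area_m2, habitat, sum)
    habitat <- names(agg)
    area_m2 <- unname(agg)
  }
  base <- habitat_types()["habitat"]
  out <- dplyr::left_join(base, tibble::tibble(habitat = habitat, area_m2 = area_m2),
                          by = "habitat")
  out$area_m2[is.na(out$area_m2)] <- 0
  dplyr::mutate(out, scenario = scenario, .before = 1)
}

#' Grounds layouts shipped with the package
#'
#' The habitat areas of the museum grounds under the current layout and the
#' proposed redevelopment, as tabulated in the planning documents.
#'
#' @param scenario `"current"` or `"proposed"`.
#' @return A layout tibble (see [read_layout_table()]).
#' @export
#' @examples
#' grounds_layout("current")
grounds_layout <- function(scenario = c("current", "proposed")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", paste0("layout_", scenario, ".csv"),
                      package = "groundscape", mustWork = TRUE)
  read_layout_table(path, scenario = scenario)
}

#' Read a zone-level occurrence table
#'
#' Occurrence records from a garden database: one row per (zone, habitat,
#' species, year) record. Used by the compositional-similarity analysis.
#'
#' @param path Path to a CSV with columns `zone_id`, `habitat`, `species_name`,
#'   `year`.
#' @param aliases Optional habitat alias map.
#' @return A validated occurrence tibble.
#' @export
read_occurrence_table <- function(path, aliases = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("zone_id", "habitat", "species_name", "year"), names(df))
  if (length(miss) > 0) {
    stop("occurrence table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    zone_id = as.character(df$zone_id),
    habitat = normalize_habitat(df$habitat, aliases),
    species_name = trimws(as.character(df$species_name)),
    year = as.integer(df$year)
  )
  bad <- is.na(out$species_name) | !nzchar(out$species_name)
  if (any(bad)) {
    stop("empty species_name at row ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  out
}
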