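#' Species sets per habitat from occurrence records
#'
#' Unions the species recorded in any zone of each habitat within the year
#' window (inclusive), after optional synonym canonicalization. Habitats with
#' no in-window records yield empty sets.
#'
#' @param occurrences An occurrence tibble (see [read_occurrence_table()]).
#' @param year_min,year_max Inclusive record window; defaults 2013-2015 (a
#'   multi-year window guards against species missed in any single survey
#'   year while staying recent).
#' @param synonyms Optional synonym map: named character vector or two-column
#'   data frame (`name`, `canonical`) collapsing name variants.
#' @return A named list of character vectors, one per habitat present in the
#'   table.
#' @export
habitat_species_sets <- function(occurrences, year_min = 2013, year_max = 2015,
                                 synonyms = NULL) {
  occ <- tibble::as_tibble(occurrences)
  occ <- occ[occ$year >= year_min & occ$year <= year_max, ]
  sp <- occ$species_name
  if (!is.null(synonyms)) {
    if (is.data.frame(synonyms)) {
      stopifnot(all(c("name", "canonical") %in% names(synonyms)))
      map <- stats::setNames(synonyms$canonical, synonyms$name)
    } else {
      map <- synonyms
    }
    hit <- match(sp, names(map))
    sp[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
  }
  split(sp, occ$habitat) |> lapply(function(s) sort(unique(s)))
}

#' Asymmetric percent-shared-species matrix
#'
#' For habitats x (rows) and y (columns), `M[x, y]` is the percentage of the
#' species found in habitat x that are also present in habitat y:
#' `100 * |S_x intersect S_y| / |S_x|`. Because the denominator is the row
#' habitat's own species count, the matrix is generally asymmetric — the two
#' triangles are not mirror images. Rows for empty habitats are undefined and
#' reported as `NA` (0/0 is not evidence of dissimilarity); the diagonal is
#' 100 for every non-empty habitat.
#'
#' @param sets Named list of species sets, e.g. from
#'   [habitat_species_sets()].
#' @return A numeric matrix with `dimnames` the habitat names, entries in
#'   `[0, 100]` or `NA`, of class `similarity_matrix`.
#' @export
similarity_matrix <- function(sets) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  habs <- names(sets)
  n <- length(habs)
  M <- matrix(NA_real_, n, n, dimnames = list(habs, habs))
  for (i in seq_len(n)) {
    nx <- length(sets[[i]])
    if (nx == 0) next
    for (j in seq_len(n)) {
      M[i, j] <- 100 * length(intersect(sets[[i]], sets[[j]])) / nx
    }
  }
  structure(M, class = c("similarity_matrix", class(M)))
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("Percent of row-habitat species shared with column habitat\n")
  print(round(unclass(x), 1), ...)
  invisible(x)
}

#' Tidy a similarity matrix into long form
#'
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `habitat_x`, `habitat_y`,
#'   `percent_shared`.
#' @method tidy similarity_matrix
#' @export
tidy.similarity_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble::tibble(
    habitat_x = rep(rownames(m), times = ncol(m)),
    habitat_y = rep(colnames(m), each = nrow(m)),
    percent_shared = as.vector(m)
  )
}
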