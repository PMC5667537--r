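#' Default coefficient-transfer rules
#'
#' Rules completing the coefficient set for the habitats that lack enough
#' collated data to be modelled, plus hard-standing. Hard-standing (asphalt
#' and pavement) is assumed to hold zero species. Each remaining unmodelled
#' habitat borrows the coefficient of an ecologically similar modelled
#' habitat, optionally adjusted by a multiplicative ratio derived from a
#' single comparative study:
#'
#' * ferns and cycad planting <- introduced shrubs (copy)
#' * paleogene asteraceae <- short/perennial vegetation (copy)
#' * neogene grass <- amenity grass/turf (copy)
#' * species-poor hedgerow <- species-rich hedgerow (ratio)
#' * introduced shrubs <- broadleaved woodland (ratio)
#' * cretaceous angiosperm shrubs <- broadleaved woodland (ratio)
#'
#' The adjustment arithmetic behind the ratio rules is not published as a
#' number; ratios default to 1.0 (plain copy) with a warning until the user
#' supplies study-derived values.
#'
#' @param ratios Named numeric vector of ratio overrides, names among
#'   `"species-poor hedgerow"`, `"introduced shrubs"`,
#'   `"cretaceous angiosperm shrubs"`.
#' @param quiet Suppress the default-ratio warning.
#' @return A tibble of rules: `target`, `mode` (`zero`/`copy`/`ratio`),
#'   `source`, `ratio`.
#' @export
default_transfer_rules <- function(ratios = NULL, quiet = FALSE) {
  rules <- tibble::tibble(
    target = c("hard-standing", "ferns and cycad planting",
               "paleogene asteraceae", "neogene grass",
               "species-poor hedgerow", "introduced shrubs",
               "cretaceous angiosperm shrubs"),
    mode   = c("zero", "copy", "copy", "copy", "ratio", "ratio", "ratio"),
    source = c(NA, "introduced shrubs", "short/perennial vegetation",
               "amenity grass/turf", "species-rich hedgerow",
               "broadleaved woodland", "broadleaved woodland"),
    ratio  = c(NA, NA, NA, NA, 1.0, 1.0, 1.0)
  )
  if (!is.null(ratios)) {
    bad <- setdiff(names(ratios), rules$target[rules$mode == "ratio"])
    if (length(bad) > 0) {
      stop("ratio override for non-ratio target(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    idx <- match(names(ratios), rules$target)
    rules$ratio[idx] <- as.numeric(ratios)
  } else if (!quiet) {
    warning("transfer ratios default to 1.0 (plain copy); supply ",
            "study-derived ratios via `ratios=` for adjusted transfers",
            call. = FALSE)
  }
  if (any(rules$mode == "ratio" & (!is.finite(rules$ratio) | rules$ratio <= 0))) {
    stop("transfer ratios must be positive", call. = FALSE)
  }
  rules
}

#' Complete a coefficient set by transfer rules
#'
#' Extends a modelled coefficient tibble (see [habitat_predictions()]) to the
#' full 19-habitat vocabulary. `zero` rules set estimate and SE to exactly 0
#' (provenance `"assumed-zero"`); `copy`/`ratio` rules scale the source
#' habitat's estimate and SE by the ratio (1 for copy; provenance
#' `"transferred"`, with the direct `source_habitat` recorded). Rules are
#' resolved iteratively, so a rule may source a habitat completed by an
#' earlier rule in the same set (the ferns-and-cycad coefficient is the
#' introduced-shrubs coefficient, which is itself adjusted from broadleaved
#' woodland); a source that never becomes available errors. Modelled entries
#' are never overwritten, and applying the same rules twice is a no-op.
#'
#' @param modelled Coefficient tibble with columns `habitat`, `estimate`,
#'   `se`, `provenance`.
#' @param rules Rule tibble from [default_transfer_rules()] or a compatible
#'   override.
#' @param require_complete Error unless the result covers all 19 habitats
#'   (default); disable for partial rule sets.
#' @return A complete coefficient tibble covering all 19 habitats, ordered as
#'   [habitat_types()].
#' @export
apply_transfers <- function(modelled, rules = default_transfer_rules(quiet = TRUE),
                            require_complete = TRUE) {
  modelled <- tibble::as_tibble(modelled)
  stopifnot(all(c("habitat", "estimate", "se", "provenance") %in% names(modelled)))
  if (!"source_habitat" %in% names(modelled)) modelled$source_habitat <- NA_character_
  if (!"response" %in% names(modelled)) modelled$response <- NA_character_
  rules$target <- normalize_habitat(rules$target)
  rules$source[!is.na(rules$source)] <- normalize_habitat(rules$source[!is.na(rules$source)])

  done <- modelled
  pending <- rules
  repeat {
    applied <- FALSE
    deferred <- pending[0, ]
    for (i in seq_len(nrow(pending))) {
      r <- pending[i, ]
      if (r$target %in% done$habitat) { applied <- TRUE; next }  # idempotence
      if (r$mode == "zero") {
        entry <- tibble::tibble(habitat = r$target, estimate = 0, se = 0,
                                conf_lo = 0, conf_hi = 0,
                                provenance = "assumed-zero",
                                source_habitat = NA_character_,
                                response = done$response[1])
      } else {
        src <- done[done$habitat == r$source, ]
        if (nrow(src) == 0) {  # source may be produced by a later rule
          deferred <- dplyr::bind_rows(deferred, r)
          next
        }
        k <- if (r$mode == "copy") 1 else r$ratio
        entry <- tibble::tibble(habitat = r$target,
                                estimate = src$estimate * k, se = src$se * k,
                                conf_lo = if ("conf_lo" %in% names(src)) src$conf_lo * k else NA_real_,
                                conf_hi = if ("conf_hi" %in% names(src)) src$conf_hi * k else NA_real_,
                                provenance = "transferred",
                                source_habitat = r$source,
                                response = src$response)
      }
      done <- dplyr::bind_rows(done, entry)
      applied <- TRUE
    }
    if (nrow(deferred) == 0) break
    if (!applied) {
      stop("transfer source(s) ", paste(sQuote(deferred$source), collapse = ", "),
           " never available for target(s) ",
           paste(sQuote(deferred$target), collapse = ", "), call. = FALSE)
    }
    pending <- deferred
  }
  missing <- setdiff(habitat_types()$habitat, done$habitat)
  if (require_complete && length(missing) > 0) {
    stop("coefficient set incomplete after transfers; uncovered habitat(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  done[stats::na.omit(match(habitat_types()$habitat, done$habitat)), ]
}
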