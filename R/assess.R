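#' Per-habitat biodiversity score under an area-scaling assumption
#'
#' The three assumptions differ in how within-sample diversity is taken to
#' scale with habitat area when a coefficient is applied to a patch:
#'
#' * **A1** — area-scaling of both input data and model output: the species
#'   density coefficient is rescaled to the patch area via the SAR exponent.
#' * **A2** — area-scaling of input data only: the density coefficient is
#'   used as-is.
#' * **A3** — no area-scaling: the within-sample richness coefficient is used
#'   as-is.
#'
#' A1/A2 therefore require a density-response coefficient set and A3 a
#' richness-response one; a mismatch errors.
#'
#' @param estimate Non-negative coefficient (expected species count).
#' @param area_m2 Patch area, >= 0.
#' @param assumption `"A1"`, `"A2"` or `"A3"`.
#' @param sar [sar_params()]; used only under A1.
#' @param response Response the coefficient was fitted on (`"density10"` or
#'   `"richness"`); `NA` skips the compatibility check.
#' @return The per-unit-area score (numeric, vectorized).
#' @export
habitat_score <- function(estimate, area_m2, assumption = c("A1", "A2", "A3"),
                          sar = sar_params(), response = NA_character_) {
  assumption <- match.arg(assumption)
  ok <- is.na(response) |
    (assumption %in% c("A1", "A2") & response == "density10") |
    (assumption == "A3" & response == "richness")
  if (!all(ok)) {
    stop("assumption ", assumption, " requires a ",
         if (assumption == "A3") "richness" else "density",
         "-response coefficient set", call. = FALSE)
  }
  if (assumption == "A1") density_at_area(estimate, area_m2, sar) else estimate
}

#' Area-weighted total score of a layout
#'
#' Multiplies each habitat's score by its area in the layout and sums across
#' all habitats: the scenario's biodiversity score. Zero-area habitats
#' contribute 0, and hard-standing contributes 0 through its assumed-zero
#' coefficient.
#'
#' @param coeffs A complete coefficient tibble (see [apply_transfers()]).
#' @param layout A layout tibble (see [read_layout_table()]).
#' @param assumption `"A1"`, `"A2"` or `"A3"`.
#' @param sar [sar_params()].
#' @return The total score (numeric scalar, score x m2 units).
#' @export
layout_total <- function(coeffs, layout, assumption = c("A1", "A2", "A3"),
                         sar = sar_params()) {
  assumption <- match.arg(assumption)
  need <- layout$habitat[layout$area_m2 > 0]
  missing <- setdiff(need, coeffs$habitat)
  if (length(missing) > 0) {
    stop("layout habitat(s) missing from coefficient set: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(layout), "habitat", "area_m2"),
    dplyr::select(tibble::as_tibble(coeffs), "habitat", "estimate", "response"),
    by = "habitat"
  )
  scores <- habitat_score(joined$estimate, joined$area_m2, assumption, sar,
                          response = joined$response)
  sum(scores * joined$area_m2)
}

#' Compare two layouts under all three assumptions
#'
#' Scores the current and proposed layouts under A1, A2 (density
#' coefficients) and A3 (richness coefficients) and reports the percent
#' change `100 * (proposed - current) / current` for each. A zero current
#' total leaves the percent change undefined (`NA`) rather than infinite.
#'
#' @param coeffs_density Complete density-response coefficient tibble.
#' @param coeffs_richness Complete richness-response coefficient tibble.
#' @param current,proposed Layout tibbles.
#' @param sar [sar_params()].
#' @return An object of class `layout_assessment`: a tibble with one row per
#'   assumption (`assumption`, `total_current`, `total_proposed`,
#'   `percent_change`).
#' @export
assess_layouts <- function(coeffs_density, coeffs_richness,
                           current, proposed, sar = sar_params()) {
  one <- function(a) {
    cf <- if (a == "A3") coeffs_richness else coeffs_density
    cur <- layout_total(cf, current, a, sar)
    pro <- layout_total(cf, proposed, a, sar)
    tibble::tibble(
      assumption = a, total_current = cur, total_proposed = pro,
      percent_change = if (cur > 0) 100 * (pro - cur) / cur else NA_real_
    )
  }
  out <- dplyr::bind_rows(lapply(c("A1", "A2", "A3"), one))
  structure(out, class = c("layout_assessment", class(out)),
            sar = sar,
            scenarios = c(current$scenario[1], proposed$scenario[1]))
}

#' @export
print.layout_assessment <- function(x, ...) {
  sc <- attr(x, "scenarios")
  cat("Layout assessment:", sc[1], "->", sc[2],
      "(z =", attr(x, "sar")$z, ")\n")
  NextMethod()
}

#' @param x A `layout_assessment`.
#' @param ... Unused.
#' @rdname assess_layouts
#' @method glance layout_assessment
#' @export
glance.layout_assessment <- function(x, ...) {
  tidyr::pivot_wider(
    tibble::as_tibble(x)[, c("assumption", "percent_change")],
    names_from = "assumption", values_from = "percent_change",
    names_prefix = "percent_change_"
  )
}
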