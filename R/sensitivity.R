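#' Draw a coefficient set from its sampling distribution
#'
#' One independent normal draw per habitat: mean the coefficient estimate,
#' standard deviation its standard error — inflated by
#' `se_inflation_transferred` for transferred habitats to reflect their extra
#' uncertainty. Assumed-zero habitats stay exactly 0. Negative draws are kept
#' unless `clip = TRUE` truncates them at 0.
#'
#' @param coeffs Complete coefficient tibble.
#' @param se_inflation_transferred Multiplier (>= 1) on transferred SEs,
#'   default 1.5.
#' @param clip Truncate draws at 0.
#' @return The coefficient tibble with `estimate` replaced by the draw.
#' @export
draw_coefficients <- function(coeffs, se_inflation_transferred = 1.5,
                              clip = FALSE) {
  stopifnot(se_inflation_transferred >= 1)
  sd <- coeffs$se *
    ifelse(coeffs$provenance == "transferred", se_inflation_transferred, 1)
  sd[coeffs$provenance == "assumed-zero"] <- 0
  draw <- stats::rnorm(nrow(coeffs), mean = coeffs$estimate, sd = sd)
  draw[coeffs$provenance == "assumed-zero"] <- 0
  if (clip) draw <- pmax(draw, 0)
  out <- coeffs
  out$estimate <- draw
  out
}

#' Monte Carlo sensitivity of the percent change
#'
#' Propagates coefficient uncertainty into the layout comparison: in each of
#' `n_reps` replicates a single coefficient set is drawn with
#' [draw_coefficients()] and used for *both* scenario totals (so shared
#' habitats cancel rather than adding spurious variance), and the percent
#' change is recorded. Reports the fraction of replicates with a negative
#' change (biodiversity loss) and summary quantiles. Replicates whose current
#' total is not positive are excluded from the fraction and counted.
#'
#' @param coeffs Complete coefficient tibble matching the assumption
#'   (density response for A1/A2, richness response for A3).
#' @param current,proposed Layout tibbles.
#' @param assumption `"A1"`, `"A2"` or `"A3"`.
#' @param sar [sar_params()].
#' @param n_reps Number of replicates, default 1000.
#' @param seed Integer seed; recorded in the result for exact rerun.
#' @param se_inflation_transferred SE multiplier for transferred habitats.
#' @param clip Truncate negative coefficient draws at 0.
#' @return An object of class `sensitivity_result`: list with `draws` (tibble
#'   of per-replicate percent changes), `fraction_negative`, `quantiles`,
#'   `n_undefined`, and the configuration.
#' @export
run_sensitivity <- function(coeffs, current, proposed,
                            assumption = c("A1", "A2", "A3"),
                            sar = sar_params(), n_reps = 1000, seed = 1L,
                            se_inflation_transferred = 1.5, clip = FALSE) {
  assumption <- match.arg(assumption)
  stopifnot(n_reps >= 1, se_inflation_transferred >= 1)
  # cheap compatibility/coverage validation on the point estimates
  invisible(layout_total(coeffs, current, assumption, sar))
  invisible(layout_total(coeffs, proposed, assumption, sar))
  # every total is linear in the coefficient vector: total = sum(c_h * w_h),
  # with w_h the (possibly SAR-rescaled) area weight, so replicates reduce to
  # a draws-matrix product instead of per-replicate joins
  area_weight <- function(layout) {
    a <- layout$area_m2[match(coeffs$habitat, layout$habitat)]
    a[is.na(a)] <- 0
    if (assumption == "A1") {
      ifelse(a == 0 & sar$z > 0, 0, (a / sar$reference_area_m2)^sar$z) * a
    } else {
      a
    }
  }
  w_cur <- area_weight(current)
  w_pro <- area_weight(proposed)
  sd <- coeffs$se *
    ifelse(coeffs$provenance == "transferred", se_inflation_transferred, 1)
  sd[coeffs$provenance == "assumed-zero"] <- 0
  nh <- nrow(coeffs)
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n_reps * nh), nrow = n_reps, byrow = TRUE)
  draws <- sweep(sweep(Z, 2, sd, "*"), 2, coeffs$estimate, "+")
  draws[, coeffs$provenance == "assumed-zero"] <- 0
  if (clip) draws <- pmax(draws, 0)
  cur <- drop(draws %*% w_cur)
  pro <- drop(draws %*% w_pro)
  pc <- ifelse(cur > 0, 100 * (pro - cur) / cur, NA_real_)
  ok <- !is.na(pc)
  structure(
    list(
      draws = tibble::tibble(rep = seq_len(n_reps), percent_change = pc),
      fraction_negative = sum(pc[ok] < 0) / sum(ok),
      n_undefined = sum(!ok),
      quantiles = stats::quantile(pc[ok], c(0.025, 0.25, 0.5, 0.75, 0.975)),
      assumption = assumption, n_reps = n_reps, seed = as.integer(seed),
      se_inflation_transferred = se_inflation_transferred, clip = clip,
      sar = sar
    ),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sensitivity analysis (", x$assumption, ", ", x$n_reps,
      " reps, seed ", x$seed, ")\n", sep = "")
  cat("  fraction of replicates with net loss:",
      signif(x$fraction_negative, 4), "\n")
  cat("  percent-change quantiles:\n")
  print(round(x$quantiles, 2))
  if (x$n_undefined > 0) {
    cat("  ", x$n_undefined, "replicate(s) with non-positive current total",
        "excluded\n")
  }
  invisible(x)
}

#' @param x A `sensitivity_result`.
#' @param ... Unused.
#' @rdname run_sensitivity
#' @method tidy sensitivity_result
#' @export
tidy.sensitivity_result <- function(x, ...) x$draws

#' @rdname run_sensitivity
#' @method glance sensitivity_result
#' @export
glance.sensitivity_result <- function(x, ...) {
  tibble::tibble(
    assumption = x$assumption, n_reps = x$n_reps,
    fraction_negative = x$fraction_negative,
    median_percent_change = unname(x$quantiles["50%"]),
    q2.5 = unname(x$quantiles["2.5%"]), q97.5 = unname(x$quantiles["97.5%"]),
    n_undefined = x$n_undefined, seed = x$seed
  )
}
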