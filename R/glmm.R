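#' Round a response to integer counts
#'
#' Rounds non-negative response values to the nearest integer, halves away
#' from zero (2.5 -> 3), so that standardized densities and digitized richness
#' values can carry a Poisson error structure. Base R's `round()` rounds
#' half-to-even and is deliberately not used.
#'
#' @param values Non-negative numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_response(c(39.716, 2.5, 0))
round_response <- function(values) {
  if (any(!is.finite(values) | values < 0)) {
    stop("response values must be non-negative and finite", call. = FALSE)
  }
  floor(values + 0.5)
}

# Build the model frame: rounded counts + factors.
.model_frame <- function(studies, response, sar) {
  studies <- validate_study_table(studies)
  y <- switch(response,
    density10 = species_density(studies$richness, studies$sampled_area_m2, sar),
    richness  = studies$richness
  )
  tibble::tibble(
    count = round_response(y),
    habitat = factor(studies$habitat, levels = sort(unique(studies$habitat))),
    taxon_group = factor(studies$taxon_group,
                         levels = c("invertebrates", "plants")),
    study_id = factor(studies$study_id)
  )
}

#' Fit the per-habitat Poisson mixed model
#'
#' Estimates the expected species count of each habitat type (species density
#' per reference frame, or within-sample richness) from a collated study
#' table. The model is Poisson with log link, habitat type as a fixed effect
#' (optionally plus an additive taxon-group effect; no interaction), and a
#' study-level random intercept absorbing between-study methodological
#' heterogeneity. The marginal likelihood is maximized by [lme4::glmer()]'s
#' Laplace approximation. With a single study, or when `fix_sigma_zero =
#' TRUE`, the random intercept is dropped and a plain Poisson GLM is fitted
#' (the two coincide when the study variance is zero).
#'
#' @param studies A study table (see [read_literature_table()]).
#' @param response `"density10"` (richness standardized to the reference frame
#'   first) or `"richness"` (raw within-sample counts).
#' @param include_taxon Include the additive taxon-group effect.
#' @param sar [sar_params()] used for the density standardization.
#' @param fix_sigma_zero Force the study variance to zero (plain GLM).
#' @return An object of class `habitat_model`.
#' @export
fit_habitat_model <- function(studies, response = c("density10", "richness"),
                              include_taxon = FALSE, sar = sar_params(),
                              fix_sigma_zero = FALSE) {
  response <- match.arg(response)
  mf <- .model_frame(studies, response, sar)
  if (nlevels(droplevels(mf$habitat)) < 2) {
    if (dplyr::n_distinct(mf$habitat) < 1) stop("no habitats in data", call. = FALSE)
  }
  notes <- character()
  thin <- names(which(table(mf$habitat) < 2))
  if (length(thin) > 0) {
    notes <- c(notes, paste0("habitat(s) with <2 records: ",
                             paste(thin, collapse = ", ")))
  }
  if (include_taxon && nlevels(droplevels(mf$taxon_group)) < 2) {
    notes <- c(notes, "single taxon group present; taxon effect not estimable")
    include_taxon <- FALSE
  }
  use_glm <- fix_sigma_zero || nlevels(droplevels(mf$study_id)) < 2
  one_habitat <- nlevels(droplevels(mf$habitat)) == 1
  hab_term <- if (one_habitat) "1" else "0 + habitat"  # 1-level factors have no contrasts
  fixed <- if (include_taxon) paste("count ~", hab_term, "+ taxon_group")
           else paste("count ~", hab_term)
  converged <- TRUE
  if (use_glm) {
    fit <- stats::glm(stats::as.formula(fixed), family = stats::poisson(),
                      data = mf)
    converged <- fit$converged
    sigma_study <- 0
  } else {
    form <- stats::as.formula(paste(fixed, "+ (1 | study_id)"))
    fit <- withCallingHandlers(
      lme4::glmer(form, family = stats::poisson(), data = mf,
                  control = lme4::glmerControl(calc.derivs = TRUE)),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {  # e.g. boundary (singular) fit
        notes <<- c(notes, trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs)) {
      notes <- c(notes, unlist(msgs))
      converged <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
    }
    sigma_study <- sqrt(unname(lme4::VarCorr(fit)$study_id[1, 1]))
  }
  structure(
    list(fit = fit, response = response, include_taxon = include_taxon,
         engine = if (use_glm) "glm" else "glmer",
         sigma_study = sigma_study,
         log_lik = as.numeric(stats::logLik(fit)),
         df = attr(stats::logLik(fit), "df"),
         n_obs = nrow(mf), n_studies = nlevels(droplevels(mf$study_id)),
         habitats = levels(droplevels(mf$habitat)),
         converged = converged, notes = notes, sar = sar),
    class = "habitat_model"
  )
}

#' @export
print.habitat_model <- function(x, ...) {
  cat("Poisson", if (x$engine == "glmer") "mixed model" else "GLM",
      "of", if (x$response == "density10") "species density" else
        "within-sample species richness",
      "across", length(x$habitats), "habitats\n")
  cat("  ", x$n_obs, "sites,", x$n_studies, "studies; sigma_study =",
      signif(x$sigma_study, 4), "\n")
  cat("  logLik =", round(x$log_lik, 2), "| df =", x$df,
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Likelihood-ratio test between two nested habitat models
#'
#' Twice the log-likelihood difference, clipped at zero, against a chi-squared
#' reference with the difference in parameter counts as degrees of freedom. A
#' log-likelihood inversion beyond tolerance (the reduced model beating the
#' full one) indicates an optimizer failure and errors.
#'
#' @param full,reduced `habitat_model` objects, `reduced` nested in `full`.
#' @param term Name of the term dropped in `reduced`.
#' @param tol Permitted log-likelihood inversion before erroring.
#' @return A one-row tibble: `term`, `chisq`, `df`, `p_value`.
#' @export
lrt_habitat_models <- function(full, reduced, term = "term", tol = 0.01) {
  dll <- full$log_lik - reduced$log_lik
  if (dll < -tol) {
    stop("log-likelihood inversion (", signif(-2 * dll, 4),
         "): optimizer failure in nested comparison", call. = FALSE)
  }
  chisq <- max(0, 2 * dll)
  df <- full$df - reduced$df
  if (df < 1) stop("models are not nested (df difference < 1)", call. = FALSE)
  tibble::tibble(
    term = term, chisq = chisq, df = df,
    p_value = stats::pchisq(chisq, df = df, lower.tail = FALSE)
  )
}

#' Fit and simplify the habitat model
#'
#' Fits the maximal model (habitat + additive taxon effect), tests the taxon
#' effect by likelihood ratio, and drops it if its p-value exceeds `alpha`.
#' The habitat effect is never dropped silently: its own LRT against a model
#' without habitat is always computed and reported alongside.
#'
#' @inheritParams fit_habitat_model
#' @param alpha Retention threshold for the taxon effect (default 0.01: the
#'   term is removed when `p > alpha`).
#' @return A list with elements `model` (the retained `habitat_model`) and
#'   `lrt` (tibble of the taxon and habitat tests, with a `dropped` flag).
#' @export
simplify_habitat_model <- function(studies, response = c("density10", "richness"),
                                   sar = sar_params(), alpha = 0.01,
                                   fix_sigma_zero = FALSE) {
  response <- match.arg(response)
  maximal <- fit_habitat_model(studies, response, include_taxon = TRUE,
                               sar = sar, fix_sigma_zero = fix_sigma_zero)
  reduced <- fit_habitat_model(studies, response, include_taxon = FALSE,
                               sar = sar, fix_sigma_zero = fix_sigma_zero)
  if (!maximal$include_taxon) {
    # single taxon group: nothing to test, the reduced model is the model
    taxon_test <- tibble::tibble(term = "taxon_group", chisq = NA_real_,
                                 df = NA_integer_, p_value = NA_real_)
    keep_taxon <- FALSE
  } else {
    taxon_test <- lrt_habitat_models(maximal, reduced, term = "taxon_group")
    keep_taxon <- taxon_test$p_value <= alpha
  }
  retained <- if (keep_taxon) maximal else reduced
  # habitat significance on the retained fixed-effect structure
  mf <- .model_frame(studies, response, retained$sar)
  null_fixed <- if (retained$include_taxon) "count ~ taxon_group" else "count ~ 1"
  null_fit <- if (retained$engine == "glm") {
    stats::glm(stats::as.formula(null_fixed), family = stats::poisson(), data = mf)
  } else {
    suppressMessages(suppressWarnings(
      lme4::glmer(stats::as.formula(paste(null_fixed, "+ (1 | study_id)")),
                  family = stats::poisson(), data = mf)
    ))
  }
  null_ll <- as.numeric(stats::logLik(null_fit))
  null_df <- attr(stats::logLik(null_fit), "df")
  hab_chisq <- max(0, 2 * (retained$log_lik - null_ll))
  hab_df <- retained$df - null_df
  lrt <- dplyr::bind_rows(
    dplyr::mutate(taxon_test, dropped = !keep_taxon),
    tibble::tibble(term = "habitat", chisq = hab_chisq, df = hab_df,
                   p_value = stats::pchisq(hab_chisq, hab_df, lower.tail = FALSE),
                   dropped = FALSE)
  )
  list(model = retained, lrt = lrt)
}

#' Per-habitat predictions from a fitted model
#'
#' Predictions at random-effect zero for each habitat in the model, on the
#' response scale, with delta-method standard errors
#' (`SE_response = estimate * SE_link`) and normal-theory 95% intervals built
#' on the link scale. When a taxon effect is retained, predictions are taken
#' at the reference taxon level.
#'
#' @param model A converged `habitat_model`.
#' @return A coefficient tibble: `habitat`, `estimate`, `se`, `conf_lo`,
#'   `conf_hi`, `provenance` (`"modelled"`), `source_habitat` (`NA`),
#'   `response`.
#' @export
habitat_predictions <- function(model) {
  stopifnot(inherits(model, "habitat_model"))
  if (!model$converged) {
    stop("model did not converge; refusing to report predictions", call. = FALSE)
  }
  fit <- model$fit
  beta <- if (model$engine == "glmer") lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  habs <- model$habitats
  # contrast rows: habitat dummy at 1, any taxon columns at the reference (0)
  C <- matrix(0, nrow = length(habs), ncol = length(beta),
              dimnames = list(habs, names(beta)))
  for (h in habs) {
    col <- if (length(habs) == 1) "(Intercept)" else paste0("habitat", h)
    C[h, col] <- 1
  }
  eta <- unname(drop(C %*% beta))
  se_link <- unname(sqrt(pmax(0, diag(C %*% V %*% t(C)))))
  est <- exp(eta)
  tibble::tibble(
    habitat = habs,
    estimate = est,
    se = est * se_link,
    conf_lo = exp(eta - 1.96 * se_link),
    conf_hi = exp(eta + 1.96 * se_link),
    provenance = "modelled",
    source_habitat = NA_character_,
    response = model$response
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a habitat model
#'
#' @param x A `habitat_model`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` on the log-link scale.
#' @method tidy habitat_model
#' @export
tidy.habitat_model <- function(x, ...) {
  beta <- if (x$engine == "glmer") lme4::fixef(x$fit) else stats::coef(x$fit)
  se <- sqrt(diag(as.matrix(stats::vcov(x$fit))))
  tibble::tibble(term = names(beta), estimate = unname(beta),
                 std.error = unname(se))
}

#' One-row model summary
#'
#' @param x A `habitat_model`.
#' @param ... Unused.
#' @return A tibble with fit diagnostics: log-likelihood, parameter count,
#'   study-level standard deviation, sizes, convergence flag.
#' @method glance habitat_model
#' @export
glance.habitat_model <- function(x, ...) {
  tibble::tibble(
    response = x$response, engine = x$engine, logLik = x$log_lik, df = x$df,
    sigma_study = x$sigma_study, nobs = x$n_obs, n_studies = x$n_studies,
    n_habitats = length(x$habitats), converged = x$converged
  )
}
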