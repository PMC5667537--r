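#' Default ground-truth species densities for simulation
#'
#' Plausible expected species densities (per 10 m2 frame) for the twelve
#' habitats with directly modellable data, spanning the order of magnitude
#' seen in urban-habitat surveys: species-rich calcareous and neutral
#' grasslands at the top, ponds and fen at the bottom.
#'
#' @return Named numeric vector of densities per 10 m2.
#' @export
default_true_densities <- function() {
  c("chalk grassland" = 32, "neutral grassland" = 24,
    "broadleaved woodland" = 20, "species-rich hedgerow" = 16,
    "acid grassland" = 14, "agricultural plants" = 12,
    "short/perennial vegetation" = 11, "marginal vegetation" = 8,
    "amenity grass/turf" = 7, "green roof" = 5, "fen" = 4, "ponds" = 3)
}

#' Simulate a literature-extraction study table with known truth
#'
#' Generates sites from the same generative model the fitting stage assumes:
#' for a site in habitat h with sampled area A,
#' `lambda = D_h * (A / A_ref)^z * exp(b_study + taxon_effect * [invertebrates])`
#' with `b_study ~ Normal(0, study_sd^2)`, and observed richness drawn
#' Poisson(lambda). Sampled areas are log-uniform over
#' `[area_min, area_max]`, by default spanning 7 to 6.25 million m2 as in
#' small-patch urban surveys. Habitats are allocated to studies round-robin
#' (each study compares several habitats, and every habitat is covered).
#'
#' @param n_studies Number of studies (default 14).
#' @param true_densities Named vector of per-habitat expected densities at
#'   the reference frame (response scale).
#' @param study_sd Log-scale SD of the study random intercept (default 0.4).
#' @param taxon_effect Additive log-scale effect of sampling invertebrates
#'   rather than plants (default 0).
#' @param sites_per_study Sites per study (default 8).
#' @param habitats_per_study Habitats compared within one study (default 4,
#'   capped at the number of habitats).
#' @param area_min,area_max Bounds of the log-uniform sampled-area
#'   distribution in m2.
#' @param sar [sar_params()]; its exponent enters the mean structure, so the
#'   density-standardization pipeline is consistent by construction.
#' @param seed Integer seed.
#' @return A list: `studies` (a study table), `truth` (list with
#'   `densities`, `study_sd`, `taxon_effect`, `study_intercepts`, `lambda`).
#' @export
simulate_literature <- function(n_studies = 14,
                                true_densities = default_true_densities(),
                                study_sd = 0.4, taxon_effect = 0,
                                sites_per_study = 8, habitats_per_study = 4,
                                area_min = 7, area_max = 6.25e6,
                                sar = sar_params(), seed = 1L) {
  stopifnot(n_studies >= 1, all(true_densities > 0), study_sd >= 0,
            area_min > 0, area_max >= area_min, sites_per_study >= 1)
  habs <- names(true_densities)
  stopifnot(!is.null(habs))
  habs <- normalize_habitat(habs)
  names(true_densities) <- habs
  k <- min(habitats_per_study, length(habs))
  set.seed(as.integer(seed))
  b <- stats::rnorm(n_studies, 0, study_sd)
  taxa <- rep(c("plants", "invertebrates"), length.out = n_studies)
  # round-robin over a shuffled habitat cycle guarantees coverage
  cycle <- rep(sample(habs), length.out = n_studies * k)
  rows <- purrr::map_dfr(seq_len(n_studies), function(s) {
    mine <- cycle[((s - 1) * k + 1):(s * k)]
    hab <- rep(mine, length.out = sites_per_study)
    area <- exp(stats::runif(sites_per_study, log(area_min), log(area_max)))
    lambda <- true_densities[hab] *
      (area / sar$reference_area_m2)^sar$z *
      exp(b[s] + taxon_effect * (taxa[s] == "invertebrates"))
    tibble::tibble(
      study_id = sprintf("study_%02d", s),
      taxon_group = taxa[s],
      habitat = hab,
      sampled_area_m2 = area,
      richness = as.numeric(stats::rpois(sites_per_study, lambda)),
      .lambda = unname(lambda)
    )
  })
  list(
    studies = dplyr::select(rows, -".lambda"),
    truth = list(densities = true_densities, study_sd = study_sd,
                 taxon_effect = taxon_effect,
                 study_intercepts = stats::setNames(b, sprintf("study_%02d",
                                                               seq_len(n_studies))),
                 lambda = rows$.lambda, sar = sar, seed = as.integer(seed))
  )
}

#' Simulate zone-level occurrence records with a known similarity truth
#'
#' Each habitat retains every species of a shared pool independently with its
#' retention probability, so the expected percent-shared matrix is available
#' in closed form: `E M[x, y] ~= 100 * p_y` for `x != y` (independence), and
#' 100 on the diagonal. Records are spread over zones and years within the
#' window.
#'
#' @param habitats Character vector of habitat labels.
#' @param pool_size Size of the shared species pool.
#' @param retention Per-habitat retention probabilities in `[0, 1]` (scalar
#'   recycled, or named vector).
#' @param years Integer vector of record years (default 2013:2015).
#' @param zones_per_habitat Zones each habitat's records are spread across.
#' @param seed Integer seed.
#' @return A list: `occurrences` (tibble), `truth` (expected
#'   `similarity_matrix`), `sets` (the realized species sets).
#' @export
simulate_occurrences <- function(habitats, pool_size = 1000, retention = 0.6,
                                 years = 2013:2015, zones_per_habitat = 2,
                                 seed = 1L) {
  habitats <- normalize_habitat(habitats)
  p <- rep(retention, length.out = length(habitats))
  names(p) <- habitats
  stopifnot(all(p >= 0 & p <= 1), pool_size >= 1)
  set.seed(as.integer(seed))
  pool <- sprintf("sp%05d", seq_len(pool_size))
  sets <- lapply(habitats, function(h) pool[stats::runif(pool_size) < p[h]])
  names(sets) <- habitats
  occ <- purrr::map_dfr(habitats, function(h) {
    s <- sets[[h]]
    if (length(s) == 0) return(NULL)
    tibble::tibble(
      zone_id = paste0(gsub("[^a-z]", "", h),
                       sample.int(zones_per_habitat, length(s), replace = TRUE)),
      habitat = h,
      species_name = s,
      year = sample(years, length(s), replace = TRUE)
    )
  })
  n <- length(habitats)
  truth <- matrix(rep(100 * p, each = n), n, n,
                  dimnames = list(habitats, habitats))
  diag(truth) <- 100
  truth[p == 0, ] <- NA_real_  # empty row habitat -> undefined
  list(occurrences = occ,
       truth = structure(truth, class = c("similarity_matrix", "matrix", "array")),
       sets = sets)
}

#' Simulate a pair of scenario layouts from allocation weights
#'
#' Splits a fixed total area across habitats proportionally to each
#' scenario's weights. With true densities in hand the percent change under
#' assumption A2 is then available analytically via
#' [analytic_percent_change()].
#'
#' @param habitats Character vector of habitat labels.
#' @param total_area_m2 Total area shared by both scenarios (default 21,800
#'   m2, a ~2.2 ha grounds).
#' @param weights_current,weights_proposed Non-negative allocation weights
#'   (recycled; normalized internally).
#' @return A list of two layout tibbles, `current` and `proposed`.
#' @export
simulate_layouts <- function(habitats, total_area_m2 = 21800,
                             weights_current = 1, weights_proposed = 1) {
  habitats <- normalize_habitat(habitats)
  wc <- rep(weights_current, length.out = length(habitats))
  wp <- rep(weights_proposed, length.out = length(habitats))
  stopifnot(all(wc >= 0), all(wp >= 0), sum(wc) > 0, sum(wp) > 0)
  list(
    current = layout_table(habitats, total_area_m2 * wc / sum(wc), "current"),
    proposed = layout_table(habitats, total_area_m2 * wp / sum(wp), "proposed")
  )
}

#' Analytic percent change under assumption A2
#'
#' The closed-form area-weighted percent change
#' `100 * (sum D_h a'_h - sum D_h a_h) / (sum D_h a_h)` implied by known true
#' densities; the oracle for end-to-end recovery tests.
#'
#' @param true_densities Named numeric vector of densities.
#' @param current,proposed Layout tibbles.
#' @return Numeric scalar percent change.
#' @export
analytic_percent_change <- function(true_densities, current, proposed) {
  d <- tibble::tibble(habitat = normalize_habitat(names(true_densities)),
                      density = unname(true_densities))
  cur <- dplyr::inner_join(current, d, by = "habitat")
  pro <- dplyr::inner_join(proposed, d, by = "habitat")
  tc <- sum(cur$density * cur$area_m2)
  tp <- sum(pro$density * pro$area_m2)
  100 * (tp - tc) / tc
}
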