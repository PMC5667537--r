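test_that("round_response rounds halves away from zero", {
  expect_equal(round_response(39.716), 40)
  expect_equal(round_response(2.5), 3)
  expect_equal(round_response(0.5), 1)
  expect_equal(round_response(0), 0)
  expect_equal(round_response(c(1.4999, 3.5)), c(1, 4))
  expect_error(round_response(-0.1), "non-negative")
})

test_that("single study, single habitat: prediction is the mean of rounded counts", {
  counts <- c(3, 7, 5, 4, 6, 5, 8, 2)
  st <- tibble::tibble(
    study_id = "s1", taxon_group = "plants", habitat = "fen",
    sampled_area_m2 = 10, richness = counts  # area = reference: no rescaling
  )
  m <- fit_habitat_model(st, "density10")
  expect_equal(m$engine, "glm")  # one study -> sigma^2 = 0 path
  pr <- habitat_predictions(m)
  expect_equal(pr$estimate, mean(counts), tolerance = 1e-8)
  # delta method: SE_response = estimate * SE_link, Poisson SE_link = 1/sqrt(sum)
  expect_equal(pr$se, mean(counts) / sqrt(sum(counts)), tolerance = 1e-5)
})

test_that("with sigma^2 = 0 mixed estimates equal plain Poisson GLM means", {
  withr::local_seed(7)
  for (i in 1:5) {
    nh <- sample(2:4, 1)
    habs <- sample(habitat_types()$habitat[-1], nh)
    st <- tibble::tibble(
      study_id = rep(c("a", "b", "c"), each = 4 * nh),
      taxon_group = "plants",
      habitat = rep(rep(habs, each = 4), 3),
      sampled_area_m2 = 10,
      richness = stats::rpois(12 * nh, lambda = 9)
    )
    m <- fit_habitat_model(st, "density10", fix_sigma_zero = TRUE)
    pr <- habitat_predictions(m)
    oracle <- tapply(round_response(st$richness), st$habitat, mean)
    expect_equal(pr$estimate[match(names(oracle), pr$habitat)],
                 as.numeric(oracle), tolerance = 1e-7)
  }
})

test_that("duplicating records under fresh study ids leaves sigma0 estimates unchanged", {
  st <- tiny_studies()
  dup <- dplyr::mutate(st, study_id = paste0(study_id, "_copy"))
  m1 <- fit_habitat_model(st, "richness", fix_sigma_zero = TRUE)
  m2 <- fit_habitat_model(dplyr::bind_rows(st, dup), "richness",
                          fix_sigma_zero = TRUE)
  expect_equal(habitat_predictions(m1)$estimate,
               habitat_predictions(m2)$estimate, tolerance = 1e-8)
})

test_that("mixed model recovers known truth on generated data", {
  sim <- simulate_literature(n_studies = 12, sites_per_study = 30,
                             study_sd = 0.3, seed = 11)
  m <- fit_habitat_model(sim$studies, "density10")
  expect_equal(m$engine, "glmer")
  expect_true(m$converged)
  pr <- habitat_predictions(m)
  truth <- sim$truth$densities[pr$habitat]
  # point estimates in the right place and sigma_study near 0.3
  expect_true(all(abs(log(pr$estimate) - log(truth)) < 0.5))
  expect_gt(m$sigma_study, 0.1)
  expect_lt(m$sigma_study, 0.6)
})

test_that("predictions are equivariant under habitat relabeling", {
  sim <- simulate_literature(n_studies = 6, sites_per_study = 10, seed = 5,
                             true_densities = c("fen" = 5, "ponds" = 10,
                                                "green roof" = 15))
  st <- sim$studies
  swap <- c("fen" = "ponds", "ponds" = "fen", "green roof" = "green roof")
  st2 <- dplyr::mutate(st, habitat = unname(swap[habitat]))
  p1 <- habitat_predictions(fit_habitat_model(st, "richness"))
  p2 <- habitat_predictions(fit_habitat_model(st2, "richness"))
  expect_equal(p1$estimate[p1$habitat == "fen"],
               p2$estimate[p2$habitat == "ponds"], tolerance = 1e-6)
  expect_equal(p1$estimate[p1$habitat == "green roof"],
               p2$estimate[p2$habitat == "green roof"], tolerance = 1e-6)
})

test_that("taxon effect simulated as zero is dropped at alpha = 0.01", {
  withr::local_seed(19)
  dropped <- vapply(1:100, function(i) {
    sim <- simulate_literature(
      n_studies = 8, sites_per_study = 12, study_sd = 0, taxon_effect = 0,
      true_densities = c("fen" = 8, "ponds" = 12, "chalk grassland" = 20),
      habitats_per_study = 3, sar = sar_params(z = 0), seed = 1000 + i
    )
    simplify_habitat_model(sim$studies, "richness",
                           fix_sigma_zero = TRUE)$lrt$dropped[1]
  }, logical(1))
  expect_gte(mean(dropped), 0.95)
})

test_that("comparing a model with itself gives chi-square 0 and no drop signal", {
  m <- fit_habitat_model(tiny_studies(), "richness", fix_sigma_zero = TRUE)
  m2 <- m
  m2$df <- m$df + 1  # pretend one extra parameter, same likelihood
  res <- lrt_habitat_models(m2, m, term = "noop")
  expect_equal(res$chisq, 0)
  expect_equal(res$p_value, 1)
})

test_that("log-likelihood inversion beyond tolerance errors", {
  m <- fit_habitat_model(tiny_studies(), "richness", fix_sigma_zero = TRUE)
  worse <- m
  worse$log_lik <- m$log_lik - 1
  worse$df <- m$df + 1
  expect_error(lrt_habitat_models(worse, m), "inversion")
})

test_that("all-zero-count habitat drives the estimate to the boundary", {
  st <- tibble::tibble(
    study_id = rep(c("a", "b"), each = 6),
    taxon_group = "plants",
    habitat = rep(c("fen", "ponds", "green roof"), 4),
    sampled_area_m2 = 10,
    richness = rep(c(5, 0, 7), 4)  # ponds never seen
  )
  m <- fit_habitat_model(st, "richness", fix_sigma_zero = TRUE)
  pr <- habitat_predictions(m)
  pond <- pr[pr$habitat == "ponds", ]
  expect_lt(pond$estimate, 1e-4)
  expect_gt(pond$conf_hi / max(pond$estimate, 1e-12), 10)  # wide interval
})

test_that("unconverged models refuse to report predictions", {
  m <- fit_habitat_model(tiny_studies(), "richness", fix_sigma_zero = TRUE)
  m$converged <- FALSE
  expect_error(habitat_predictions(m), "converge")
})

test_that("tidy and glance expose the fit surface", {
  m <- fit_habitat_model(tiny_studies(), "richness")
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$nobs, 6)
  expect_equal(gl$n_studies, 2)
  expect_true(is.finite(gl$logLik))
})
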