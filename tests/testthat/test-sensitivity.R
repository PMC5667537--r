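test_that("draw_coefficients honours SEs, inflation and provenance", {
  cf <- make_coeffs()
  # degenerate: all SEs zero -> draw equals the point set
  cf0 <- dplyr::mutate(cf, se = 0)
  set.seed(1)
  expect_equal(draw_coefficients(cf0)$estimate, cf0$estimate)

  # transferred SE 0.4 with inflation 1.5 -> sample sd 0.6 within 1%
  cf1 <- make_coeffs()
  cf1$provenance[cf1$habitat == "fen"] <- "transferred"
  cf1$se[cf1$habitat == "fen"] <- 0.4
  set.seed(42)
  draws <- replicate(1e5, draw_coefficients(cf1[cf1$habitat == "fen", ],
                                            1.5)$estimate)
  expect_equal(stats::sd(draws), 0.6, tolerance = 0.01)

  # assumed-zero stays exactly zero
  set.seed(3)
  d <- draw_coefficients(cf)
  expect_equal(d$estimate[d$provenance == "assumed-zero"], 0)

  # clipping truncates at zero
  cfneg <- dplyr::mutate(cf, estimate = 0.01, se = 5)
  set.seed(4)
  expect_true(all(draw_coefficients(cfneg, clip = TRUE)$estimate >= 0))
  set.seed(4)
  expect_true(any(draw_coefficients(cfneg, clip = FALSE)$estimate < 0))
})

test_that("fixed seed gives identical sensitivity runs", {
  cf <- make_coeffs()
  cur <- make_layout(c("fen" = 100, "ponds" = 200), "current")
  pro <- make_layout(c("fen" = 300, "ponds" = 50), "proposed")
  r1 <- run_sensitivity(cf, cur, pro, "A2", n_reps = 200, seed = 99)
  r2 <- run_sensitivity(cf, cur, pro, "A2", n_reps = 200, seed = 99)
  expect_identical(r1$draws, r2$draws)
  expect_identical(r1$fraction_negative, r2$fraction_negative)
})

test_that("a habitat shared with equal areas cancels exactly", {
  cf <- make_coeffs()
  lay <- make_layout(c("fen" = 150), "current")
  res <- run_sensitivity(cf, lay, dplyr::mutate(lay, scenario = "proposed"),
                         "A2", n_reps = 500, seed = 7)
  expect_true(all(res$draws$percent_change == 0))
  expect_equal(res$fraction_negative, 0)
})

test_that("fraction_negative matches the normal-tail closed form", {
  # baseline habitat with SE 0 in both layouts; one habitat only in the
  # proposed layout with mu = sigma -> P(loss) = Phi(-1) ~= 0.1587
  cf <- make_coeffs()
  cf$estimate <- 0; cf$se <- 0
  cf$estimate[cf$habitat == "fen"] <- 5
  cf$estimate[cf$habitat == "ponds"] <- 2
  cf$se[cf$habitat == "ponds"] <- 2
  cur <- make_layout(c("fen" = 100), "current")
  pro <- make_layout(c("fen" = 100, "ponds" = 80), "proposed")
  res <- run_sensitivity(cf, cur, pro, "A2", n_reps = 1e5, seed = 123)
  mc_se <- sqrt(0.1587 * (1 - 0.1587) / 1e5)
  expect_equal(res$fraction_negative, stats::pnorm(-1),
               tolerance = 3 * mc_se / stats::pnorm(-1))
})

test_that("as SEs shrink the draw distribution collapses to the point estimate", {
  cfd <- make_coeffs("density10")
  cur <- make_layout(c("fen" = 100, "ponds" = 300), "current")
  pro <- make_layout(c("fen" = 250, "ponds" = 100), "proposed")
  point <- assess_layouts(cfd, make_coeffs("richness"), cur, pro)
  tiny <- dplyr::mutate(cfd, se = se * 1e-8)
  res <- run_sensitivity(tiny, cur, pro, "A2", n_reps = 200, seed = 5)
  expect_equal(max(abs(res$draws$percent_change - point$percent_change[2])),
               0, tolerance = 1e-5)
})

test_that("fraction_negative is invariant to habitat order", {
  cf <- make_coeffs()
  cur <- make_layout(c("fen" = 100, "ponds" = 200), "current")
  pro <- make_layout(c("fen" = 400, "ponds" = 20), "proposed")
  r1 <- run_sensitivity(cf, cur, pro, "A2", n_reps = 2000, seed = 11)
  perm <- sample(nrow(cf))
  r2 <- run_sensitivity(cf[perm, ], cur, pro, "A2", n_reps = 2000, seed = 11)
  # same seed but permuted assignment of normals: distributions agree closely
  expect_equal(r1$fraction_negative, r2$fraction_negative, tolerance = 0.05)
})

test_that("undefined replicates are excluded and counted", {
  cf <- make_coeffs()
  cf$estimate <- 0; cf$se <- 0
  cf$estimate[cf$habitat == "fen"] <- 0.5
  cf$se[cf$habitat == "fen"] <- 2  # current total frequently negative
  cur <- make_layout(c("fen" = 100), "current")
  pro <- make_layout(c("fen" = 200), "proposed")
  res <- run_sensitivity(cf, cur, pro, "A2", n_reps = 2000, seed = 2)
  expect_gt(res$n_undefined, 0)
  expect_equal(nrow(res$draws), 2000)
  # with clipping all totals are >= 0 and percent changes shared-scale
  resc <- run_sensitivity(cf, cur, pro, "A2", n_reps = 2000, seed = 2,
                          clip = TRUE)
  expect_true(all(resc$draws$percent_change >= 0 |
                    is.na(resc$draws$percent_change)))
})
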