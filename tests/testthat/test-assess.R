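test_that("habitat_score implements the three assumptions", {
  p <- sar_params(z = 0.1)
  expect_equal(habitat_score(4, 12345, "A2", p), 4)    # no output rescaling
  expect_equal(habitat_score(4, 10, "A1", p), 4)       # reference area
  expect_equal(habitat_score(4, 1000, "A1", p), 4 * 100^0.1, tolerance = 1e-12)
  # assumption/response mismatch errors
  expect_error(habitat_score(4, 10, "A1", p, response = "richness"), "density")
  expect_error(habitat_score(4, 10, "A3", p, response = "density10"),
               "richness")
  expect_equal(habitat_score(4, 10, "A3", p, response = "richness"), 4)
})

test_that("layout_total is the area-weighted sum of scores", {
  cf <- make_coeffs()
  cf$estimate <- 0
  cf$estimate[cf$habitat == "fen"] <- 2
  cf$estimate[cf$habitat == "ponds"] <- 3
  lay <- make_layout(c("fen" = 100, "ponds" = 50))
  expect_equal(layout_total(cf, lay, "A2"), 2 * 100 + 3 * 50)

  # all areas zero
  expect_equal(layout_total(cf, make_layout(c("fen" = 0)), "A2"), 0)

  # A1 brute-force oracle: one habitat, D = 2, area 1000, z = 0.1
  cf1 <- make_coeffs()
  cf1$estimate <- 0
  cf1$estimate[cf1$habitat == "fen"] <- 2
  expect_equal(layout_total(cf1, make_layout(c("fen" = 1000)), "A1",
                            sar_params(z = 0.1)),
               2 * 100^0.1 * 1000, tolerance = 1e-10)

  # positive-area habitat missing from the coefficient set errors
  expect_error(
    layout_total(cf[cf$habitat != "fen", ], lay, "A2"), "fen"
  )
})

test_that("hard-standing contributes zero through its assumed-zero coefficient", {
  cf <- make_coeffs()
  with_hs <- make_layout(c("hard-standing" = 10000, "fen" = 100))
  without <- make_layout(c("fen" = 100))
  expect_equal(layout_total(cf, with_hs, "A2"),
               layout_total(cf, without, "A2"))
})

test_that("assess_layouts reports totals and percent change per assumption", {
  cfd <- make_coeffs("density10")
  cfr <- make_coeffs("richness")
  cur <- make_layout(c("fen" = 200, "ponds" = 100), "current")
  pro <- make_layout(c("fen" = 100, "ponds" = 400), "proposed")
  res <- assess_layouts(cfd, cfr, cur, pro)
  expect_s3_class(res, "layout_assessment")
  expect_equal(res$assumption, c("A1", "A2", "A3"))
  # identity: proposed == current -> exactly 0% everywhere
  res0 <- assess_layouts(cfd, cfr, cur, cur)
  expect_equal(res0$percent_change, c(0, 0, 0))
  # A2 percent change against hand-computed weighted sums
  d <- cfd$estimate[match(c("fen", "ponds"), cfd$habitat)]
  expect_equal(res$percent_change[2],
               100 * (sum(d * c(100, 400)) - sum(d * c(200, 100))) /
                 sum(d * c(200, 100)), tolerance = 1e-12)
  # zero current total -> undefined percent change
  cf0 <- make_coeffs("density10"); cf0$estimate <- 0; cf0$se <- 0
  cr0 <- make_coeffs("richness"); cr0$estimate <- 0; cr0$se <- 0
  res_na <- assess_layouts(cf0, cr0, cur, pro)
  expect_true(all(is.na(res_na$percent_change)))
})

test_that("swapping layouts relates the two percent changes algebraically", {
  cfd <- make_coeffs("density10")
  cfr <- make_coeffs("richness")
  cur <- make_layout(c("fen" = 300, "chalk grassland" = 120), "current")
  pro <- make_layout(c("fen" = 50, "chalk grassland" = 600), "proposed")
  fwd <- assess_layouts(cfd, cfr, cur, pro)
  rev <- assess_layouts(cfd, cfr, pro, cur)
  # (1 + d_fwd/100) * (1 + d_rev/100) = 1 for each assumption
  expect_equal((1 + fwd$percent_change / 100) * (1 + rev$percent_change / 100),
               rep(1, 3), tolerance = 1e-12)
})

test_that("A2/A3 changes are invariant to common area rescaling; z=0 makes A1 = A2", {
  cfd <- make_coeffs("density10")
  cfr <- make_coeffs("richness")
  cur <- make_layout(c("fen" = 300, "ponds" = 120), "current")
  pro <- make_layout(c("fen" = 100, "ponds" = 500), "proposed")
  res <- assess_layouts(cfd, cfr, cur, pro)
  cur2 <- dplyr::mutate(cur, area_m2 = area_m2 * 7.3)
  pro2 <- dplyr::mutate(pro, area_m2 = area_m2 * 7.3)
  res2 <- assess_layouts(cfd, cfr, cur2, pro2)
  expect_equal(res$percent_change[2:3], res2$percent_change[2:3],
               tolerance = 1e-12)
  resz0 <- assess_layouts(cfd, cfr, cur, pro, sar_params(z = 0))
  expect_equal(resz0$percent_change[1], resz0$percent_change[2],
               tolerance = 1e-12)

  # additivity over a partition under A2: splitting fen's area across two
  # sub-layouts sums to the whole
  half <- dplyr::mutate(cur, area_m2 = area_m2 / 2)
  expect_equal(layout_total(cfd, cur, "A2"),
               2 * layout_total(cfd, half, "A2"), tolerance = 1e-12)

  # A1 superadditivity: one contiguous patch never scores below two halves
  expect_gte(layout_total(cfd, cur, "A1"), 2 * layout_total(cfd, half, "A1"))
})

test_that("glance widens the assessment to one row", {
  res <- assess_layouts(make_coeffs("density10"), make_coeffs("richness"),
                        make_layout(c("fen" = 10), "current"),
                        make_layout(c("fen" = 20), "proposed"))
  g <- glance(res)
  expect_equal(names(g), c("percent_change_A1", "percent_change_A2",
                           "percent_change_A3"))
  expect_equal(g$percent_change_A2, 100, tolerance = 1e-12)
})
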