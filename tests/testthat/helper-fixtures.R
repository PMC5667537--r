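# Small in-code fixtures shared across test files.

# a hand-sized study table: 2 studies, 3 habitats
tiny_studies <- function() {
  tibble::tibble(
    study_id = c("s1", "s1", "s1", "s2", "s2", "s2"),
    taxon_group = c("plants", "plants", "plants",
                    "invertebrates", "invertebrates", "invertebrates"),
    habitat = c("ponds", "fen", "chalk grassland",
                "ponds", "fen", "chalk grassland"),
    sampled_area_m2 = c(10, 25, 100, 7, 50, 400),
    richness = c(3, 5, 30, 2, 6, 25)
  )
}

# a complete density coefficient set with simple numbers
make_coeffs <- function(response = "density10",
                        estimates = NULL, ses = NULL) {
  habs <- habitat_types()$habitat
  est <- if (is.null(estimates)) seq(1, 10, length.out = length(habs)) else estimates
  se <- if (is.null(ses)) rep(0.5, length(habs)) else ses
  cf <- tibble::tibble(
    habitat = habs, estimate = est, se = se,
    conf_lo = pmax(0, est - 1.96 * se), conf_hi = est + 1.96 * se,
    provenance = "modelled", source_habitat = NA_character_,
    response = response
  )
  cf$estimate[cf$habitat == "hard-standing"] <- 0
  cf$se[cf$habitat == "hard-standing"] <- 0
  cf$provenance[cf$habitat == "hard-standing"] <- "assumed-zero"
  cf
}

# layout over an explicit habitat->area map (other habitats zero)
make_layout <- function(areas, scenario = "layout") {
  layout_table(names(areas), unname(areas), scenario)
}

write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  readr::write_csv(df, path)
  path
}
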