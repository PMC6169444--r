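# Shared fixtures: the packaged two-season survey and a tiny hand-built table.

fixture_wells <- function() divandarreh_wells()

# Three wells covering the censoring cases: fully detected, one-season ND,
# both-seasons ND (nitrite).
tiny_wells <- function() {
  well_table(data.frame(
    name = c("a", "b", "c"),
    easting = 1:3, northing = 4:6,
    nitrate_spring = c(48, 18.1, 123),
    nitrate_autumn = c(42, 15.6, 63.5),
    nitrite_spring = c(0.01, NA, NA),
    nitrite_autumn = c(0.02, 0.05, NA),
    nitrite_spring_cens = c(FALSE, TRUE, TRUE),
    nitrite_autumn_cens = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  ), provenance = "hand-built test table")
}

adult_nitrate <- function() default_exposure_params("adult", "nitrate")
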