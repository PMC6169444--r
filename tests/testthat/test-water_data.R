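test_that("the packaged survey parses with values and censoring intact", {
  w <- fixture_wells()
  expect_s3_class(w, "well_table")
  expect_equal(nrow(w), 58)

  dar <- w[w$name == "Dar asb", ]
  expect_equal(dar$nitrate_spring, 48)
  expect_equal(dar$nitrate_autumn, 42)
  expect_equal(dar$nitrite_spring, 0.01)
  expect_equal(dar$nitrite_autumn, 0.02)
  expect_false(any(unlist(dar[grepl("_cens$", names(dar))])))

  hez <- w[w$name == "Hezar kanian", ]
  expect_true(hez$nitrite_spring_cens)
  expect_true(hez$nitrite_autumn_cens)
  expect_true(is.na(hez$nitrite_spring) && is.na(hez$nitrite_autumn))

  # one-season ND
  zik <- w[w$name == "Ziki big alai", ]
  expect_true(zik$nitrite_spring_cens)
  expect_false(zik$nitrite_autumn_cens)
})

test_that("reader rejects malformed inputs with informative errors", {
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("name,easting,northing,nitrate_spring,nitrate_autumn,nitrite_spring,nitrite_autumn",
             empty)
  expect_error(read_well_table(empty), "no records")

  expect_error(read_well_table(tempfile()), "does not exist")

  miss <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,easting,northing,nitrate_spring",
               "a,1,2,3"), miss)
  expect_error(read_well_table(miss), "not found in header")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,easting,northing,nitrate_spring,nitrate_autumn,nitrite_spring,nitrite_autumn",
               "a,1,2,-3,4,0.1,0.1"), neg)
  expect_error(read_well_table(neg), "negative concentration.*row 1")

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,easting,northing,nitrate_spring,nitrate_autumn,nitrite_spring,nitrite_autumn",
               "a,1,2,3,4,0.1,0.1", "a,1,2,3,4,0.1,0.1"), dup)
  expect_error(read_well_table(dup), "duplicate locality")
})

test_that("ND resolution implements all four substitution policies", {
  # detected values are identity under every policy
  for (p in nd_policies())
    expect_equal(resolve_nd(5.6, FALSE, lod = 0.05, policy = p), 5.6)
  expect_equal(resolve_nd(NA, TRUE, lod = 0.05, "half_lod"), 0.025)
  expect_equal(resolve_nd(NA, TRUE, lod = 0.05, "lod"), 0.05)
  expect_equal(resolve_nd(NA, TRUE, lod = 0.05, "zero"), 0)
  expect_true(is.na(resolve_nd(NA, TRUE, lod = 0.05, "exclude")))
})

test_that("seasonal averages match the survey's printed Average column", {
  w <- fixture_wells()
  avg <- seasonal_average(w, "nitrate")
  expect_equal(unname(avg["Hossen abbad maran"]), 93.25)

  # single detected season under exclude: that value alone
  ni <- seasonal_average(w, "nitrite", policy = "exclude")
  expect_equal(unname(ni["Ziki big alai"]), 0.05)
  # both seasons ND under exclude: absent
  expect_true(is.na(ni["Hezar kanian"]))
})

test_that("seasonal average is bounded by the two resolved season values", {
  w <- fixture_wells()
  for (policy in nd_policies()) {
    for (a in c("nitrate", "nitrite")) {
      sp <- resolve_nd(w[[paste0(a, "_spring")]],
                       w[[paste0(a, "_spring_cens")]],
                       lod = default_lods()[[a]], policy = policy)
      au <- resolve_nd(w[[paste0(a, "_autumn")]],
                       w[[paste0(a, "_autumn_cens")]],
                       lod = default_lods()[[a]], policy = policy)
      avg <- seasonal_average(w, a, policy = policy)
      lo <- pmin(sp, au, na.rm = TRUE)
      hi <- pmax(sp, au, na.rm = TRUE)
      ok <- !is.na(avg)
      expect_true(all(avg[ok] >= lo[ok] - 1e-12 & avg[ok] <= hi[ok] + 1e-12))
    }
  }
})

test_that("under exclude no substituted value enters the resolved series", {
  w <- tiny_wells()
  sp <- resolve_nd(w$nitrite_spring, w$nitrite_spring_cens,
                   lod = 0.05, policy = "exclude")
  # every resolved value must equal a detected raw value, never the LOD
  expect_true(all(is.na(sp[w$nitrite_spring_cens])))
  expect_identical(sp[!w$nitrite_spring_cens],
                   w$nitrite_spring[!w$nitrite_spring_cens])
})

test_that("CSV round-trip reproduces values and censoring flags exactly", {
  w <- fixture_wells()
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(w, path)
  w2 <- read_well_table(path)
  cols <- c(outer(c("nitrate", "nitrite"), c("spring", "autumn"),
                  paste, sep = "_"))
  for (cc in c(cols, paste0(cols, "_cens")))
    expect_identical(w2[[cc]], w[[cc]], info = cc)
  expect_identical(w2$name, w$name)
})

test_that("normalized output carries averages and censoring counts", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_well_table(tiny_wells(), path, normalized = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  expect_true(all(c("nitrate_average", "nitrite_average", "n_censored")
                  %in% names(out)))
  expect_equal(out$n_censored, c(0, 1, 2))
  expect_equal(out$nitrite_average[3], "ND")
})

test_that("structural invariants are enforced by the validator", {
  w <- tiny_wells()
  bad <- w; bad$name[2] <- bad$name[1]
  expect_error(validate_well_table(bad), "duplicate")
  bad <- w; bad$nitrate_spring[1] <- NA  # value absent but not censored
  expect_error(validate_well_table(bad), "uncensored")
  bad <- w; bad$nitrite_spring[2] <- 0.2  # value present though censored
  expect_error(validate_well_table(bad), "censored")
})
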