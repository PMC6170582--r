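test_that("measurement schemes have the fixed code counts and flag undefined codes", {
  expect_length(scheme_codes("femur"), 20)
  expect_length(scheme_codes("tibiotarsus"), 21)
  expect_length(scheme_codes("tarsometatarsus"), 44)
  for (el in c("femur", "tibiotarsus", "tarsometatarsus")) {
    sc <- measurement_scheme(el)
    expect_false(anyDuplicated(sc$codes) > 0)
    expect_identical(names(sc$descriptions), sc$codes)
  }
  expect_identical(unname(measurement_scheme("femur")$descriptions["F15"]),
                   "definition unknown")
  expect_identical(unname(measurement_scheme("tibiotarsus")$descriptions["Tt21"]),
                   "definition unknown")
})

test_that("breakage blocks partition each element's scheme", {
  for (el in c("femur", "tibiotarsus", "tarsometatarsus")) {
    bl <- breakage_blocks(el)
    all_codes <- sort(unlist(bl, use.names = FALSE))
    expect_identical(all_codes, sort(scheme_codes(el)))
  }
})

test_that("reading a complete specimen table validates and round-trips", {
  path <- tiny_femur_csv()
  ds <- read_specimen_table(path, "femur")
  expect_s3_class(ds, "specimen_dataset")
  expect_equal(nrow(ds$measurements), 3)
  expect_equal(unname(missing_fraction(ds)), c(0, 0, 0))
  # round-trip is bit-exact and preserves the missing mask
  path2 <- tempfile(fileext = ".csv")
  write_specimen_table(ds, path2)
  ds2 <- read_specimen_table(path2, "femur")
  expect_identical(ds$measurements, ds2$measurements)

  path3 <- tiny_femur_csv(holes = TRUE)
  ds3 <- read_specimen_table(path3, "femur")
  expect_equal(unname(missing_fraction(ds3)), c(0, 5 / 20, 0))
  path4 <- tempfile(fileext = ".csv")
  write_specimen_table(ds3, path4)
  ds4 <- read_specimen_table(path4, "femur")
  expect_identical(ds3$measurements, ds4$measurements)
  expect_identical(is.na(ds3$measurements), is.na(ds4$measurements))
})

test_that("schema and value errors name the offender", {
  codes <- scheme_codes("femur")
  M <- matrix(50, 2, 20, dimnames = list(NULL, codes))
  df <- cbind(data.frame(specimen_id = c("x", "y")), as.data.frame(M))
  df$Tmt3 <- 1  # tarsometatarsal code in a femur table
  p <- tempfile(fileext = ".csv"); utils::write.csv(df, p, row.names = FALSE)
  expect_error(read_specimen_table(p, "femur"), "Tmt3")

  df$Tmt3 <- NULL
  df$F3[1] <- -10
  p2 <- tempfile(fileext = ".csv"); utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_specimen_table(p2, "femur"), "F3")

  df$F3[1] <- "oops"
  p3 <- tempfile(fileext = ".csv"); utils::write.csv(df, p3, row.names = FALSE)
  expect_error(read_specimen_table(p3, "femur"), "F3")

  # a specimen with nothing observed is rejected
  df2 <- cbind(data.frame(specimen_id = "z"),
               as.data.frame(matrix(NA_real_, 1, 20, dimnames = list(NULL, codes))))
  expect_error(specimen_dataset("femur", df2[codes], df2["specimen_id"]),
               "zero observed")
})

test_that("missing_fraction uses the full scheme and ignores column order and metadata", {
  codes <- scheme_codes("tarsometatarsus")
  M <- matrix(100, 1, 44, dimnames = list(NULL, codes))
  M[1, codes[1:11]] <- NA
  ds <- specimen_dataset("tarsometatarsus", M)
  expect_equal(unname(missing_fraction(ds)), 11 / 44)  # exactly 0.25
  M2 <- M[, rev(codes), drop = FALSE]
  ds2 <- specimen_dataset("tarsometatarsus", M2,
                          meta = data.frame(specimen_id = "s1", locality = "x"))
  expect_equal(unname(missing_fraction(ds2)), 11 / 44)
  # 12 of 44
  M[1, codes[12]] <- NA
  expect_equal(unname(missing_fraction(specimen_dataset("tarsometatarsus", M))),
               12 / 44)
})
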