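test_that("spectra_set construction enforces the axis invariants", {
  s <- spectra_set(c(1, 2, 3), matrix(1:6, 2, 3, byrow = TRUE))
  expect_equal(n_channels(s), 3L)
  expect_equal(n_spectra(s), 2L)

  # descending file order is reversed together with intensities
  d <- spectra_set(c(3, 2, 1), rbind(c(30, 20, 10)))
  expect_equal(d$wavenumber, c(1, 2, 3))
  expect_equal(as.numeric(d$intensities), c(10, 20, 30))

  expect_error(spectra_set(5, rbind(1)), "at least 2")
  expect_error(spectra_set(c(1, 1, 2), matrix(0, 1, 3)), "monotonically")
  expect_error(spectra_set(c(1, 2), rbind(c(1, NaN))), "non-finite")
  expect_error(spectra_set(c(1, 2, 3), rbind(c(1, 2))), "3 channels")
})

test_that("validate_set reports violations without raising", {
  s <- random_set()
  expect_length(validate_set(s), 0L)

  bad <- s
  bad$intensities[2, 5] <- NaN
  v <- validate_set(bad)
  expect_length(v, 1L)
  expect_match(v, "record 2, channel 5")

  bad2 <- s
  bad2$intensities <- bad2$intensities[, 1:10]
  expect_match(validate_set(bad2), "not aligned", all = FALSE)

  bad3 <- s
  bad3$meta$c_bsa[1] <- -1
  expect_match(validate_set(bad3), "negative concentration", all = FALSE)
})

test_that("spectra tables round-trip through disk to 1e-12", {
  set.seed(42)
  s <- spectra_set(sort(runif(200, 400, 1800)),
                   matrix(rnorm(50 * 200), 50, 200),
                   data.frame(spectrum_id = sprintf("r%02d", 1:50),
                              sample_id = "x", spot_id = rep(c("a", "b"), 25),
                              replicate = "1", c_bsa = 1.5, c_al = 0.5,
                              day = "day1"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(s, path)
  r <- read_spectra_table(path, default_meta_path(path))
  expect_equal(r$wavenumber, s$wavenumber, tolerance = 1e-12)
  expect_lt(max(abs(r$intensities - s$intensities)), 1e-12)
  expect_identical(r$meta$spectrum_id, s$meta$spectrum_id)
  expect_identical(r$meta$spot_id, s$meta$spot_id)
  expect_equal(r$meta$c_bsa, s$meta$c_bsa)
})

test_that("reader restores ascending axis order and flags bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,s1,s2", "700,7,70", "500,5,50", "600,6,60"), path)
  r <- read_spectra_table(path)
  expect_equal(r$wavenumber, c(500, 600, 700))
  expect_equal(as.numeric(r$intensities[1, ]), c(5, 6, 7))
  expect_equal(as.numeric(r$intensities[2, ]), c(50, 60, 70))

  writeLines(c("wavenumber_cm-1,s1", "500,5", "600,oops"), path)
  expect_error(read_spectra_table(path), "row 2, column 's1'")

  writeLines(c("wavenumber_cm-1,s1", "500,5", "500,6"), path)
  expect_error(read_spectra_table(path), "duplicate wavenumber")
})

test_that("metadata joins by spectrum id; collisions and strays are handled", {
  s <- random_set(n = 2L, b = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  meta_path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_table(s, path, meta_path = NA)

  writeLines(c("spectrum_id,sample_id,c_bsa_mg_ml",
               "sp1,x,0.2", "sp2,x,2", "ghost,x,1"), meta_path)
  expect_warning(r <- read_spectra_table(path, meta_path), "no matching spectrum")
  expect_equal(r$meta$c_bsa, c(0.2, 2))

  writeLines(c("spectrum_id,sample_id", "sp1,x", "sp1,y"), meta_path)
  expect_error(read_spectra_table(path, meta_path), "collision")
})

test_that("endmember and abundance containers enforce their invariants", {
  expect_error(endmember_set(1:4, rbind(c(1, -1, 0, 0)), "a"), ">= 0")
  expect_error(endmember_set(1:4, matrix(1, 2, 4), c("a", "a")), "unique")
  em <- toy_basis()
  expect_identical(em$labels, c("BSA", "AlOH3"))

  expect_error(abundance_matrix(cbind(a = -1, b = 2)), "non-negative")
  ab <- abundance_matrix(cbind(BSA = c(1, 2), AlOH3 = c(0.5, 0.5)),
                         units = "mg_per_mL")
  expect_identical(attr(ab, "units"), "mg_per_mL")
})

test_that("bind_spectra refuses mismatched axes", {
  a <- random_set(seed = 1)
  b <- random_set(seed = 2)   # different random axis
  expect_error(bind_spectra(a, b), "axes do not match")
  both <- bind_spectra(a, subset_spectra(a, 1:2))
  expect_equal(n_spectra(both), 7L)
  expect_false(anyDuplicated(both$meta$spectrum_id) > 0)
})
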