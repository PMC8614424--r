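test_that("spectra_set enforces its invariants", {
  wl <- c(850, 850.5, 851)
  A <- matrix(runif(6), 2, 3)
  s <- spectra_set(wl, A, c("a", "b"))
  expect_s3_class(s, "spectra_set")
  expect_equal(dim(s), c(2L, 3L))

  expect_error(spectra_set(c(850, 851, 850.5), A, c("a", "b")), "increasing")
  expect_error(spectra_set(c(850, 850.5, 851.6), A, c("a", "b")), "uniform")
  expect_error(spectra_set(wl, A, c("a", "a")), "duplicated")
  A2 <- A; A2[1, 2] <- NA
  expect_error(spectra_set(wl, A2, c("a", "b")), "finite")
  expect_error(spectra_set(wl, A[, 1:2], c("a", "b")), "columns")
})

test_that("read_spectra parses well-formed files and rejects malformed ones", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,850,850.5,851",
               "a,0.1,0.2,0.3",
               "b,0.4,0.5,0.6"), tmp)
  s <- read_spectra(tmp)
  expect_equal(length(s$wavelengths), 3)
  expect_equal(nrow(s$absorbance), 2)
  expect_equal(unname(s$absorbance[2, 3]), 0.6)

  # full instrument grid: 850-2500 nm at 0.5 nm is 3301 points
  wl <- seq(850, 2500, by = 0.5)
  expect_length(wl, 3301)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(paste(c("sample_id", wl), collapse = ","),
               paste(c("a", rep("0.5", 3301)), collapse = ",")), tmp2)
  s2 <- read_spectra(tmp2)
  expect_length(s2$wavelengths, 3301)

  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,850,850.5,851", "a,0.1,0.2,0.3", "a,0.4,0.5,0.6"), tmp3)
  expect_error(read_spectra(tmp3), "duplicated sample id.*a")

  tmp4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,850,850.5,851", "a,0.1,0.2"), tmp4)
  expect_error(read_spectra(tmp4), "ragged row")

  tmp5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,850,850.5,851", "a,0.1,oops,0.3"), tmp5)
  expect_error(read_spectra(tmp5), "row 1.*850.5")

  tmp6 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,851,850,852", "a,0.1,0.2,0.3"), tmp6)
  expect_error(read_spectra(tmp6), "increasing")
})

test_that("write/read round trip is bit-exact, species preserved", {
  s <- tiny_spectra(4, 25, species = rep(c("corn_stover", "wheat_straw"), 2))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s, tmp)
  s2 <- read_spectra(tmp)
  expect_identical(s2$absorbance, s$absorbance)
  expect_identical(s2$wavelengths, s$wavelengths)
  expect_identical(s2$species, s$species)
  # second round trip is also stable
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_spectra(s2, tmp2)
  expect_identical(read_spectra(tmp2)$absorbance, s$absorbance)
})

test_that("reference tables validate ranges, fiber consistency and missingness", {
  expect_silent(reference_table(c("a", "b"),
                                data.frame(ndf = c(63.97, 70), adf = c(36.28, 40))))
  expect_warning(reference_table("a", data.frame(ndf = 30, adf = 40)), "NDF < ADF")
  expect_error(reference_table("a", data.frame(cp = 120)), "outside")
  expect_error(reference_table("a", data.frame(cp = -2)), "outside")

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,cp,ndf,adf,species",
               "a,5.2,63.97,36.28,corn_stover",
               "b,NA,70.1,38.2,corn_stover"), tmp)
  ref <- read_reference(tmp)
  expect_true(is.na(ref$cp[2]))
  expect_equal(ref$species, c("corn_stover", "corn_stover"))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_reference(ref, tmp2)
  ref2 <- read_reference(tmp2)
  expect_equal(ref2$ndf, ref$ndf)
  expect_true(is.na(ref2$cp[2]))
})

test_that("average_replicates averages groups and validates scan ids", {
  s <- tiny_spectra(6, 20)
  groups <- setNames(rep(c("g1", "g2"), each = 3), s$sample_ids)
  avg <- average_replicates(s, groups)
  expect_equal(avg$sample_ids, c("g1", "g2"))
  expect_equal(avg$absorbance[1, ], colMeans(s$absorbance[1:3, ]), ignore_attr = TRUE)

  # identical scans: mean equals any input row
  s3 <- spectra_set(s$wavelengths, s$absorbance[c(1, 1, 1), ], c("x", "y", "z"))
  avg3 <- average_replicates(s3, c(x = "m", y = "m", z = "m"))
  expect_equal(avg3$absorbance[1, ], s$absorbance[1, ], ignore_attr = TRUE)

  # 0.2 / 0.4 constant scans -> 0.3 everywhere
  s4 <- spectra_set(s$wavelengths, rbind(rep(0.2, 20), rep(0.4, 20)), c("u", "v"))
  avg4 <- average_replicates(s4, c(u = "m", v = "m"))
  expect_equal(unname(avg4$absorbance[1, ]), rep(0.3, 20))

  expect_error(average_replicates(s, c(bogus = "g1")), "unknown scan id")
})

test_that("average_replicates commutes with wavelength subsetting", {
  s <- tiny_spectra(6, 30)
  groups <- setNames(rep(c("g1", "g2"), each = 3), s$sample_ids)
  idx <- seq(3, 27, by = 2)
  a <- subset_wavelengths(average_replicates(s, groups), idx)
  b <- average_replicates(subset_wavelengths(s, idx), groups)
  expect_equal(a$absorbance, b$absorbance)
  expect_equal(a$wavelengths, b$wavelengths)
})
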