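test_that("rank-stratified split follows the block rule", {
  ref <- reference_table(sprintf("s%02d", 1:10), data.frame(cp = c(10:1) / 2))
  sp <- rank_stratified_split(ref, "cp", fold = 5, offset = 2)
  # sorted ascending by cp: s10 (0.5) ... s01 (5.0); 0-based positions 2 and 7
  sorted_ids <- ref$sample_id[order(ref$cp, ref$sample_id)]
  expect_equal(sp$validation, sorted_ids[c(3, 8)])
  expect_equal(sort(c(sp$calibration, sp$validation)), sort(ref$sample_id))
  expect_length(sp$calibration, 8)

  # n = 156 at fold 5: about 125 calibrate, 31 validate
  set.seed(59)
  big <- reference_table(sprintf("x%03d", 1:156), data.frame(cp = runif(156, 2, 10)))
  spb <- rank_stratified_split(big, "cp", fold = 5)
  expect_equal(length(spb$validation), 31)
  expect_equal(length(spb$calibration), 125)
  frac <- length(spb$validation) / 156
  expect_true(frac >= 1 / 5 - 0.05 && frac <= 1 / 5 + 0.05)

  # all values tied: split by id order, still disjoint and exhaustive
  tied <- reference_table(sprintf("t%02d", 1:10), data.frame(cp = rep(5, 10)))
  spt <- rank_stratified_split(tied, "cp", fold = 5, offset = 0)
  expect_length(intersect(spt$calibration, spt$validation), 0)
  expect_setequal(c(spt$calibration, spt$validation), tied$sample_id)
  expect_equal(spt$validation, c("t01", "t06"))

  # default offset keeps validation off the extremes
  spd <- rank_stratified_split(big, "cp", fold = 5)
  vals <- big$cp[match(spd$validation, big$sample_id)]
  cals <- big$cp[match(spd$calibration, big$sample_id)]
  expect_gt(min(vals), min(cals))
  expect_lt(max(vals), max(cals))

  miss <- reference_table(sprintf("m%02d", 1:10),
                          data.frame(cp = c(rep(NA, 3), runif(7))))
  expect_error(rank_stratified_split(miss, "cp"), "missing")
})

test_that("build_grid forms the deduplicated product; default has 30 cells", {
  g <- build_grid()
  expect_length(g, 30)
  strings <- vapply(g, format_pretreatment, character(1))
  expect_length(unique(strings), 30)
  # winning pretreatments with default-grid scatters are all present
  for (s in c("2,4,4,1+none", "1,4,4,1+none", "1,4,4,1+DT", "1,4,4,1+SNV",
              "1,4,4,1+WMSC", "2,4,4,1+MSC", "2,4,4,1+SCL", "0,0,1,1+SCL",
              "1,4,4,1+SCL", "0,0,1,1+MSC")) {
    expect_true(s %in% strings, info = s)
  }
  expect_length(build_grid(list(math_treatment(1, 4, 4, 1)), "snv_only"), 1)
  expect_length(build_grid(list(math_treatment(1, 4, 4, 1), math_treatment(1, 4, 4, 1)),
                           c("snv_only", "snv_only")), 1)
})

test_that("grid search ranks honestly and tolerates failing pretreatments", {
  d <- noiseless_species(50, seed = 61)
  # scatter-dominant regime so corrections matter
  prof <- corn_stover_profile(seed = 61, slope_sd = 0.3, offset_sd = 0.15,
                              tilt_sd = 0.05, noise_sd = 0.005)
  lib <- default_band_library(default_wavelength_grid(8))
  s <- simulate_spectra(d$reference, lib, prof)

  grid <- list(pretreatment(math_treatment(0, 0, 1, 1), "none"),
               pretreatment(math_treatment(0, 0, 1, 1), "snv_only"),
               pretreatment(math_treatment(1, 4, 4, 1), "none"),
               pretreatment(math_treatment(1, 4, 4, 1), "snv_only"),
               pretreatment(math_treatment(2, 400, 1, 1), "none"))  # window too large
  gs <- grid_search(s, d$reference, "cp", grid, groups = 4, max_factors = 8, seed = 3)
  expect_equal(nrow(gs$report), 5)
  expect_equal(sum(grepl("^failed", gs$report$status)), 1)
  ok <- gs$report[gs$report$status == "ok", ]
  expect_true(!is.unsorted(rev(ok$one_minus_vr)))
  # some scatter-corrected candidate outranks the scatter-free identity
  best <- gs$report$pretreatment[1]
  expect_true(best != "0,0,1,1+none")

  # winner stats invariant to grid order
  gs2 <- grid_search(s, d$reference, "cp", rev(grid), groups = 4, max_factors = 8, seed = 3)
  expect_equal(gs2$report$pretreatment[1], gs$report$pretreatment[1])
  expect_equal(gs2$candidates[[1]]$stats$secv, gs$candidates[[1]]$stats$secv)

  # reported n equals calibration n minus compositional removals
  for (cand in gs$candidates) {
    if (identical(cand$status, "ok")) {
      expect_equal(cand$stats$n, sum(cand$keep))
    }
  }
})

test_that("noiseless identity pretreatment achieves near-perfect 1-VR", {
  d <- noiseless_species(40, seed = 67)
  grid <- list(pretreatment(math_treatment(0, 0, 1, 1), "none"))
  gs <- grid_search(d$spectra, d$reference, "cp", grid, groups = 4,
                    max_factors = 8, seed = 5)
  expect_gt(gs$candidates[[1]]$stats$one_minus_vr, 0.999)
})
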