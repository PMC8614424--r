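test_that("snv standardizes and is affine invariant", {
  expect_equal(snv(c(1, 2, 3)), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  r <- sin(seq(0, 3, length.out = 50))
  z <- snv(r)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(snv(2.5 + 0.3 * r), z, tolerance = 1e-10)
  expect_error(snv(rep(1, 10)), "constant")
})

test_that("detrend annihilates polynomials and is a projection", {
  wl <- seq(850, 2500, by = 10)
  quad <- 0.2 + 0.001 * wl + 1e-6 * wl^2
  expect_equal(detrend(quad, wl, 2), rep(0, length(wl)), tolerance = 1e-8)
  line <- 1 - 0.0004 * wl
  expect_equal(detrend(line, wl, 1), rep(0, length(wl)), tolerance = 1e-10)
  r <- sin(wl / 200)
  expect_equal(detrend(r + quad, wl, 2), detrend(r, wl, 2), tolerance = 1e-8)
})

test_that("MSC state and application behave per contract", {
  s <- tiny_spectra(8, 30)
  st <- fit_msc(s)
  expect_equal(st$mean, colMeans(s$absorbance), ignore_attr = TRUE)
  expect_error(fit_msc(s[1]), "at least 2")

  # identical rows: weighted weights hit the floor, strictly positive finite
  same <- spectra_set(s$wavelengths, s$absorbance[c(1, 1, 1), ], c("a", "b", "c"))
  stw <- fit_msc(same, weighted = TRUE, eps = 1e-10)
  expect_true(all(stw$weights == 1e10))
  stw2 <- fit_msc(s, weighted = TRUE)
  expect_true(all(is.finite(stw2$weights) & stw2$weights > 0))

  # closed-form inversion: row = 2*mean + 3 -> mean
  m <- st$mean
  expect_equal(apply_msc(2 * m + 3, st), m, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(apply_msc(m, st), m, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(apply_msc(rep(1, 30), fit_msc(
    spectra_set(s$wavelengths, rbind(rep(1, 30), rep(1, 30)), c("a", "b")))),
    "degenerate")

  # MSC shrinks between-sample variance on a multiplicative scatter family
  prof <- corn_stover_profile(seed = 31, slope_sd = 0.15, offset_sd = 0.05,
                              tilt_sd = 0, noise_sd = 1e-4)
  d <- simulate_species(prof, 20, grid = default_wavelength_grid(8))
  stm <- fit_msc(d$spectra)
  corrected <- t(apply(d$spectra$absorbance, 1, apply_msc, state = stm))
  expect_lt(mean(apply(corrected, 2, var)), mean(apply(d$spectra$absorbance, 2, var)))
})

test_that("scale_polynomial is scale invariant and kills scaled baselines", {
  wl <- seq(850, 2500, by = 10)
  const <- rep(4, length(wl))
  expect_equal(scale_polynomial(const, wl, 1), rep(0, length(wl)), tolerance = 1e-12)
  r <- 0.5 + exp(-0.5 * ((wl - 1900) / 100)^2)
  expect_equal(scale_polynomial(3 * r, wl, 1), scale_polynomial(r, wl, 1),
               tolerance = 1e-10)
  expect_equal(scale_polynomial(5 * r, wl, 2), scale_polynomial(r, wl, 2),
               tolerance = 1e-10)
  expect_error(scale_polynomial(rep(0, length(wl)), wl, 1), "zero-mean")
})

test_that("math treatments: identity, derivative closed forms, trimming", {
  s <- tiny_spectra(3, 40)
  ident <- apply_math_treatment(s, math_treatment(0, 0, 1, 1))
  expect_identical(ident$absorbance, s$absorbance)
  expect_identical(ident$wavelengths, s$wavelengths)

  # constant spectrum: any derivative treatment gives zero
  cs <- spectra_set(s$wavelengths, matrix(2, 1, 40), "c")
  for (t in list(math_treatment(1, 4, 4, 1), math_treatment(2, 8, 8, 1))) {
    out <- apply_math_treatment(cs, t)
    expect_equal(unname(out$absorbance[1, ]), rep(0, length(out$wavelengths)))
  }

  # y = i^2 on a unit grid, second derivative with gap 4 -> 2 * 4^2 = 32
  wl <- 1:30
  sq <- spectra_set(wl, matrix((1:30)^2, 1), "q")
  out <- apply_math_treatment(sq, math_treatment(2, 4, 1, 1))
  expect_equal(unname(out$absorbance[1, ]), rep(32, 30 - 8))
  expect_equal(out$wavelengths, 5:26)

  # first derivative of a line on a unit grid: 2h * slope
  ln <- spectra_set(wl, matrix(3 * (1:30) + 1, 1), "l")
  out1 <- apply_math_treatment(ln, math_treatment(1, 4, 1, 1))
  expect_equal(unname(out1$absorbance[1, ]), rep(3 * 2 * 2, 30 - 4))

  # derivative treatments annihilate lines even with smoothing (order 2)
  out2 <- apply_math_treatment(ln, math_treatment(2, 4, 5, 3))
  expect_equal(max(abs(out2$absorbance)), 0, tolerance = 1e-10)

  # window bookkeeping: (1,4,4,1) trims grid by smoothing + gap
  tr <- apply_math_treatment(s, math_treatment(1, 4, 4, 1))
  expect_lt(length(tr$wavelengths), length(s$wavelengths))
  expect_equal(diff(tr$wavelengths[1:2]), diff(s$wavelengths[1:2]))
  expect_error(apply_math_treatment(spectra_set(1:4, matrix(1:4, 1), "x"),
                                    math_treatment(2, 4, 1, 1)), "too short")
})

test_that("pretreatment serialization round-trips and pipeline composes", {
  p <- pretreatment(math_treatment(1, 4, 4, 1), "snv_only")
  expect_equal(format_pretreatment(p), "1,4,4,1+SNV")
  p2 <- parse_pretreatment("1,4,4,1+SNV")
  expect_equal(p2$math$gap, 4L)
  expect_equal(p2$scatter, "snv_only")
  expect_equal(format_pretreatment(parse_pretreatment("0,0,1,1+none")), "0,0,1,1+none")
  expect_error(parse_pretreatment("1,4,4+SNV"), "malformed")
  expect_error(parse_pretreatment("1,4,4,1+XYZ"), "unknown scatter")

  s <- tiny_spectra(8, 50)
  # identity pretreatment is the identity transform
  out <- apply_pretreatment(s, pretreatment(math_treatment(0, 0, 1, 1), "none"))
  expect_identical(out$spectra$absorbance, s$absorbance)

  # SNV + 1,4,4,1 runs end to end and trims the grid
  out2 <- apply_pretreatment(s, p)
  expect_lt(length(out2$spectra$wavelengths), length(s$wavelengths))

  # train/apply consistency: rows processed with a calibration-fitted MSC
  # state match the same rows processed alongside the calibration set
  pm <- pretreatment(math_treatment(1, 4, 4, 1), "msc_standard")
  cal <- s[1:5]
  val <- s[6:8]
  fit <- apply_pretreatment(cal, pm)
  val_out <- apply_pretreatment(val, pm, state = fit$state)
  all_out <- apply_pretreatment(s, pm, state = fit$state)
  expect_equal(val_out$spectra$absorbance, all_out$spectra$absorbance[6:8, ],
               ignore_attr = TRUE)
})

test_that("preprocessing operators commute with sample reordering", {
  s <- tiny_spectra(7, 45)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  for (sc in c("snv_only", "detrend_only", "scale_linear", "scale_quadratic")) {
    p <- pretreatment(math_treatment(1, 4, 4, 1), sc)
    a <- apply_pretreatment(s, p)$spectra$absorbance[perm, ]
    b <- apply_pretreatment(s[perm], p)$spectra$absorbance
    expect_equal(a, b, ignore_attr = TRUE)
  }
})
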