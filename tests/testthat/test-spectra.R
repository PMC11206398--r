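single_stick <- function(nm, f, owner = "s")
  stick_spectrum(owner, data.frame(index = 1, wavelength_nm = nm, f = f))

test_that("a single broadened band peaks at the stick position", {
  sp <- broaden(single_stick(330, 0.5), grid = c(300, 360, 0.1))
  peak <- sp$wavelength_nm[which.max(sp$absorbance)]
  expect_lte(abs(peak - 330), 0.1)  # within one grid step
})

test_that("broadening is linear in the stick list", {
  s1 <- single_stick(330, 0.5)
  s2 <- stick_spectrum("s", data.frame(index = 1:2,
                                       wavelength_nm = c(330, 330),
                                       f = c(0.5, 0.5)))
  a <- broaden(s1); b <- broaden(s2)
  expect_equal(b$absorbance, 2 * a$absorbance, tolerance = 1e-12)
  # distinct sticks: sum of parts equals broadened union
  sA <- single_stick(320, 0.2); sB <- single_stick(250, 0.3)
  sAB <- stick_spectrum("s", data.frame(index = 1:2,
                                        wavelength_nm = c(320, 250),
                                        f = c(0.2, 0.3)))
  expect_equal(broaden(sAB)$absorbance,
               broaden(sA)$absorbance + broaden(sB)$absorbance,
               tolerance = 1e-12)
})

test_that("energy-domain area is proportional to summed oscillator strength", {
  grid <- c(150, 500, 0.05)  # spans every band by far more than 5 sigma
  a1 <- spectrum_area(broaden(single_stick(330, 0.2), grid = grid))
  s2 <- stick_spectrum("s", data.frame(index = 1:2,
                                       wavelength_nm = c(330, 300),
                                       f = c(0.2, 0.3)))
  a2 <- spectrum_area(broaden(s2, grid = grid))
  expect_equal(a2 / a1, 0.5 / 0.2, tolerance = 0.01)
  expect_equal(a1, 0.2, tolerance = 0.01 * 0.2)  # area-normalized bands
})

test_that("a grid excluding all sticks warns and returns a zero spectrum", {
  expect_warning(sp <- broaden(single_stick(330, 0.5),
                               grid = c(180, 200, 0.1)),
                 "excludes all sticks")
  expect_true(all(sp$absorbance == 0))
})

test_that("shifting every stick in energy shifts the band maximum with it", {
  s <- stick_spectrum("s", data.frame(index = 1:2,
                                      wavelength_nm = c(330, 300),
                                      f = c(0.6, 0.3)))
  delta_ev <- 0.2
  shifted <- s
  shifted$states$wavelength_nm <-
    1239.84198 / (1239.84198 / s$states$wavelength_nm + delta_ev)
  g <- c(200, 360, 0.02)
  p0 <- with(broaden(s, grid = g), wavelength_nm[which.max(absorbance)])
  p1 <- with(broaden(shifted, grid = g), wavelength_nm[which.max(absorbance)])
  expected <- 1239.84198 / (1239.84198 / p0 + delta_ev)
  expect_lte(abs(p1 - expected), 2 * g[3])
})

test_that("lambda_max applies the oscillator-strength rule on sticks", {
  st <- stick_spectrum("Br", data.frame(index = 1:2,
                                        wavelength_nm = c(326.71, 220),
                                        f = c(0.5295, 0.9)))
  got <- lambda_max(st, f_threshold = 0.5, window = c(320, 400))
  expect_equal(got$wavelength_nm, 326.71)
  expect_equal(got$f, 0.5295)
  # without the window the longest qualifying wavelength still wins
  expect_equal(lambda_max(st)$wavelength_nm, 326.71)
  # single qualifying stick
  expect_equal(lambda_max(single_stick(330, 0.6))$wavelength_nm, 330)
  # all below threshold: explicit error, never a silent fallback
  weak <- stick_spectrum("w", data.frame(index = 1:2,
                                         wavelength_nm = c(330, 300),
                                         f = c(0.4, 0.49)))
  expect_error(lambda_max(weak), "no-qualifying-transition")
  # wavelength tie broken toward larger f
  tie <- stick_spectrum("t", data.frame(index = 1:2,
                                        wavelength_nm = c(330, 330),
                                        f = c(0.55, 0.65)))
  expect_equal(lambda_max(tie)$f, 0.65)
})

test_that("peak shifts carry the sign convention: crystal minus calculated", {
  h <- peak_shift(331.21, 333.17, "H")
  expect_equal(h$delta_lambda, 1.96, tolerance = 1e-9)
  expect_identical(h$shift_class, "red")
  br <- peak_shift(329.99, 326.71, "Br")
  expect_equal(br$delta_lambda, -3.28, tolerance = 1e-9)
  expect_identical(br$shift_class, "blue")
  same <- peak_shift(330, 330)
  expect_equal(same$delta_lambda, 0)
  expect_identical(same$shift_class, "none")
  expect_error(peak_shift(-1, 330), "positive")
  # antisymmetry
  set.seed(3)
  for (i in 1:10) {
    a <- runif(1, 200, 400); b <- runif(1, 200, 400)
    expect_equal(peak_shift(a, b)$delta_lambda,
                 -peak_shift(b, a)$delta_lambda)
  }
})

test_that("difference spectra subtract pointwise and refuse grid mismatch", {
  s <- single_stick(330, 0.5)
  a <- broaden(s)
  expect_true(all(difference_spectrum(a, a)$absorbance == 0))
  twice <- broaden(stick_spectrum("s", data.frame(
    index = 1:2, wavelength_nm = c(330, 330), f = c(0.5, 0.5))))
  expect_equal(difference_spectrum(twice, a)$absorbance, a$absorbance,
               tolerance = 1e-12)
  b <- broaden(s, grid = c(180, 350, 0.2))
  expect_error(difference_spectrum(a, b), "grid")
})

test_that("difference-curve extrema sit where a dense brute-force scan puts them", {
  # two single-stick spectra offset by 3 nm; oracle: 0.01 nm grid scan
  g_fine <- c(300, 360, 0.01)
  a <- broaden(single_stick(330, 0.5), grid = g_fine)
  b <- broaden(single_stick(333, 0.5), grid = g_fine)
  d <- difference_spectrum(a, b)
  arg <- d$wavelength_nm[which.max(abs(d$absorbance))]
  # oracle by direct evaluation of the two Gaussians on the same dense grid
  sigma <- 0.333 / (2 * sqrt(2 * log(2)))
  wl <- seq(g_fine[1], g_fine[2], by = g_fine[3])
  e <- 1239.84198 / wl
  f1 <- 0.5 * dnorm(e, 1239.84198 / 330, sigma)
  f2 <- 0.5 * dnorm(e, 1239.84198 / 333, sigma)
  expect_equal(arg, wl[which.max(abs(f1 - f2))])
  # the extremum lies between the band centers or on a flank within about
  # one Gaussian width of them, never far outside the two-band envelope
  expect_gte(arg, 315); expect_lte(arg, 350)
})

test_that("band onset matches the analytic Gaussian crossing", {
  f <- 0.5; center <- 330; frac <- 0.02
  sp <- broaden(single_stick(center, f), grid = c(250, 400, 0.05))
  onset <- band_onset(sp, frac)
  expect_lt(onset, center)               # onset precedes the band center
  expect_equal(band_onset(sp, frac),
               {sp2 <- sp; sp2$absorbance <- 2 * sp2$absorbance
                band_onset(sp2, frac)})  # scale invariance
  sigma <- 0.333 / (2 * sqrt(2 * log(2)))
  e_cross <- 1239.84198 / center + sigma * sqrt(2 * log(1 / frac))
  expect_lte(abs(onset - 1239.84198 / e_cross), 0.05 + 1e-9)
  zero <- sp; zero$absorbance[] <- 0
  expect_error(band_onset(zero), "all-zero")
})

test_that("provisional peaks are the local maxima of the broadened curve", {
  s <- stick_spectrum("s", data.frame(index = 1:2,
                                      wavelength_nm = c(330, 250),
                                      f = c(0.6, 0.4)))
  pk <- provisional_peaks(broaden(s, grid = c(200, 360, 0.05)))
  expect_equal(nrow(pk), 2L)
  expect_equal(sort(pk$wavelength_nm), c(250, 330), tolerance = 0.1)
  expect_true(all(pk$provisional))
})
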