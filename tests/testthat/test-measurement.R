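test_that("spline upsampling is exact on the original grid and on straight lines", {
  w <- c(1, 4, 2, 8, 5)
  up1 <- upsample_spline(w, 1000, 1)
  expect_identical(up1$wave, w)
  ramp <- seq(0, 10, length.out = 11)
  up <- upsample_spline(ramp, 1000, 4)
  expect_equal(up$srate, 4000)
  expect_length(up$wave, 41L)
  grid <- seq(0, 10, length.out = 41)
  expect_lt(max(abs(up$wave - grid)), 1e-9)
  expect_identical(up$wave[seq(1, 41, by = 4)], ramp)
  expect_error(upsample_spline(c(1, 2, 3), 1000, 2), "at least 4 samples")
  expect_error(upsample_spline(w, 1000, 0), "factor")
})

test_that("mean amplitude handles constants, ramps, and the printed Fig. 5 window", {
  erp <- make_constant_erp(5, srate = 1000, tmin = -200, tmax = 800)
  expect_equal(mean_amplitude(erp, 1, 1, c(0, 100)), 5)

  ramp <- make_wave_erp(seq(0, 10, length.out = 100), srate = 1000, tmin = 0)
  m <- mean_amplitude(ramp, 1, 1, c(0, 100))
  expect_equal(m, 5, tolerance = 0.06)   # half-sample discretization

  erp2 <- make_constant_erp(1, srate = 500, tmin = -200, tmax = 800)
  expect_equal(mean_amplitude(erp2, 1, 1, c(300, 798)), 1)
  expect_error(mean_amplitude(erp2, 1, 1, c(300, 900)), "outside epoch")
})

test_that("area amplitude respects polarity modes and the signed-area identity", {
  pos <- make_constant_erp(2, srate = 1000, tmin = 0, tmax = 100)
  expect_equal(area_amplitude(pos, 1, 1, c(0, 100), "positive"), 200)
  expect_equal(area_amplitude(pos, 1, 1, c(0, 100), "negative"), 0)
  expect_equal(area_amplitude(pos, 1, 1, c(0, 100), "integral"), 200)
  expect_equal(area_amplitude(pos, 1, 1, c(0, 100), "rectified"), 200)

  neg <- make_constant_erp(-2, srate = 1000, tmin = 0, tmax = 100)
  expect_equal(area_amplitude(neg, 1, 1, c(0, 100), "negative"), 200)  # magnitude
  expect_equal(area_amplitude(neg, 1, 1, c(0, 100), "integral"), -200)

  # sine over whole cycles: integral ~ 0, rectified > 0
  fs <- 1000
  sine <- make_wave_erp(3 * sin(2 * pi * 10 * seq(0, 0.3 - 1 / fs, by = 1 / fs)),
                        srate = fs, tmin = 0)
  expect_lt(abs(area_amplitude(sine, 1, 1, c(0, 300), "integral")), 3 * 1000 / fs)
  expect_gt(area_amplitude(sine, 1, 1, c(0, 300), "rectified"), 0)

  # identity: positive - negative == integral, for arbitrary waveforms
  set.seed(13)
  w <- make_wave_erp(rnorm(200), srate = 1000, tmin = 0)
  expect_equal(area_amplitude(w, 1, 1, c(0, 200), "positive") -
               area_amplitude(w, 1, 1, c(0, 200), "negative"),
               area_amplitude(w, 1, 1, c(0, 200), "integral"), tolerance = 1e-9)
})

test_that("peaks honor polarity, the local criterion, and earliest-tie-break", {
  fs <- 1000
  tt <- seq(0, 799, by = 1)
  tri <- pmax(0, 10 - abs(tt - 400) / 10)       # triangular peak at 400 ms
  erp <- make_wave_erp(tri, srate = fs, tmin = 0)
  pk <- peak_measure(erp, 1, 1, c(200, 600), "positive", local_points = 3)
  expect_equal(pk$amplitude, 10)
  expect_equal(pk$latency, 400)
  expect_true(pk$local)

  # monotone rising edge: no local peak, falls back with a warning
  rise <- make_wave_erp(tt / 100, srate = fs, tmin = 0)
  expect_warning(pf <- peak_measure(rise, 1, 1, c(100, 500), "positive",
                                    local_points = 3), "absolute extreme")
  expect_false(pf$local)
  expect_equal(pf$latency, 499)

  two <- 8 * exp(-(tt - 250)^2 / (2 * 30^2)) + 10 * exp(-(tt - 500)^2 / (2 * 30^2))
  erp2 <- make_wave_erp(two, srate = fs, tmin = 0)
  pk2 <- peak_measure(erp2, 1, 1, c(100, 700), "positive", local_points = 5)
  expect_equal(pk2$latency, 500)

  flat <- make_wave_erp(rep(c(0, 7, 0), c(100, 100, 100)), srate = fs, tmin = 0)
  expect_equal(peak_measure(flat, 1, 1, c(0, 300), "positive")$latency, 100)

  neg <- make_wave_erp(-tri, srate = fs, tmin = 0)
  pkn <- peak_measure(neg, 1, 1, c(200, 600), "negative")
  expect_equal(pkn$amplitude, -10)
})

test_that("fractional area latency divides areas by the closed forms", {
  fs <- 1000
  tt <- seq(0, 200 - 1, by = 1)
  tri <- pmax(0, 1 - abs(tt - 100) / 100)
  erp <- make_wave_erp(tri, srate = fs, tmin = 0)
  expect_equal(fractional_area_latency(erp, 1, 1, c(0, 200), 0.5, "positive"),
               100, tolerance = 1)

  const <- make_constant_erp(3, srate = fs, tmin = 0, tmax = 100)
  expect_equal(fractional_area_latency(const, 1, 1, c(0, 100), 0.2, "positive"),
               20, tolerance = 1)

  # right triangle rising 0 -> 10 over [0, 100]: A(t) ~ t^2, so t50 = 100/sqrt(2)
  rt <- make_wave_erp(seq(0, 10, length.out = 1000), srate = 10000, tmin = 0)
  expect_equal(fractional_area_latency(rt, 1, 1, c(0, 100), 0.5, "positive"),
               100 / sqrt(2), tolerance = 0.2)

  expect_error(fractional_area_latency(make_constant_erp(-1, tmin = 0, tmax = 100),
                                       1, 1, c(0, 100), 0.5, "positive"),
               "no area to divide")
})

test_that("fractional area latency of symmetric waveforms is the symmetry center", {
  fs <- 500
  tt <- seq(-200, 798, by = 1000 / fs)
  for (sig in c(30, 60, 120)) {
    g <- make_wave_erp(exp(-(tt - 300)^2 / (2 * sig^2)), srate = fs, tmin = -200)
    lat <- fractional_area_latency(g, 1, 1, c(0, 600), 0.5, "positive")
    expect_equal(lat, 300, tolerance = 1000 / fs)
  }
})

test_that("fractional peak latency interpolates the crossing and flags misses", {
  fs <- 1000
  tt <- seq(0, 799, by = 1)
  lin <- approx(c(0, 300, 400, 800), c(0, 0, 10, 10), xout = tt)$y
  erp <- make_wave_erp(lin, srate = fs, tmin = 0)
  expect_equal(fractional_peak_latency(erp, 1, 1, c(300, 500), 0.5, "positive"),
               350, tolerance = 1)

  # Gaussian half-maximum: peak - sigma * sqrt(2 ln 2)
  g <- make_wave_erp(10 * exp(-(tt - 400)^2 / (2 * 50^2)), srate = fs, tmin = 0)
  expect_equal(fractional_peak_latency(g, 1, 1, c(200, 600), 0.5, "positive"),
               400 - 50 * sqrt(2 * log(2)), tolerance = 1)

  # never drops below half peak -> NA with warning
  high <- make_wave_erp(5 + exp(-(tt - 400)^2 / (2 * 50^2)), srate = fs, tmin = 0)
  expect_warning(lat <- fractional_peak_latency(high, 1, 1, c(200, 600), 0.5,
                                                "positive"), "never reaches")
  expect_true(is.na(lat))
})

test_that("upsampling changes fractional peak latency by at most one raw sample", {
  fs <- 250
  tt <- seq(-200, 796, by = 1000 / fs)
  g <- make_wave_erp(10 * exp(-(tt - 400)^2 / (2 * 50^2)), srate = fs, tmin = -200)
  raw <- fractional_peak_latency(g, 1, 1, c(200, 600), 0.5, "positive")
  for (f in c(2, 5, 10)) {
    up <- fractional_peak_latency(g, 1, 1, c(200, 600), 0.5, "positive",
                                  interp_factor = f)
    expect_lt(abs(up - raw), 1000 / fs)
  }
})

test_that("broad-window negative area is robust where the signed integral is not", {
  # synthetic oddball difference: N2 flanked by P2 and P3
  fs <- 1000
  tt <- seq(-200, 799, by = 1)
  wave <- 4 * exp(-(tt - 180)^2 / (2 * 30^2)) -
          6 * exp(-(tt - 320)^2 / (2 * 40^2)) +
          8 * exp(-(tt - 550)^2 / (2 * 70^2))
  erp <- make_wave_erp(wave, srate = fs, tmin = -200)
  neg_narrow <- area_amplitude(erp, 1, 1, c(250, 450), "negative")
  neg_wide <- area_amplitude(erp, 1, 1, c(200, 500), "negative")
  expect_lt(abs(neg_wide - neg_narrow) / neg_narrow, 0.05)
  int_narrow <- area_amplitude(erp, 1, 1, c(250, 450), "integral")
  int_wide <- area_amplitude(erp, 1, 1, c(200, 500), "integral")
  expect_gt(abs(int_wide - int_narrow) / abs(int_narrow), 0.2)
})

test_that("measurement tables have the documented shapes and equal value multisets", {
  set.seed(14)
  erps <- lapply(1:3, function(i) {
    data <- array(rnorm(2 * 3 * 100), dim = c(2, 3, 100))
    erp_set(data, srate = 1000, tmin = -20, tmax = 80,
            chan_labels = c("Fz", "Cz", "Pz"), subject = paste0("S", i))
  })
  long <- measure_erps(erps, "mean_amp", c(0, 50), layout = "long")
  expect_equal(nrow(long), 18L)
  wide <- measure_erps(erps, "mean_amp", c(0, 50), layout = "wide")
  expect_equal(dim(wide), c(3L, 8L))   # erpset + subject + 6 measurement columns
  expect_true(all(c("bin1_Fz", "bin2_Pz") %in% names(wide)))
  expect_equal(sort(long$value),
               sort(unlist(wide[, -(1:2)])), ignore_attr = TRUE)

  path <- withr::local_tempfile(fileext = ".tsv")
  measure_erps(erps, "mean_amp", c(0, 50), layout = "long", path = path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 18L)

  viewer <- measure_viewer_data(erps[[1]], "mean_amp", c(0, 50))
  expect_equal(nrow(viewer), 2 * 3 * 100)
  expect_true(all(c("time", "amplitude", "value") %in% names(viewer)))
})
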