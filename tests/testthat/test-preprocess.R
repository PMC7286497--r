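# Cleaning rules, regularization, decimation, step/angle derivation.

test_that("landing buffer removes strictly-within fixes only", {
  sites <- landing_site("LS", 0, 9)
  # fixes due east of the site at ~2.9 km, ~3.0 km, 10 km, 20 km; the
  # boundary radius is taken as the exact haversine distance of fix 2 so the
  # boundary comparison is on identical doubles
  km_per_deg <- R_EARTH * pi / 180 / 1000
  lon_at <- function(km) 9 + km / km_per_deg
  tr <- make_trip(c(0, 5, 10, 15), rep(0, 4),
                  c(lon_at(2.9), lon_at(3.0), lon_at(10), lon_at(20)))
  boundary_km <- haversine_m(0, 9, 0, lon_at(3.0)) / 1000
  out <- trim_landing_buffer(tr, sites, radius_km = boundary_km)
  expect_equal(nrow(out$fixes), 3)
  expect_equal(out$fixes$lon[1], lon_at(3.0))   # boundary retained
  # inclusive flag removes the boundary fix too
  out2 <- trim_landing_buffer(tr, sites, radius_km = boundary_km,
                              inclusive = TRUE)
  expect_equal(nrow(out2$fixes), 2)
  # distant site: identity
  far <- landing_site("far", 45, 100)
  expect_equal(trim_landing_buffer(tr, far, 3)$fixes, tr$fixes)
  # everything inside the buffer -> NULL with warning
  expect_warning(gone <- trim_landing_buffer(tr, sites, radius_km = 5000),
                 "fewer than 2")
  expect_null(gone)
})

test_that("speed filter is a forward sweep from the first fix", {
  km_per_deg <- R_EARTH * pi / 180 / 1000
  # 60 km/h for 60 s is 1 km
  lon_km <- function(km) 9 + km / km_per_deg
  # middle fix implies 60 km/h in and out; outer pair alone implies 30 km/h
  tr <- make_trip(c(0, 60, 120), rep(0, 3), c(lon_km(0), lon_km(1), lon_km(1)))
  out <- speed_filter(tr, vmax_kmh = 50)
  expect_equal(nrow(out$fixes), 2)
  expect_equal(out$fixes$lon, c(lon_km(0), lon_km(1)))

  # all slow: identity
  tr2 <- make_trip(c(0, 60, 120), rep(0, 3),
                   c(lon_km(0), lon_km(0.5), lon_km(1)))
  expect_equal(speed_filter(tr2, 50)$fixes, tr2$fixes)

  # a single 60 km/h pair: second removed (geodesic oracle: 1 km in 60 s)
  tr3 <- make_trip(c(0, 60, 120), rep(0, 3),
                   c(lon_km(0), lon_km(1), lon_km(1.2)))
  out3 <- speed_filter(tr3, 50)
  expect_false(lon_km(1) %in% out3$fixes$lon)

  # property: output never implies > vmax between consecutive retained fixes
  set.seed(21)
  for (rep in 1:5) {
    n <- 50
    lon <- 9 + cumsum(runif(n, 0, 0.008))   # up to ~53 km/h at 60 s
    tr4 <- make_trip(seq(0, by = 60, length.out = n), rep(0.3, n), lon)
    out4 <- speed_filter(tr4, 50)
    f <- out4$fixes
    sp <- haversine_m(f$lat[-nrow(f)], f$lon[-nrow(f)],
                      f$lat[-1], f$lon[-1]) / 1000 /
      (diff(as.numeric(f$time)) / 3600)
    expect_true(all(sp <= 50 + 1e-9))
  }
})

test_that("regularize interpolates at constant speed along segments", {
  # midpoint of a 10-s constant-speed segment
  tr <- make_trip(c(0, 10), c(0, 0), c(0, 0.001))
  out <- regularize(tr, 5)
  expect_equal(nrow(out$fixes), 3)
  expect_equal(out$fixes$lon[2], 0.0005, tolerance = 1e-12)
  expect_equal(attr(out, "interval_s"), 5)

  # already regular at the target interval: identity on positions
  tr2 <- make_trip(seq(0, 30, by = 5), rep(0, 7), 9 + (0:6) * 1e-4)
  out2 <- regularize(tr2, 5)
  expect_equal(out2$fixes$lat, tr2$fixes$lat, tolerance = 1e-12)
  expect_equal(out2$fixes$lon, tr2$fixes$lon, tolerance = 1e-12)

  # 60 s span at 5 s -> floor(span/interval) + 1 = 13 fixes
  tr3 <- make_trip(c(0, 25, 60), c(0, 0.001, 0.002), c(9, 9.001, 9.002))
  expect_equal(nrow(regularize(tr3, 5)$fixes), 13)

  # grid points inside a gap larger than max_gap_s come back missing
  tr4 <- make_trip(c(0, 5, 300, 305), rep(0, 4), 9 + c(0, 1, 2, 3) * 1e-4)
  out4 <- regularize(tr4, 5, max_gap_s = 50)
  inside <- out4$fixes$time > as.POSIXct(5, tz = "UTC",
                                         origin = "1970-01-01") &
    out4$fixes$time < as.POSIXct(300, tz = "UTC", origin = "1970-01-01")
  expect_true(all(is.na(out4$fixes$lat[inside])))
  expect_false(anyNA(out4$fixes$lat[!inside]))
})

test_that("decimate keeps every k-th fix and requires a regular grid", {
  tr <- regularize(make_trip(c(0, 30, 60), c(0, 0.001, 0.002),
                             c(9, 9.001, 9.002)), 5)
  expect_equal(nrow(tr$fixes), 13)
  d2 <- decimate(tr, 2)
  expect_equal(nrow(d2$fixes), 7)
  expect_equal(attr(d2, "interval_s"), 10)
  expect_identical(decimate(tr, 1), tr)
  # decimating below 2 fixes warns (downstream empty-series signal)
  expect_warning(decimate(tr, 20), "< 2 fixes")

  # non-regular input: error directing the user to regularize
  irregular <- make_trip(c(0, 5, 12), c(0, 0, 0), c(9, 9.0001, 9.0002))
  expect_error(decimate(irregular, 2), "regularize")
})

test_that("regularize-then-decimate equals coarse regularize (<= 1 m per fix)", {
  set.seed(22)
  for (rep in 1:3) {
    n <- 12
    t_s <- cumsum(c(0, sample(c(7, 13, 20, 31), n - 1, replace = TRUE)))
    lat <- 0.3 + cumsum(rnorm(n, 0, 5e-4))
    lon <- 9.2 + cumsum(rnorm(n, 0, 5e-4))
    tr <- make_trip(t_s, lat, lon)
    k <- 3
    a <- decimate(regularize(tr, 5, max_gap_s = 1e6), k)
    b <- regularize(tr, 5 * k, max_gap_s = 1e6)
    m <- min(nrow(a$fixes), nrow(b$fixes))
    d <- haversine_m(a$fixes$lat[1:m], a$fixes$lon[1:m],
                     b$fixes$lat[1:m], b$fixes$lon[1:m])
    expect_true(all(d <= 1))
  }
})

test_that("interpolated path length never exceeds the original (chord shortening)", {
  set.seed(23)
  n <- 15
  t_s <- cumsum(c(0, sample(c(6, 11, 17), n - 1, replace = TRUE)))
  tr <- make_trip(t_s, 0.3 + cumsum(rnorm(n, 0, 4e-4)),
                  9.2 + cumsum(rnorm(n, 0, 4e-4)))
  coarse <- regularize(tr, 30, max_gap_s = 1e6)
  expect_lte(trip_summary(coarse)$total_distance_km,
             trip_summary(tr)$total_distance_km + 1e-9)
})

test_that("steps_and_angles: conventions and unit checks", {
  # three collinear equally spaced fixes on the equator: angle 0
  tr <- make_trip(c(0, 5, 10), c(0, 0, 0), c(9, 9.001, 9.002))
  sa <- steps_and_angles(tr)
  expect_equal(length(sa$step), 2)
  expect_equal(length(sa$angle), 1)
  expect_equal(sa$angle, 0, tolerance = 1e-9)

  # due east then due north: left turn, +pi/2
  tr2 <- make_trip(c(0, 5, 10), c(0, 0, 0.001), c(9, 9.001, 9.001))
  expect_equal(steps_and_angles(tr2)$angle, pi / 2, tolerance = 1e-6)
  # due east then due south: right turn, -pi/2
  tr3 <- make_trip(c(0, 5, 10), c(0, 0, -0.001), c(9, 9.001, 9.001))
  expect_equal(steps_and_angles(tr3)$angle, -pi / 2, tolerance = 1e-6)

  # step of 0.001 degree along the equator: oracle R * dlon
  tr4 <- make_trip(c(0, 5), c(0, 0), c(0, 0.001))
  oracle_m <- R_EARTH * 0.001 * pi / 180
  expect_equal(steps_and_angles(tr4)$step, oracle_m, tolerance = 1e-6)
  expect_equal(steps_and_angles(tr4)$step, 111.1949, tolerance = 1e-3)

  # zero-length adjacent step: angle missing, not 0
  tr5 <- make_trip(c(0, 5, 10), c(0, 0, 0), c(9, 9, 9.001))
  sa5 <- steps_and_angles(tr5)
  expect_equal(sa5$step[1], 0)
  expect_true(is.na(sa5$angle[1]))

  expect_error(steps_and_angles(make_trip(c(0, 5), c(0, 0), c(9, 9.001))),
               NA)
})

test_that("reversing a trip negates its turning angles", {
  set.seed(24)
  n <- 20
  tr <- make_trip(seq(0, by = 5, length.out = n),
                  0.3 + cumsum(runif(n, 1e-5, 3e-4)),
                  9.2 + cumsum(runif(n, 1e-5, 3e-4)))
  fw <- steps_and_angles(tr)
  rv <- steps_and_angles(make_trip(seq(0, by = 5, length.out = n),
                                   rev(tr$fixes$lat), rev(tr$fixes$lon)))
  expect_equal(rv$angle, -rev(fw$angle), tolerance = 1e-6)
})

test_that("speed_series converts correctly", {
  s <- make_series(c(100, 0, 50), c(0, 0), interval_s = 5)
  expect_equal(speed_series(s), c(72, 0, 36))
})

test_that("a simulated two-state trip has bimodal speeds", {
  prof <- recovery_profile(5000)
  tr <- simulate_trip(prof, seed = 31)
  sp <- speed_series(steps_and_angles(tr))
  ms <- speed_mode_separation(sp)
  expect_gt(ms$separation_ratio, 2)
  # per-state mean speeds sit at the profile means (5 m and 50 m per 5 s)
  f <- tr$truth$labels == "fishing"
  expect_equal(mean(sp[f]), 5 * 3.6 / 5, tolerance = 0.05)
  expect_equal(mean(sp[!f]), 50 * 3.6 / 5, tolerance = 0.05)
  expect_lt(ms$centers[1], ms$centers[2] / 2)
})
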