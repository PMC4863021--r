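test_that("Hargreaves PET handles degenerate and invalid temperature inputs", {
  # zero diurnal range kills the sqrt term regardless of site or season
  expect_equal(hargreaves_pet(15, 15, 47, 2000, 7), 0)
  expect_equal(hargreaves_pet(-3, -3, 0, 1999, 1), 0)
  # deep-winter months where Tmean + 17.8 < 0 clamp to zero with a warning
  expect_warning(p <- hargreaves_pet(-40, -35, 47, 2000, 1), "clamped")
  expect_equal(p, 0)
  expect_error(hargreaves_pet(10, 5, 47, 2000, 7), "tmax < tmin")
  expect_error(hargreaves_pet(0, 10, 70, 2000, 7), "latitude")
  expect_error(hargreaves_pet(0, 10, 47, 2000, 13), "month")
})

test_that("Hargreaves PET matches a brute-force daily computation", {
  # independent oracle: daily FAO-56 extraterrestrial radiation, daily PET,
  # summed over the days of the month
  daily_pet <- function(tmin, tmax, lat, year, month) {
    dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
    if (leap) dm[2] <- 29
    yl <- if (leap) 366 else 365
    j0 <- if (month == 1) 0 else sum(dm[1:(month - 1)])
    phi <- lat * pi / 180
    tot <- 0
    for (day in seq_len(dm[month])) {
      j <- j0 + day
      dr <- 1 + 0.033 * cos(2 * pi * j / yl)
      dec <- 0.409 * sin(2 * pi * j / yl - 1.39)
      ws <- acos(max(-1, min(1, -tan(phi) * tan(dec))))
      ra <- (24 * 60 / pi) * 0.0820 * dr *
        (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws)) * 0.408
      tot <- tot + 0.0023 * ra * ((tmin + tmax) / 2 + 17.8) * sqrt(tmax - tmin)
    }
    tot
  }
  cases <- list(c(10, 25, 47, 2000, 7), c(-5, 3, 47, 2000, 3),
                c(15, 30, -30, 1988, 12), c(0, 9, 60, 2004, 2))
  for (cs in cases) {
    got <- hargreaves_pet(cs[1], cs[2], cs[3], cs[4], cs[5])
    want <- daily_pet(cs[1], cs[2], cs[3], cs[4], cs[5])
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("water balance is precipitation minus PET, and rejects gaps", {
  clim <- data.frame(site_id = "A", year = rep(2000:2001, each = 12),
                     month = rep(1:12, 2),
                     precip_mm = runif(24, 0, 120),
                     tmin_c = rnorm(24, 5, 8), latitude = 45)
  clim$tmax_c <- clim$tmin_c + runif(24, 1, 12)
  wb <- water_balance(clim)
  pet <- hargreaves_pet(wb$tmin_c, wb$tmax_c, wb$latitude, wb$year, wb$month)
  expect_equal(wb$d_mm, wb$precip_mm - pet)

  gap <- clim[-15, ]
  expect_error(water_balance(gap), "gaps")
})

test_that("uniform aggregation equals a brute-force windowed sum", {
  set.seed(4)
  x <- rnorm(60, 10, 5)
  expect_identical(aggregate_uniform(x, 1), x)
  expect_equal(aggregate_uniform(rep(3, 30), 7)[7:30], rep(21, 24))
  for (k in c(2, 12, 60)) {
    got <- aggregate_uniform(x, k)
    expect_true(all(is.na(got[seq_len(k - 1)])))
    for (m in k:60) expect_equal(got[m], sum(x[(m - k + 1):m]))
  }
  expect_error(aggregate_uniform(x, 0), "k must be")
  expect_error(aggregate_uniform(x, 61), "k must be")
})

test_that("log-logistic standardization is centered, monotone and errors cleanly", {
  set.seed(11)
  n_yr <- 100
  month <- rep(1:12, n_yr)
  d <- rnorm(12 * n_yr, 20, 30)
  agg <- aggregate_uniform(d, 12)
  z <- standardize_loglogistic(agg, month)
  expect_true(all(is.na(z[1:11])) && !anyNA(z[12:length(z)]))
  for (mo in 1:12) {
    sel <- month == mo & !is.na(z)
    expect_lt(abs(mean(z[sel])), 0.15)
    expect_lt(abs(sd(z[sel]) - 1), 0.15)
    # monotone: larger aggregated value never gives a smaller z
    o <- order(agg[sel])
    expect_true(all(diff(z[sel][o]) >= 0))
  }
  # the fitted median maps to z = 0
  par <- droughtscale:::loglogistic_pwm(agg[month == 1 & !is.na(agg)])
  med <- par["origin"] + par["scale"]
  vals1 <- c(agg[month == 1], med)
  zz <- standardize_loglogistic(vals1, rep(1, n_yr + 1),
                                reference = c(rep(TRUE, n_yr), FALSE))
  expect_lt(abs(zz[n_yr + 1]), 1e-6)

  expect_error(standardize_loglogistic(rnorm(15), rep(1, 15)),
               "calendar month 1.*at least 20")
  expect_error(standardize_loglogistic(rep(2, 30), rep(1, 30)), "degenerate")
})

test_that("gamma standardization honours the zero point mass", {
  # q = 0.5 with x = 0 lands exactly at the distribution median
  vals <- c(rep(0, 20), rgamma(20, 3, 0.1))
  z <- standardize_gamma(vals, rep(1, 40))
  expect_equal(unique(z[vals == 0]), 0)
  # with no zeros, the fitted gamma median maps to ~0
  set.seed(2)
  pos <- rgamma(200, shape = 4, rate = 0.1)
  par <- droughtscale:::gamma_ml(pos)
  med <- qgamma(0.5, par[1], par[2])
  z2 <- standardize_gamma(c(pos, med), rep(1, 201),
                          reference = c(rep(TRUE, 200), FALSE))
  expect_lt(abs(z2[201]), 1e-6)
  expect_error(standardize_gamma(rep(0, 25), rep(1, 25)), "all reference")
  expect_error(standardize_gamma(c(-1, rgamma(24, 2)), rep(1, 25)),
               "requires values >= 0")
})

test_that("SPEI/SPI columns match the independent reference implementation", {
  # fixture frozen from the numpy/scipy oracle at tools/oracle_spei.py
  fx <- read.csv(test_path("fixture-spei-oracle-synthetic.csv"))
  for (k in c(3, 12)) {
    z <- standardize_loglogistic(aggregate_uniform(fx$d, k), fx$month)
    ref <- fx[[paste0("spei_k", k)]]
    ok <- !is.na(z)
    expect_equal(is.na(z), is.na(ref))
    expect_lt(max(abs(z[ok] - ref[ok])), 0.05)
  }
  for (k in 1:3) {
    z <- standardize_gamma(aggregate_uniform(fx$precip, k), fx$month)
    ref <- fx[[paste0("spi_k", k)]]
    ok <- !is.na(z)
    expect_lt(max(abs(z[ok] - ref[ok])), 0.05)
  }
})

test_that("index bank has the right shape, missing pattern and is pure", {
  bank <- small_bank()
  expect_s3_class(bank, "index_bank")
  expect_equal(ncol(bank$spei), 24)
  expect_equal(ncol(bank$spi), 3)
  # per site, column k is NA for exactly the first k-1 months
  for (s in unique(bank$site_id)) {
    rows <- which(bank$site_id == s)
    for (k in c(1, 2, 12, 24)) {
      col <- bank$spei[rows, k]
      expect_equal(which(is.na(col)), seq_len(k - 1))
      expect_true(all(is.finite(col[k:length(col)])))
    }
  }
  bank2 <- suppressWarnings(
    build_index_bank(small_climate(), spei_scales = 1:24, spi_scales = 1:3))
  expect_identical(bank, bank2)

  short <- small_climate()
  short <- short[short$year <= 1950, ]
  expect_error(suppressWarnings(build_index_bank(short)), "too short")
})
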