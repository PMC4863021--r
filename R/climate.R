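#' Hargreaves potential evapotranspiration
#'
#' Monthly potential evapotranspiration (PET) from the temperature-based
#' Hargreaves equation,
#' \deqn{PET = 0.0023 \, R_a \, (T_{mean} + 17.8) \sqrt{T_{max} - T_{min}},}
#' where \eqn{R_a} is the month-mean extraterrestrial radiation in equivalent
#' mm/day derived from latitude and day of year (FAO-56 formulation), and the
#' daily value is scaled by the number of days in the month.
#'
#' @param tmin Monthly mean daily minimum temperature, degrees C.
#' @param tmax Monthly mean daily maximum temperature, degrees C. Must be
#'   \code{>= tmin}.
#' @param latitude Latitude in decimal degrees; \code{abs(latitude) < 66.5}
#'   (no polar-night handling).
#' @param year Calendar year (used for leap-day counting).
#' @param month Month of year, 1-12.
#' @return PET in mm/month (vectorised over all arguments; always \code{>= 0}).
#'   Months where \eqn{T_{mean} + 17.8 < 0} are clamped to 0 with a warning.
#' @examples
#' hargreaves_pet(10, 25, 47, 2000, 7)
#' @export
hargreaves_pet <- function(tmin, tmax, latitude, year, month) {
  n <- max(length(tmin), length(tmax), length(latitude), length(year),
           length(month))
  tmin <- rep_len(tmin, n); tmax <- rep_len(tmax, n)
  latitude <- rep_len(latitude, n)
  year <- rep_len(year, n); month <- rep_len(month, n)
  if (any(tmax < tmin))
    stop("hargreaves_pet: tmax < tmin for ", sum(tmax < tmin), " record(s)")
  if (any(abs(latitude) >= 66.5))
    stop("hargreaves_pet: |latitude| must be < 66.5 degrees")
  if (any(month < 1 | month > 12))
    stop("hargreaves_pet: month must be in 1..12")

  ra <- mapply(monthly_mean_ra, latitude, year, month)
  nd <- mapply(days_in_month, year, month)
  tmean <- (tmin + tmax) / 2
  heat <- tmean + 17.8
  if (any(heat < 0)) {
    warning("hargreaves_pet: (Tmean + 17.8) < 0 for ", sum(heat < 0),
            " record(s); PET clamped to 0")
    heat <- pmax(heat, 0)
  }
  pet <- 0.0023 * ra * heat * sqrt(tmax - tmin) * nd
  pmax(pet, 0)
}

# FAO-56 daily extraterrestrial radiation in equivalent mm/day, averaged over
# the days of the month.
monthly_mean_ra <- function(latitude, year, month) {
  nd <- days_in_month(year, month)
  j0 <- cumsum(c(0, vapply(1:11, function(m) days_in_month(year, m), 0)))[month]
  j <- j0 + seq_len(nd)
  phi <- latitude * pi / 180
  yl <- if (is_leap(year)) 366 else 365
  dr <- 1 + 0.033 * cos(2 * pi * j / yl)
  dec <- 0.409 * sin(2 * pi * j / yl - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(dec))))
  gsc <- 0.0820  # MJ m-2 min-1
  ra_mj <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(dec) + cos(phi) * cos(dec) * sin(ws))
  mean(ra_mj * 0.408)  # MJ m-2 day-1 -> mm day-1
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}

days_in_month <- function(year, month) {
  dm <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  d <- dm[month]
  d[month == 2 & is_leap(year)] <- 29
  d
}

#' Monthly climatic water balance
#'
#' Computes the water balance D = precipitation - PET for every site-month of
#' a climate series, the raw material for SPEI.
#'
#' @param climate A data frame with columns \code{site_id, year, month,
#'   precip_mm, tmin_c, tmax_c, latitude} (one row per site-month; see
#'   \code{\link{read_climate}}).
#' @return The input with two columns appended: \code{pet_mm} and \code{d_mm}
#'   (\code{precip_mm - pet_mm}), ordered by site then time.
#' @export
water_balance <- function(climate) {
  climate <- check_climate(climate)
  climate$pet_mm <- hargreaves_pet(climate$tmin_c, climate$tmax_c,
                                   climate$latitude, climate$year,
                                   climate$month)
  climate$d_mm <- climate$precip_mm - climate$pet_mm
  climate
}

# validates schema, ordering and gap-free monthly coverage per site
check_climate <- function(climate) {
  need <- c("site_id", "year", "month", "precip_mm", "tmin_c", "tmax_c",
            "latitude")
  miss <- setdiff(need, names(climate))
  if (length(miss))
    stop("climate table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(climate$precip_mm < 0)) stop("negative precipitation")
  if (any(climate$tmax_c < climate$tmin_c)) stop("tmax < tmin in climate table")
  climate <- climate[order(climate$site_id, climate$year, climate$month), ]
  for (s in unique(climate$site_id)) {
    sub <- climate[climate$site_id == s, ]
    idx <- sub$year * 12L + (sub$month - 1L)
    gaps <- which(diff(idx) != 1L)
    if (length(gaps)) {
      bad <- paste0(sub$year[gaps], "-", sub$month[gaps], "+1")
      stop("climate series for site ", s, " has gaps after: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  rownames(climate) <- NULL
  climate
}

#' Backward-looking uniform aggregation
#'
#' Aggregates a monthly series with a rectangular (uniform) kernel: the output
#' at month m is the unweighted sum of the values at months m-k+1, ..., m.
#' The first k-1 months, where the window is incomplete, are \code{NA}.
#'
#' @param values Numeric monthly series.
#' @param k Integer timescale in months, \code{1 <= k <= length(values)}.
#' @return Numeric vector of the same length as \code{values}.
#' @export
aggregate_uniform <- function(values, k) {
  n <- length(values)
  if (length(k) != 1 || k != round(k) || k < 1 || k > n)
    stop("aggregate_uniform: k must be a single integer in 1..length(values)")
  if (k == 1) return(values)
  cs <- cumsum(values)
  out <- c(rep(NA_real_, k - 1), cs[k:n] - c(0, cs[seq_len(n - k)]))
  out
}

# unbiased probability-weighted moments W0, W1, W2 with decreasing weights
# (1-F)^s, the type used in the standard SPEI log-logistic fit
pwm_unbiased <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  w0 <- mean(x)
  w1 <- sum((n - i) / (n - 1) * x) / n
  w2 <- sum((n - i) * (n - i - 1) / ((n - 1) * (n - 2)) * x) / n
  c(w0, w1, w2)
}

# three-parameter log-logistic fit by PWM; returns c(shape, scale, origin).
# A negative shape (negatively L-skewed sample) gives the reflected
# distribution, supported below the origin.
loglogistic_pwm <- function(x) {
  if (stats::sd(x) == 0)
    stop("degenerate (constant) values: log-logistic fit impossible")
  w <- pwm_unbiased(x)
  shape <- (2 * w[2] - w[1]) / (6 * w[2] - w[1] - 6 * w[3])
  if (!is.finite(shape) || abs(shape) <= 1)
    stop("log-logistic PWM fit failed (|shape| <= 1); values unsuitable")
  g1 <- gamma(1 + 1 / shape) * gamma(1 - 1 / shape)
  scale <- (w[1] - 2 * w[2]) * shape / g1
  origin <- w[1] - scale * g1
  c(shape = shape, scale = scale, origin = origin)
}

ploglogistic <- function(x, par) {
  u <- x - par[3]
  if (par[1] > 0) {
    ifelse(u > 0, 1 / (1 + (par[2] / u)^par[1]), 0)
  } else {
    # reflected (negative shape): support below the origin
    ifelse(u < 0, 1 / (1 + (par[2] / u)^par[1]), 1)
  }
}

Z_CLIP <- 6  # standardized indices clipped to +/- 6 for numerical safety

#' Standardize an aggregated water-balance series (SPEI recipe)
#'
#' For each calendar month separately, fits a three-parameter log-logistic
#' distribution to the reference-period values by unbiased probability-weighted
#' moments, maps each value to its cumulative probability and then to a
#' standard-normal quantile. This is the SPEI construction.
#'
#' @param aggregated Aggregated monthly series (from
#'   \code{\link{aggregate_uniform}}); may contain leading \code{NA}s.
#' @param month Calendar month (1-12) of each entry.
#' @param reference Logical mask of entries forming the reference period
#'   (default: all defined entries).
#' @return z-score series, \code{NA} where the input is \code{NA}; values
#'   clipped to \eqn{\pm 6}.
#' @export
standardize_loglogistic <- function(aggregated, month,
                                    reference = !is.na(aggregated)) {
  z <- rep(NA_real_, length(aggregated))
  for (mo in sort(unique(month))) {
    sel <- month == mo & !is.na(aggregated)
    ref <- sel & reference
    if (sum(ref) < 20)
      stop("calendar month ", mo, ": only ", sum(ref),
           " reference values; at least 20 required for log-logistic fit")
    par <- tryCatch(loglogistic_pwm(aggregated[ref]),
                    error = function(e) stop("calendar month ", mo, ": ",
                                             conditionMessage(e)))
    p <- ploglogistic(aggregated[sel], par)
    z[sel] <- clip_z(stats::qnorm(p))
  }
  z
}

#' Standardize an aggregated precipitation series (SPI recipe)
#'
#' For each calendar month, fits a two-parameter gamma distribution by maximum
#' likelihood to the positive reference values, treats zeros as a point mass
#' with probability q = #zeros/n, forms H(x) = q + (1-q) G(x) and maps to a
#' standard-normal quantile.
#'
#' @inheritParams standardize_loglogistic
#' @return z-score series (SPI), clipped to \eqn{\pm 6}.
#' @export
standardize_gamma <- function(aggregated, month,
                              reference = !is.na(aggregated)) {
  if (any(aggregated < 0, na.rm = TRUE))
    stop("standardize_gamma: negative values; SPI requires values >= 0")
  z <- rep(NA_real_, length(aggregated))
  for (mo in sort(unique(month))) {
    sel <- month == mo & !is.na(aggregated)
    ref <- sel & reference
    n <- sum(ref)
    if (n < 20)
      stop("calendar month ", mo, ": only ", n,
           " reference values; at least 20 required for gamma fit")
    pos <- aggregated[ref][aggregated[ref] > 0]
    if (length(pos) == 0)
      stop("calendar month ", mo, ": all reference values are zero")
    q <- (n - length(pos)) / n
    par <- gamma_ml(pos)
    x <- aggregated[sel]
    h <- q + (1 - q) * stats::pgamma(x, shape = par[1], rate = par[2])
    h[x == 0] <- q
    z[sel] <- clip_z(stats::qnorm(h))
  }
  z
}

# two-parameter gamma ML fit via the digamma score equation
gamma_ml <- function(x) {
  if (stats::sd(x) == 0)
    stop("degenerate (constant) values: gamma fit impossible")
  m <- mean(x)
  s <- log(m) - mean(log(x))
  f <- function(a) log(a) - digamma(a) - s
  # method-of-moments bracket around the Thom starting value
  a0 <- (1 + sqrt(1 + 4 * s / 3)) / (4 * s)
  shape <- stats::uniroot(f, lower = a0 / 100, upper = a0 * 100,
                          extendInt = "yes")$root
  c(shape = shape, rate = shape / m)
}

clip_z <- function(z) pmin(pmax(z, -Z_CLIP), Z_CLIP)

#' Build the bank of candidate drought indices
#'
#' Computes, for every site, the SPEI at every timescale in \code{spei_scales}
#' (from the Hargreaves water balance) and the SPI at every timescale in
#' \code{spi_scales} (from precipitation alone), storing all candidate columns
#' so a model-fitting algorithm can sample among them. The full available
#' record is the reference period for distribution fitting.
#'
#' @param climate Climate data frame (see \code{\link{water_balance}}).
#' @param spei_scales Integer vector of SPEI timescales in months (default
#'   \code{1:120}).
#' @param spi_scales Integer vector of SPI timescales (default \code{1:3}).
#' @return An object of class \code{index_bank}: a list with vectors
#'   \code{site_id}, \code{year}, \code{month}, matrices \code{spei}
#'   (site-months x timescales) and \code{spi}, the scale grids, and the
#'   reference period. Cells in the first k-1 months of a site's record are
#'   \code{NA}.
#' @export
build_index_bank <- function(climate, spei_scales = 1:120, spi_scales = 1:3) {
  wb <- water_balance(climate)
  sites <- unique(wb$site_id)
  kmax <- max(spei_scales, spi_scales)
  pieces <- lapply(sites, function(s) {
    sub <- wb[wb$site_id == s, ]
    n <- nrow(sub)
    need <- kmax - 1 + 20 * 12
    if (n < need)
      stop("site ", s, ": series of ", n, " months is too short; at least ",
           need, " months required for timescale ", kmax,
           " with 20 reference values per calendar month")
    spei <- sapply(spei_scales, function(k)
      standardize_loglogistic(aggregate_uniform(sub$d_mm, k), sub$month))
    spi <- sapply(spi_scales, function(k)
      standardize_gamma(aggregate_uniform(sub$precip_mm, k), sub$month))
    list(site_id = sub$site_id, year = sub$year, month = sub$month,
         spei = matrix(spei, nrow = n), spi = matrix(spi, nrow = n))
  })
  bank <- list(
    site_id = unlist(lapply(pieces, `[[`, "site_id")),
    year    = unlist(lapply(pieces, `[[`, "year")),
    month   = unlist(lapply(pieces, `[[`, "month")),
    spei    = do.call(rbind, lapply(pieces, `[[`, "spei")),
    spi     = do.call(rbind, lapply(pieces, `[[`, "spi")),
    spei_scales = as.integer(spei_scales),
    spi_scales  = as.integer(spi_scales),
    reference_period = range(climate$year))
  colnames(bank$spei) <- sprintf("spei_k%03d", spei_scales)
  colnames(bank$spi) <- sprintf("spi_k%d", spi_scales)
  class(bank) <- "index_bank"
  bank
}

#' @export
print.index_bank <- function(x, ...) {
  cat("Drought-index bank\n")
  cat("  sites:", length(unique(x$site_id)),
      " site-months:", length(x$year), "\n")
  cat("  SPEI timescales:", length(x$spei_scales),
      sprintf("(%d..%d)", min(x$spei_scales), max(x$spei_scales)), "\n")
  cat("  SPI timescales: ", length(x$spi_scales),
      sprintf("(%d..%d)", min(x$spi_scales), max(x$spi_scales)), "\n")
  cat("  reference period:", x$reference_period[1], "-",
      x$reference_period[2], "\n")
  invisible(x)
}

# row indices in the bank for given (site, year, month) triples
bank_rows <- function(bank, site_id, year, month) {
  key <- paste(bank$site_id, bank$year, bank$month)
  match(paste(site_id, year, month), key)
}
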