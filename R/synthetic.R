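#' Generating truth for synthetic studies
#'
#' Bundles the parameter values used to generate synthetic wetland data. The
#' defaults echo the magnitudes a field study of northern-prairie pothole
#' wetlands would produce: a negative intercept (basins well below full on
#' average), a positive era effect (fuller contemporary wetlands), a strong
#' positive SPEI effect damped in the contemporary era, a negligible SPI
#' effect, and SPEI timescales of 84 (historical) and 64 (contemporary)
#' months with a 2-month SPI timescale.
#'
#' @param beta Mean-model coefficients in design order (intercept, era, SPEI,
#'   SPI, SPEI x era, SPEI x SPI, SPEI x SPI x era).
#' @param bphi Dispersion intercept, log scale.
#' @param tau_gamma,tau_delta,tau_eps,tau_zeta Precisions (1/variance) of
#'   the wetland effects and residuals on the two linear scales.
#' @param t_hist,t_cont,t_spi True timescales (months; positions in the
#'   1-based scale grids).
#' @return Named list of class \code{ts_truth}.
#' @export
ts_truth <- function(beta = c(-0.62, 0.65, 0.68, -0.02, -0.32, 0, 0),
                     bphi = 3.65,
                     tau_gamma = 19.7, tau_delta = 0.51,
                     tau_eps = 0.2, tau_zeta = 0.51,
                     t_hist = 84, t_cont = 64, t_spi = 2) {
  if (any(c(tau_gamma, tau_delta, tau_eps, tau_zeta) <= 0))
    stop("precisions must be > 0")
  structure(list(beta = beta, bphi = bphi, tau_gamma = tau_gamma,
                 tau_delta = tau_delta, tau_eps = tau_eps,
                 tau_zeta = tau_zeta, t_hist = as.integer(t_hist),
                 t_cont = as.integer(t_cont), t_spi = as.integer(t_spi)),
            class = "ts_truth")
}

# northern-plains-like monthly climatology used by the climate generator
CLIM_DEFAULTS <- list(
  precip_mean = c(12, 11, 22, 35, 55, 85, 70, 60, 45, 30, 18, 13),  # mm
  precip_shape = 2,            # gamma shape per month
  precip_zero = c(0.06, 0.06, 0.03, 0.01, 0, 0, 0, 0, 0, 0.01, 0.03, 0.06),
  tmax_mean = c(-8, -5, 2, 12, 19, 24, 28, 27, 21, 13, 2, -6),      # deg C
  diurnal = c(11, 11, 11, 12, 13, 13, 14, 14, 13, 12, 11, 11),
  temp_sd = 2.2,               # SD of the AR(1) monthly anomaly
  temp_ar = 0.5,
  latitude = 47)

#' Simulate a monthly climate series
#'
#' Generates seeded synthetic monthly climate for one or more sites:
#' precipitation from a calendar-month-specific gamma distribution with an
#' occasional exact zero in dry months, and minimum/maximum temperature from
#' seasonal climatological means plus a shared AR(1) anomaly, with
#' \code{tmax > tmin} enforced.
#'
#' @param n_sites Number of sites.
#' @param years Year range, default \code{c(1895, 2011)}.
#' @param seed Integer seed (the series is deterministic given it).
#' @param clim List of climatology settings overriding \code{CLIM_DEFAULTS}.
#' @return Climate data frame as consumed by \code{\link{build_index_bank}}.
#' @export
simulate_climate <- function(n_sites = 5, years = c(1895, 2011), seed = 1,
                             clim = list()) {
  cl <- utils::modifyList(CLIM_DEFAULTS, clim)
  set.seed(seed)
  yrs <- years[1]:years[2]
  n <- length(yrs) * 12
  out <- lapply(seq_len(n_sites), function(s) {
    mo <- rep(1:12, length(yrs))
    yr <- rep(yrs, each = 12)
    shp <- rep_len(cl$precip_shape, 12)[mo]
    pr <- if (all(is.finite(shp)))
      stats::rgamma(n, shape = shp, scale = cl$precip_mean[mo] / shp)
    else cl$precip_mean[mo]  # degenerate (noise-free) limit
    if (any(cl$precip_zero > 0))
      pr[stats::runif(n) < cl$precip_zero[mo]] <- 0
    anom <- if (cl$temp_sd > 0)
      as.numeric(stats::arima.sim(list(ar = cl$temp_ar), n,
                                  sd = cl$temp_sd * sqrt(1 - cl$temp_ar^2)))
    else rep(0, n)
    tmax <- cl$tmax_mean[mo] + anom + stats::rnorm(n, 0, 0.35 * cl$temp_sd)
    tmin <- tmax - pmax(0.5, cl$diurnal[mo] +
                          stats::rnorm(n, 0, 0.45 * cl$temp_sd))
    data.frame(site_id = paste0("S", s), year = yr, month = mo,
               precip_mm = pr, tmin_c = tmin, tmax_c = tmax,
               latitude = cl$latitude + (s - (n_sites + 1) / 2) * 0.4)
  })
  do.call(rbind, out)
}

#' Simulate wetland observations from the generative model
#'
#' Draws wetland-year observations from the hierarchical beta regression at
#' known parameter values: wetland effects and residuals from their
#' precision-implied normals, the design built at the TRUE timescales from
#' the supplied index bank, responses from the beta likelihood, then the
#' boundary clamping applied. Wetlands are assigned to the bank's sites
#' round-robin. Historical years are drawn per wetland from
#' \code{hist_window} and contemporary years from \code{cont_window} (with
#' replacement when the window is shorter than \code{years_per_era},
#' mirroring repeated imagery).
#'
#' @param truth A \code{\link{ts_truth}}.
#' @param bank An \code{index_bank} defined at the truth's timescales for all
#'   requested years.
#' @param n_wetlands Number of wetlands (default 147).
#' @param years_per_era Observations per wetland and era (default 10).
#' @param seed Integer seed.
#' @param hist_window,cont_window Year ranges for the two eras (defaults
#'   1938-1969 and 2003-2010 excluding 2007-2008).
#' @param month Evaluation month for the index join (default 8).
#' @param basin_ha Basin area given to every synthetic wetland (the response
#'   is a proportion, so this only scales the stored areas).
#' @return List with \code{obs} (observation data frame), \code{data} (the
#'   assembled \code{\link{wetland_data}}), and \code{truth}.
#' @export
simulate_observations <- function(truth, bank, n_wetlands = 147,
                                  years_per_era = 10, seed = 1,
                                  hist_window = 1938:1969,
                                  cont_window = c(2003:2006, 2009:2010),
                                  month = 8, basin_ha = 100) {
  stopifnot(inherits(truth, "ts_truth"))
  set.seed(seed)
  sites <- unique(bank$site_id)
  I <- n_wetlands
  wl_site <- sites[(seq_len(I) - 1) %% length(sites) + 1]
  pick <- function(win) sample(win, years_per_era,
                               replace = years_per_era > length(win))
  obs <- do.call(rbind, lapply(seq_len(I), function(i) {
    data.frame(wetland_id = sprintf("W%03d", i), site_id = wl_site[i],
               year = c(pick(hist_window), pick(cont_window)),
               era = rep(0:1, each = years_per_era))
  }))
  rows <- bank_rows(bank, obs$site_id, obs$year, month)
  if (anyNA(rows))
    stop("bank does not cover year(s): ",
         paste(unique(obs$year[is.na(rows)]), collapse = ", "))
  ks <- match(c(truth$t_hist, truth$t_cont), bank$spei_scales)
  kp <- match(truth$t_spi, bank$spi_scales)
  if (anyNA(ks) || is.na(kp))
    stop("bank grid does not include the truth's timescales")
  s <- ifelse(obs$era == 0, bank$spei[rows, ks[1]], bank$spei[rows, ks[2]])
  p <- bank$spi[rows, kp]
  if (anyNA(s) || anyNA(p))
    stop("undefined index at requested year(s); extend the climate record")
  N <- nrow(obs)
  gam <- stats::rnorm(I, 0, 1 / sqrt(truth$tau_gamma))
  ep <- stats::rnorm(I, 0, 1 / sqrt(truth$tau_eps))
  delta <- stats::rnorm(N, 0, 1 / sqrt(truth$tau_delta))
  zeta <- stats::rnorm(N, 0, 1 / sqrt(truth$tau_zeta))
  wid <- match(obs$wetland_id, unique(obs$wetland_id))
  b <- truth$beta
  e <- obs$era
  eta <- b[1] + b[2] * e + s * (b[3] + b[5] * e) + b[4] * p +
    s * p * (b[6] + b[7] * e) + gam[wid] + delta
  mu <- inv_logit(eta)
  phi <- exp(truth$bphi + ep[wid] + zeta)
  yraw <- stats::rbeta(N, mu * phi, (1 - mu) * phi)
  obs$basin_ha <- basin_ha
  obs$area_ha <- yraw * basin_ha
  data <- wetland_data(obs, bank, month = month)
  list(obs = obs, data = data, truth = truth,
       latent = list(gamma = gam, eps = ep, delta = delta, zeta = zeta,
                     mu = mu, phi = phi))
}
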