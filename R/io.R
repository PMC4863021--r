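#' Read / write the delimited file formats of the pipeline
#'
#' All pipeline artifacts are plain comma-delimited text with a header row
#' and \code{NA} as the missing marker: climate series
#' (\code{site_id,year,month,precip_mm,tmin_c,tmax_c,latitude}), wetland
#' observation tables (\code{wetland_id,site_id,year,era,area_ha,basin_ha}),
#' index banks (\code{site_id,year,month,spei_k001..,spi_k1..}), and
#' posterior draw tables (\code{chain,iteration,} one column per scalar
#' parameter).
#'
#' @param path File path.
#' @return \code{read_climate} and \code{read_observations} return validated
#'   data frames; \code{read_index_bank} an \code{index_bank};
#'   \code{read_draws} a list with \code{draws}, \code{chain},
#'   \code{iteration}. Writers return the path invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_climate <- function(path) {
  check_climate(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname pipeline_io
#' @param x Object to write.
#' @export
write_climate <- function(x, path) {
  utils::write.csv(check_climate(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("wetland_id", "site_id", "year", "era", "area_ha", "basin_ha")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop("observation file missing column(s): ", paste(miss, collapse = ", "))
  if (!all(obs$era %in% c(0, 1))) stop("era must be 0 or 1")
  obs
}

#' @rdname pipeline_io
#' @export
write_observations <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
write_index_bank <- function(x, path) {
  stopifnot(inherits(x, "index_bank"))
  df <- data.frame(site_id = x$site_id, year = x$year, month = x$month)
  df <- cbind(df, as.data.frame(x$spei), as.data.frame(x$spi))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_index_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  sp_cols <- grep("^spei_k", names(df))
  pi_cols <- grep("^spi_k", names(df))
  if (!length(sp_cols) || !length(pi_cols))
    stop("not an index-bank file: no spei_k*/spi_k* columns in ", path)
  bank <- list(
    site_id = df$site_id, year = df$year, month = df$month,
    spei = as.matrix(df[sp_cols]), spi = as.matrix(df[pi_cols]),
    spei_scales = as.integer(sub("^spei_k", "", names(df)[sp_cols])),
    spi_scales = as.integer(sub("^spi_k", "", names(df)[pi_cols])),
    reference_period = range(df$year))
  class(bank) <- "index_bank"
  bank
}

#' @rdname pipeline_io
#' @param fit A \code{ts_betareg} fit (scalar draws only; wetland-effect
#'   draws go to a companion long-format file when \code{effects_path} is
#'   given).
#' @param effects_path Optional path for the long-format wetland-effect
#'   draws (\code{chain,iteration,wetland_id,gamma,eps}).
#' @export
write_draws <- function(fit, path, effects_path = NULL) {
  df <- data.frame(chain = fit$chain, iteration = fit$iteration)
  df <- cbind(df, as.data.frame(fit$draws))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(effects_path)) {
    I <- ncol(fit$gamma)
    long <- data.frame(
      chain = rep(fit$chain, I),
      iteration = rep(fit$iteration, I),
      wetland_id = rep(colnames(fit$gamma), each = nrow(fit$gamma)),
      gamma = as.vector(fit$gamma),
      eps = as.vector(fit$eps))
    utils::write.csv(long, effects_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_draws <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chain", "iteration") %in% names(df)))
  list(draws = as.matrix(df[setdiff(names(df), c("chain", "iteration"))]),
       chain = df$chain, iteration = df$iteration)
}
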