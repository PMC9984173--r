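#' Generate the latent risk process
#'
#' Each risk component (conflict, price, weather, pest, displacement by
#' default) follows a district-level AR(1) whose monthly innovation is the sum
#' of a country shock, a province shock and a district shock; the shared
#' province/country shocks induce the spatial correlation that makes
#' province- and country-level aggregates informative for a district. The
#' process is simulated from its stationary distribution and extends
#' `burn_months` before the world's first calendar month so that lagged values
#' (phase impact delays, reporting delays) are defined from the start.
#'
#' @param world a [gen_world()] object
#' @param ar_coef,shock_sd,shock_share,lead_tau see [scenario_config()];
#'   default to the world's configuration
#' @param burn_months extra months simulated before the calendar start
#' @param seed integer seed
#' @return `cc_risk` object: array `z` of dim (component, district, month)
#'   over the extended month range, plus the process parameters
#' @export
gen_latent_risk <- function(world,
                            ar_coef = world$config$ar_coef,
                            shock_sd = world$config$shock_sd,
                            shock_share = world$config$shock_share,
                            lead_tau = world$config$lead_tau,
                            burn_months = max(lead_tau) +
                              world$config$report_lag_months + 12L,
                            seed = world$config$seed + 1L) {
  stopifnot(inherits(world, "cc_world"), abs(ar_coef) < 1, shock_sd > 0,
            all(lead_tau >= 0))
  set.seed(seed)
  comps <- world$config$components
  geo <- world$geo
  months <- (min(world$months) - as.integer(burn_months)):max(world$months)
  D <- nrow(geo); Tn <- length(months); K <- length(comps)
  sd_d <- shock_sd * sqrt(shock_share[["district"]])
  sd_p <- shock_sd * sqrt(shock_share[["province"]])
  sd_c <- shock_sd * sqrt(shock_share[["country"]])
  provs <- unique(geo$province_id); ctrs <- unique(geo$country_id)
  pi_idx <- match(geo$province_id, provs)
  ci_idx <- match(geo$country_id, ctrs)
  z <- array(NA_real_, dim = c(K, D, Tn),
             dimnames = list(comps, geo$district_id, as.character(months)))
  stat_scale <- 1 / sqrt(1 - ar_coef^2)
  for (k in seq_len(K)) {
    innov <- function() {
      sd_c * stats::rnorm(length(ctrs))[ci_idx] +
        sd_p * stats::rnorm(length(provs))[pi_idx] +
        sd_d * stats::rnorm(D)
    }
    zk <- matrix(NA_real_, D, Tn)
    zk[, 1] <- innov() * stat_scale
    for (t in 2:Tn) zk[, t] <- ar_coef * zk[, t - 1] + innov()
    z[k, , ] <- zk
  }
  structure(list(z = z, months = months, components = comps,
                 districts = geo$district_id, ar_coef = ar_coef,
                 shock_sd = shock_sd, shock_share = shock_share,
                 lead_tau = lead_tau),
            class = "cc_risk")
}

# z values for one component at given districts x months (recycling-safe)
risk_z <- function(risk, component, districts, months) {
  di <- match(districts, risk$districts)
  ti <- match(months, risk$months)
  if (anyNA(di)) stop("unknown district in risk lookup")
  if (anyNA(ti)) stop("month outside simulated risk range: ",
                      paste(ym_format(months[is.na(ti)][1])))
  zk <- risk$z[component, , ]
  dim(zk) <- dim(risk$z)[2:3]   # keep matrix shape for 1-district worlds
  zk[cbind(di, ti)]
}

# aggregated (phase-driving) risk: mean over components of z lagged by lead_tau
aggregate_risk <- function(risk, districts, months) {
  acc <- 0
  for (k in risk$components) {
    acc <- acc + risk_z(risk, k, districts, months - risk$lead_tau[[k]])
  }
  acc / length(risk$components)
}

#' Generate the synthetic IPC phase panel
#'
#' The ordinal phase at each reporting period end is a deterministic
#' thresholding of the aggregated latent risk: phase = 1 + number of
#' cutpoints lying below the district's aggregated risk (each component
#' entering with its phase-impact delay `lead_tau`). The panel is complete
#' over (district, reporting period).
#'
#' @param world a [gen_world()] object
#' @param risk a [gen_latent_risk()] object
#' @param cutpoints four strictly increasing reals
#' @return tibble `district_id`, `period_ym`, `phase` (integer 1..5) of class
#'   `cc_ipc`
#' @export
gen_ipc_panel <- function(world, risk,
                          cutpoints = world$config$ipc_cutpoints) {
  stopifnot(inherits(world, "cc_world"), inherits(risk, "cc_risk"))
  if (length(cutpoints) != 4 || is.unsorted(cutpoints, strictly = TRUE)) {
    stop("configuration error: cutpoints must be 4 strictly increasing values")
  }
  grid <- tidyr::expand_grid(district_id = world$geo$district_id,
                             period_ym = world$period_ends)
  a <- aggregate_risk(risk, grid$district_id, grid$period_ym)
  grid$phase <- 1L + findInterval(a, cutpoints)
  class(grid) <- c("cc_ipc", class(grid))
  grid
}

# definition table for the nine time-varying traditional factors:
# monotone (increasing) transforms of one latent component each; the
# displacement component is deliberately unmeasured, mirroring the premise
# that some crisis drivers are invisible to traditional indicators
trad_factor_defs <- function() {
  tibble::tibble(
    factor = c("conflict_events", "conflict_fatalities",
               "food_price_index", "food_price_change",
               "evapotranspiration_index",
               "rainfall_deficit", "rainfall_anomaly",
               "vegetation_deficit", "vegetation_anomaly"),
    component = c("conflict", "conflict", "price", "price", "weather",
                  "weather", "weather", "pest", "pest"),
    transform = list(
      function(z) exp(0.5 * z), function(z) exp(0.3 * z),
      function(z) 100 * exp(0.05 * z), function(z) 1.2 * z,
      function(z) 1.5 * z, function(z) z, function(z) 0.8 * z,
      function(z) 1.2 * z, function(z) 0.7 * z)
  )
}

#' Generate the traditional risk-factor panels
#'
#' Produces nine monthly time-varying factors per district (conflict events
#' and fatalities, a food price index and its change, evapotranspiration,
#' rainfall deficit/anomaly, vegetation deficit/anomaly), each a noisy
#' monotone transform of one latent risk component observed with a reporting
#' delay, plus five time-invariant district attributes (population, area,
#' ruggedness, cropland and pasture shares).
#'
#' @param world a [gen_world()] object
#' @param risk a [gen_latent_risk()] object
#' @param noise_sd additive observation noise sd
#' @param report_lag_months reporting delay in months relative to the latent
#'   process
#' @param seed integer seed
#' @return `cc_factors` object: list with `time_varying` (tibble `factor`,
#'   `district_id`, `ym`, `value`) and `static` (tibble `district_id`,
#'   `attr`, `value`)
#' @export
gen_traditional_factors <- function(world, risk,
                                    noise_sd = world$config$factor_noise_sd,
                                    report_lag_months =
                                      world$config$report_lag_months,
                                    seed = world$config$seed + 2L) {
  stopifnot(inherits(world, "cc_world"), inherits(risk, "cc_risk"),
            report_lag_months >= 0, noise_sd >= 0)
  set.seed(seed)
  defs <- trad_factor_defs()
  defs <- defs[defs$component %in% risk$components, ]
  grid <- tidyr::expand_grid(district_id = world$geo$district_id,
                             ym = world$months)
  tv <- purrr::pmap_dfr(defs, function(factor, component, transform) {
    z <- risk_z(risk, component, grid$district_id,
                grid$ym - as.integer(report_lag_months))
    tibble::tibble(factor = factor, district_id = grid$district_id,
                   ym = grid$ym,
                   value = transform(z) + stats::rnorm(nrow(grid), 0, noise_sd))
  })
  d <- nrow(world$geo)
  static <- tibble::tibble(
    district_id = rep(world$geo$district_id, 5),
    attr = rep(c("population", "district_area", "ruggedness",
                 "cropland_share", "pasture_share"), each = d),
    value = c(stats::rlnorm(d, 11, 1), stats::rlnorm(d, 7, 0.8),
              stats::rlnorm(d, 3, 0.9), stats::rbeta(d, 2, 3),
              stats::rbeta(d, 2, 4))
  )
  structure(list(time_varying = tv, static = static), class = "cc_factors")
}
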