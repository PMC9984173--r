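#' Scenario configuration for the synthetic world
#'
#' Bundles every knob of the synthetic-data generator: the size of the
#' geographic hierarchy, the monthly calendar and the IPC reporting schedule,
#' the latent-risk process, the article stream, and the planted text-feature
#' lexicon. The defaults describe the study conditions the package is designed
#' around: 21 countries partitioned into provinces and districts (189
#' districts in total), ten years of monthly data with quarterly IPC reporting
#' until the end of 2015 and three reports per year thereafter, roughly 40
#' articles per district-month, and news mentions of planted cause features
#' leading their impact on the IPC phase by four months.
#'
#' @param n_countries number of countries
#' @param provinces_per_country provinces in each country
#' @param districts_per_province districts in each province
#' @param start_year,start_month first calendar month generated
#' @param n_months number of consecutive months
#' @param regime_switch year-month index (see [ym()]) at which IPC reporting
#'   switches from four times a year (Jan/Apr/Jul/Oct) to three (Feb/Jun/Oct)
#' @param components names of the latent risk components
#' @param ar_coef monthly AR(1) persistence of each latent component, in (-1, 1)
#' @param shock_sd total innovation standard deviation of each component
#' @param shock_share named proportions of innovation variance attributed to
#'   district-, province- and country-level shocks (must sum to 1); the
#'   province/country shares induce the spatial correlation that makes
#'   province- and country-level aggregates informative
#' @param lead_tau months by which the latent risk (and hence news mentions of
#'   its cause features) leads its effect on the IPC phase; scalar or one value
#'   per component
#' @param ipc_cutpoints four increasing cutpoints on the aggregated latent risk
#'   defining phases 1..5; defaults are the normal quantiles that give
#'   approximately 55/30/12/2.5/0.5 percent of district-periods in phases
#'   1/2/3/4/5 under the default risk process
#' @param article_rate expected articles per district-month before coverage bias
#' @param coverage_sdlog log-sd of the per-district log-normal coverage-bias
#'   multiplier (mean 1); bias is drawn independently of risk, a modelling
#'   choice (the joint distribution of coverage and food insecurity is unknown)
#' @param base_mention_prob baseline probability that an article mentions a
#'   planted cause feature when its component's risk is at its mean
#' @param mention_slope increase in log-odds of a cause-feature mention per
#'   unit of (current) latent risk
#' @param noise_mention_prob constant mention probability of each noise feature
#' @param n_noise_features number of planted noise (irrelevant) features
#' @param frame_emission_prob probability that an article mentioning a cause
#'   feature also emits a cause/effect semantic frame for it
#' @param decoy_frame_prob probability that an article emits a decoy frame
#'   (no seed in the effect, or a non-causal trigger)
#' @param report_lag_months months by which traditional factors lag the latent
#'   risk process; the default of 4 encodes the documented pattern that
#'   ground-measured indicators (vegetation indices, conflict event counts)
#'   reflect a shock several months after local news reports on it
#' @param factor_noise_sd additive noise sd of the traditional factors
#' @param embedding_dim,embedding_within_sd,embedding_between_sd geometry of
#'   the synthetic embedding table: cluster centroids are drawn with sd
#'   `embedding_between_sd` and words around their centroid with sd
#'   `embedding_within_sd`
#' @param lexicon planted lexicon, a data frame with columns `ngram`,
#'   `component` (a component name or "noise"/"seed") and `cluster`;
#'   defaults to [default_lexicon()]
#' @param seed integer seed fixing the whole generation stream
#' @return an object of class `cc_config` (a validated list)
#' @export
scenario_config <- function(n_countries = 21,
                            provinces_per_country = 3,
                            districts_per_province = 3,
                            start_year = 2010, start_month = 1,
                            n_months = 120,
                            regime_switch = ym(2016, 1),
                            components = c("conflict", "price", "weather",
                                           "pest", "displacement"),
                            ar_coef = 0.85,
                            shock_sd = 1,
                            shock_share = c(district = 0.6, province = 0.25,
                                            country = 0.15),
                            lead_tau = 4,
                            ipc_cutpoints = c(0.11, 0.88, 1.60, 2.19),
                            article_rate = 40,
                            coverage_sdlog = 0.5,
                            base_mention_prob = 0.02,
                            mention_slope = 1,
                            noise_mention_prob = 0.02,
                            n_noise_features = 20,
                            frame_emission_prob = 0.25,
                            decoy_frame_prob = 0.03,
                            report_lag_months = 4,
                            factor_noise_sd = 0.5,
                            embedding_dim = 25,
                            embedding_within_sd = 0.1,
                            embedding_between_sd = 2,
                            lexicon = default_lexicon(components,
                                                      n_noise_features),
                            seed = 1L) {
  counts <- c(n_countries, provinces_per_country, districts_per_province,
              n_months, article_rate)
  if (any(counts <= 0)) {
    stop("configuration error: counts and rates must be positive")
  }
  probs <- c(base_mention_prob, noise_mention_prob, frame_emission_prob,
             decoy_frame_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (abs(ar_coef) >= 1) stop("configuration error: |ar_coef| must be < 1")
  if (any(lead_tau < 0)) stop("configuration error: lead_tau must be >= 0")
  if (length(lead_tau) == 1) {
    lead_tau <- stats::setNames(rep(lead_tau, length(components)), components)
  }
  stopifnot(length(lead_tau) == length(components))
  if (is.null(names(lead_tau))) names(lead_tau) <- components
  if (is.unsorted(ipc_cutpoints, strictly = TRUE) ||
      length(ipc_cutpoints) != 4) {
    stop("configuration error: ipc_cutpoints must be 4 strictly increasing values")
  }
  if (abs(sum(shock_share) - 1) > 1e-8 || any(shock_share < 0)) {
    stop("configuration error: shock_share must be non-negative and sum to 1")
  }
  lexicon <- tibble::as_tibble(lexicon)
  stopifnot(all(c("ngram", "component", "cluster") %in% names(lexicon)))
  if (anyDuplicated(lexicon$ngram)) {
    stop("configuration error: duplicate ngrams in lexicon")
  }
  cfg <- list(
    n_countries = n_countries,
    provinces_per_country = provinces_per_country,
    districts_per_province = districts_per_province,
    start_ym = ym(start_year, start_month),
    n_months = n_months,
    regime_switch = regime_switch,
    components = components,
    ar_coef = ar_coef,
    shock_sd = shock_sd,
    shock_share = shock_share,
    lead_tau = lead_tau,
    ipc_cutpoints = ipc_cutpoints,
    article_rate = article_rate,
    coverage_sdlog = coverage_sdlog,
    base_mention_prob = base_mention_prob,
    mention_slope = mention_slope,
    noise_mention_prob = noise_mention_prob,
    n_noise_features = n_noise_features,
    frame_emission_prob = frame_emission_prob,
    decoy_frame_prob = decoy_frame_prob,
    report_lag_months = report_lag_months,
    factor_noise_sd = factor_noise_sd,
    embedding_dim = embedding_dim,
    embedding_within_sd = embedding_within_sd,
    embedding_between_sd = embedding_between_sd,
    lexicon = lexicon,
    seed = as.integer(seed)
  )
  structure(cfg, class = "cc_config")
}

#' Default planted text-feature lexicon
#'
#' Cause features are tied to a latent risk component and carry the cluster
#' label of the corresponding semantic theme; seeds anchor the frame filter;
#' noise features are mentioned at a constant rate and belong to no risk
#' component.
#'
#' @param components latent risk component names
#' @param n_noise_features how many noise features to plant
#' @return tibble with columns `ngram`, `component`, `cluster`
#' @export
default_lexicon <- function(components = c("conflict", "price", "weather",
                                           "pest", "displacement"),
                            n_noise_features = 20) {
  cause <- list(
    conflict = c("conflict", "violence", "armed clashes", "civil war"),
    price = c("food prices", "price rise", "rising food prices", "inflation"),
    weather = c("drought", "floods", "failed rains", "heat wave"),
    pest = c("pests", "locusts", "armyworm", "crop disease"),
    displacement = c("displacement", "refugees", "forced migration",
                     "displaced people")
  )
  clusters <- c(conflict = "conflict and violence", price = "economic issues",
                weather = "weather conditions", pest = "pests and diseases",
                displacement = "forced displacements")
  cause <- cause[intersect(names(cause), components)]
  planted <- purrr::imap_dfr(cause, function(ngrams, comp) {
    tibble::tibble(ngram = ngrams, component = comp,
                   cluster = unname(clusters[comp]))
  })
  seeds <- tibble::tibble(
    ngram = c("food insecurity", "hunger crisis", "famine"),
    component = "seed", cluster = "food crisis"
  )
  noise <- tibble::tibble(
    ngram = sprintf("noise_%03d", seq_len(n_noise_features)),
    component = "noise", cluster = "other"
  )
  dplyr::bind_rows(planted, seeds, noise)
}

#' Generate the synthetic world: geography and calendar
#'
#' Builds a district/province/country hierarchy with unique names and a
#' monthly calendar carrying the IPC reporting schedule (period-end months in
#' January, April, July and October before the regime switch; February, June
#' and October after it).
#'
#' @param config a [scenario_config()] object
#' @return an object of class `cc_world`: a list with `geo` (tibble:
#'   `district_id`, `province_id`, `country_id`, and name columns),
#'   `months` (integer year-month indexes), `period_ends` (the subset of
#'   months on which an IPC reporting period ends) and `regime_switch`
#' @examples
#' w <- gen_world(scenario_config(n_countries = 2, provinces_per_country = 2,
#'                                districts_per_province = 3, n_months = 24))
#' nrow(w$geo)            # 12 districts
#' length(w$period_ends)  # 8 reporting periods in 2 pre-switch years
#' @export
gen_world <- function(config) {
  stopifnot(inherits(config, "cc_config"))
  cid <- sprintf("C%02d", seq_len(config$n_countries))
  geo <- tidyr::expand_grid(
    country_id = cid,
    p = seq_len(config$provinces_per_country),
    d = seq_len(config$districts_per_province)
  )
  geo <- dplyr::mutate(
    geo,
    province_id = sprintf("%s-P%02d", .data$country_id, .data$p),
    district_id = sprintf("%s-D%02d", .data$province_id, .data$d),
    country_name = sprintf("Country %s", substring(.data$country_id, 2)),
    province_name = sprintf("Province %s", substring(.data$province_id, 2)),
    district_name = sprintf("District %s", substring(.data$district_id, 2))
  )
  geo <- dplyr::select(geo, "district_id", "province_id", "country_id",
                       "district_name", "province_name", "country_name")
  months <- config$start_ym + seq_len(config$n_months) - 1L
  period_ends <- reporting_period_ends(months, config$regime_switch)
  structure(list(geo = geo, months = months, period_ends = period_ends,
                 regime_switch = config$regime_switch, config = config),
            class = "cc_world")
}

#' IPC reporting period-end months
#'
#' @param months integer year-month indexes
#' @param regime_switch first month of the 3-per-year schedule
#' @return the subset of `months` on which a reporting period ends
#' @export
reporting_period_ends <- function(months, regime_switch) {
  mo <- ym_month(months)
  pre <- months < regime_switch & mo %in% c(1L, 4L, 7L, 10L)
  post <- months >= regime_switch & mo %in% c(2L, 6L, 10L)
  sort(months[pre | post])
}

#' @export
print.cc_world <- function(x, ...) {
  cat(sprintf(
    "<cc_world> %d districts in %d countries; %d months (%s..%s), %d reporting periods\n",
    nrow(x$geo), length(unique(x$geo$country_id)), length(x$months),
    ym_format(min(x$months)), ym_format(max(x$months)), length(x$period_ends)))
  invisible(x)
}

#' @export
print.cc_config <- function(x, ...) {
  cat(sprintf(
    "<cc_config> %d x %d x %d geography, %d months, %d planted features, seed %d\n",
    x$n_countries, x$provinces_per_country, x$districts_per_province,
    x$n_months, nrow(x$lexicon), x$seed))
  invisible(x)
}
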