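# Simulator for censored qPCR experiments. Normalized Cq (delta-Cq) is drawn
# from one of three location-scale families on the cycle scale — normal,
# minimum-extreme-value (Gumbel), logistic — equivalent to e^(delta-Cq)
# following a log-normal, Weibull (shape 1/sigma) or log-logistic (scale
# parameter sigma) distribution. Raw Cq is delta-Cq plus a per-sample normal
# normalizer; values at or above the quality cycle c1 are reported
# undetermined, and the uncensored truth is retained for the BFD benchmark.

.sim_families <- c("lognormal", "weibull", "loglogistic")

#' Draw normalized Cq values from one simulation family
#'
#' Location `m = beta0 + x * beta1` on the cycle scale; dispersion `sigma`.
#' * `"lognormal"`: delta-Cq ~ Normal(m, sigma);
#' * `"weibull"`: delta-Cq = m + sigma * G with G a standard minimum-Gumbel
#'   variate (CDF `1 - exp(-e^g)`), so `e^delta-Cq` is Weibull with shape
#'   `1/sigma`;
#' * `"loglogistic"`: delta-Cq ~ Logistic(m, sigma), so `e^delta-Cq` is
#'   log-logistic.
#'
#' Uses the current RNG stream (seed upstream for reproducibility).
#'
#' @param family One of `"lognormal"`, `"weibull"`, `"loglogistic"`.
#' @param beta0 Intercept (cycles).
#' @param beta1 Group effect (cycles).
#' @param sigma Positive dispersion (cycles).
#' @param x Group covariate, 0 or 1.
#' @param n Number of draws.
#' @return Numeric vector of `n` delta-Cq values.
#' @export
sample_delta_cq <- function(family, beta0, beta1, sigma, x, n) {
  family <- match.arg(family, .sim_families)
  stopifnot(sigma > 0, x %in% c(0, 1))
  m <- beta0 + x * beta1
  switch(family,
    lognormal = stats::rnorm(n, mean = m, sd = sigma),
    weibull = m + sigma * log(stats::rexp(n)),   # log(Exp(1)) is minimum-Gumbel
    loglogistic = stats::rlogis(n, location = m, scale = sigma)
  )
}

#' Build a simulation scenario
#'
#' @param family Simulation family (see [sample_delta_cq()]).
#' @param beta0,beta1,sigma Model parameters (cycles).
#' @param n_per_group Samples per group (default 5, the small-sample design
#'   typical of preclinical studies).
#' @param c1 Maximum quality cycle (default 40).
#' @param normalizer_mean,normalizer_sd Per-sample normalizer Cq distribution
#'   (default Normal(25, 0.45)).
#' @param scenario_id Optional identifier.
#' @return A one-row tibble.
#' @export
new_scenario <- function(family, beta0, beta1, sigma, n_per_group = 5,
                         c1 = 40, normalizer_mean = 25, normalizer_sd = 0.45,
                         scenario_id = NA_integer_) {
  family <- match.arg(family, .sim_families)
  stopifnot(sigma > 0, n_per_group >= 2)
  tibble::tibble(
    scenario_id = scenario_id, family = family,
    beta0 = beta0, beta1 = beta1, sigma = sigma,
    n_per_group = as.integer(n_per_group), c1 = c1,
    normalizer_mean = normalizer_mean, normalizer_sd = normalizer_sd
  )
}

# fast internal draw: plain list, no tibbles; uses current RNG stream
.sim_draw <- function(scn) {
  n <- scn$n_per_group
  x <- rep(c(0, 1), each = n)
  dcq <- c(
    sample_delta_cq(scn$family, scn$beta0, scn$beta1, scn$sigma, 0, n),
    sample_delta_cq(scn$family, scn$beta0, scn$beta1, scn$sigma, 1, n)
  )
  norm_cq <- stats::rnorm(2 * n, scn$normalizer_mean, scn$normalizer_sd)
  cq <- dcq + norm_cq
  event <- cq < scn$c1
  list(
    group = rep(1:2, each = n),
    true_delta_y = dcq,
    normalizer_cq = norm_cq,
    cq = cq,
    phi = as.integer(event),
    # analysis value: observed delta-Cq for events, bound c1 - normalizer else
    value = ifelse(event, dcq, scn$c1 - norm_cq)
  )
}

#' Simulate one replicate experiment under a scenario
#'
#' Per sample: draw the normalizer Cq ~ Normal(`normalizer_mean`,
#' `normalizer_sd`), draw delta-Cq from the scenario family, and set
#' Cq = delta-Cq + normalizer Cq. The record is "determined" iff Cq < c1;
#' otherwise the instrument would report it undetermined. The uncensored
#' truth is kept so the BFD benchmark never has to re-derive it.
#'
#' @param scenario A one-row scenario tibble ([new_scenario()]).
#' @param seed Optional integer seed (session RNG state is preserved).
#' @return A list of class `sim_replicate`: `data` (a [as_cq_data()] tibble
#'   with target `"sim_target"` and normalizer `"sim_norm"`), `normalized`
#'   (the matching `cq_normalized` tibble), `true_delta_y` (list with
#'   `group1`, `group2`), and `scenario`.
#' @export
simulate_replicate <- function(scenario, seed = NULL) {
  stopifnot(nrow(scenario) == 1)
  scn <- as.list(scenario)
  draw <- if (is.null(seed)) .sim_draw(scn) else withr::with_seed(seed, .sim_draw(scn))
  n <- scn$n_per_group
  ids <- sprintf("S%02d", seq_len(2 * n))
  labels <- rep(c("group1", "group2"), each = n)
  records <- tibble::tibble(
    sample_id = rep(ids, 2),
    group_label = rep(labels, 2),
    target_id = rep(c("sim_target", "sim_norm"), each = 2 * n),
    cq = c(ifelse(draw$phi == 1L, draw$cq, NA_real_), draw$normalizer_cq),
    is_determined = c(draw$phi == 1L, rep(TRUE, 2 * n))
  )
  data <- as_cq_data(records, c1 = scn$c1, normalizer_target = "sim_norm",
                     max_cycles = max(scn$c1, 40))
  normalized <- new_normalized(
    draw$value[draw$group == 1L], draw$value[draw$group == 2L],
    draw$phi[draw$group == 1L], draw$phi[draw$group == 2L],
    c1 = scn$c1, target_id = "sim_target"
  )
  normalized$raw_cq <- ifelse(draw$phi == 1L, draw$cq, NA_real_)
  normalized$normalizer_cq <- draw$normalizer_cq
  structure(
    list(
      data = data,
      normalized = normalized,
      true_delta_y = list(group1 = draw$true_delta_y[draw$group == 1L],
                          group2 = draw$true_delta_y[draw$group == 2L]),
      scenario = scenario
    ),
    class = "sim_replicate"
  )
}

#' Draw random scenarios for the power study
#'
#' Intercepts `beta0 ~ Normal(10, 2.24)` and effects `beta1 ~ Normal(1, 4.47)`
#' independently per scenario; `sigma` is assigned deterministically across
#' scenarios according to `sigma_scheme` (default alternating 1, 2, 1, 2, ...
#' by scenario index).
#'
#' @param family Simulation family.
#' @param n_scenarios Number of scenarios (default 100 per family).
#' @param sigma_scheme `"alternate"` (default), `"all1"`, `"all2"`, or
#'   `"random"` (equiprobable 1 or 2).
#' @param seed Optional seed.
#' @inheritParams new_scenario
#' @return A tibble of scenarios, one row each.
#' @export
draw_power_scenarios <- function(family, n_scenarios = 100,
                                 sigma_scheme = c("alternate", "all1", "all2", "random"),
                                 n_per_group = 5, c1 = 40, seed = NULL) {
  family <- match.arg(family, .sim_families)
  sigma_scheme <- match.arg(sigma_scheme)
  draw <- function() {
    b0 <- stats::rnorm(n_scenarios, 10, 2.24)
    b1 <- stats::rnorm(n_scenarios, 1, 4.47)
    sg <- switch(sigma_scheme,
      alternate = rep_len(c(1, 2), n_scenarios),
      all1 = rep(1, n_scenarios),
      all2 = rep(2, n_scenarios),
      random = sample(c(1, 2), n_scenarios, replace = TRUE)
    )
    list(b0 = b0, b1 = b1, sg = sg)
  }
  par <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  purrr::map_dfr(seq_len(n_scenarios), function(i) {
    new_scenario(family, par$b0[i], par$b1[i], par$sg[i],
                 n_per_group = n_per_group, c1 = c1, scenario_id = i)
  })
}

#' The four null scenarios of the type-I-error design
#'
#' Log-normal family with no group effect (`beta1 = 0`), crossing
#' `beta0` in {5, 10} with `sigma` in {1, 2}.
#'
#' @inheritParams new_scenario
#' @return A four-row scenario tibble.
#' @export
type1_scenarios <- function(n_per_group = 5, c1 = 40) {
  grid <- expand.grid(sigma = c(1, 2), beta0 = c(5, 10))
  # parameter sets ordered as: (5,1), (10,1), (5,2), (10,2)
  grid <- grid[order(grid$sigma, grid$beta0), ]
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    new_scenario("lognormal", grid$beta0[i], 0, grid$sigma[i],
                 n_per_group = n_per_group, c1 = c1, scenario_id = i)
  })
}
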