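# Synthetic cohort generation calibrated to the published marginal
# distributions of a community-dwelling cohort aged 70-79. Right-skewed
# biomarkers are log-normal with location = log(median) and scale derived
# from the printed IQR under log-normality: sdlog = log(q3/q1) / (2 * z0.75).

.lognorm_scale <- function(q1, q3) log(q3 / q1) / (2 * stats::qnorm(0.75))

default_marginals <- function() {
  list(
    albumin   = list(dist = "normal", mean = 4.3, sd = 0.4, min = 2.0),
    d25_3     = list(dist = "lognormal", meanlog = log(20.3),
                     sdlog = .lognorm_scale(13.4, 28.9)),
    d25_2     = list(dist = "lognormal", meanlog = log(0.33),
                     sdlog = .lognorm_scale(0.2, 1.2)),
    vdbp      = list(dist = "lognormal", meanlog = log(253.3),
                     sdlog = .lognorm_scale(226.9, 284.1)),
    d1_25_3   = list(dist = "lognormal", meanlog = log(40.2),
                     sdlog = .lognorm_scale(30.2, 50.4)),
    vmr       = list(dist = "lognormal", meanlog = log(8.9),
                     sdlog = .lognorm_scale(6.5, 11.4)),
    ipth      = list(dist = "lognormal", meanlog = log(34), sdlog = 0.45),
    ifgf23    = list(dist = "lognormal", meanlog = log(44),
                     sdlog = .lognorm_scale(33, 59)),
    age       = list(dist = "normal", mean = 75, sd = 3, min = 70, max = 79),
    bmi       = list(dist = "normal", mean = 27.2, sd = 4.6, min = 15),
    egfr      = list(dist = "normal", mean = 72, sd = 19, min = 10),
    calcium   = list(dist = "normal", mean = 8.9, sd = 0.45, min = 6),
    phosphate = list(dist = "normal", mean = 3.58, sd = 0.5, min = 1.5),
    sex       = list(dist = "categorical",
                     prob = c(female = 0.53, male = 0.47)),
    race      = list(dist = "categorical",
                     prob = c(white = 221 / 370, black = 149 / 370)),
    season    = list(dist = "categorical",
                     prob = c(winter = 94 / 370, spring = 110 / 370,
                              summer = 84 / 370, fall = 82 / 370)),
    site      = list(dist = "categorical",
                     prob = c(memphis = 190 / 370, pittsburgh = 180 / 370)),
    diabetes  = list(dist = "bernoulli", prob = 154 / 370),
    phenotype = list(dist = "categorical",
                     prob = stats::setNames(
                       c(72, 60, 91, 48, 78, 21) / 370, gc_diplotypes()))
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of the source cohort: log-normal
#' biomarkers parameterized from published medians and IQRs, categorical
#' frequencies (sex, race, season, site, diabetes, Gc diplotype) from the
#' published counts, and measured free 25(OH)D produced by a truth model plus
#' additive Gaussian noise of magnitude comparable to the published
#' development RMSE (1.16 pg/mL). 24,25(OH)2D3 is generated multiplicatively
#' as VMR x 25(OH)D3 / 100, which induces the observed strong positive
#' dependence between the two metabolites; log iPTH is negatively correlated
#' with log 25(OH)D3 through a shared latent factor.
#'
#' @param n Number of participants.
#' @param seed Integer seed; identical configurations and seeds reproduce
#'   identical cohorts.
#' @param truth_model A [equation_spec()] mapping predictors to measured free
#'   25(OH)D; default the published Eq. (2), the fullest specification.
#' @param noise_sd SD of additive Gaussian noise on measured free 25(OH)D,
#'   pg/mL; default 1.16.
#' @param marginals Per-variable distribution parameters; see
#'   `freevitd:::default_marginals()` for the structure.
#' @param ipth_d3_rho Latent-normal correlation between log iPTH and log
#'   25(OH)D3 (rank correlation approximately equal); default -0.31, set 0
#'   for independence.
#' @param d25_2_floor Detection floor substituted for low 25(OH)D2 draws,
#'   ng/mL; default 0.2.
#' @param free_floor Lower bound on generated measured free 25(OH)D, pg/mL;
#'   default 0.5, just below the observed cohort minimum, preventing
#'   non-positive values under additive noise.
#' @return List of class `free25d_generator_config`.
#' @export
generator_config <- function(n = 370L, seed = 1L,
                             truth_model = eq2_spec(),
                             noise_sd = 1.16,
                             marginals = default_marginals(),
                             ipth_d3_rho = -0.31,
                             d25_2_floor = 0.2,
                             free_floor = 0.5) {
  stopifnot(n >= 1L, noise_sd >= 0, abs(ipth_d3_rho) < 1,
            inherits(truth_model, "free25d_equation"))
  for (nm in names(marginals)) {
    m <- marginals[[nm]]
    if (m$dist == "categorical" &&
        abs(sum(m$prob) - 1) > 1e-9) {
      stop(sprintf("categorical frequencies for '%s' must sum to 1", nm),
           call. = FALSE)
    }
    if (m$dist == "bernoulli" && (m$prob < 0 || m$prob > 1)) {
      stop(sprintf("bernoulli probability for '%s' out of [0, 1]", nm),
           call. = FALSE)
    }
  }
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         truth_model = truth_model, noise_sd = noise_sd,
         marginals = marginals, ipth_d3_rho = ipth_d3_rho,
         d25_2_floor = d25_2_floor, free_floor = free_floor),
    class = "free25d_generator_config"
  )
}

draw_marginal <- function(m, n) {
  x <- switch(m$dist,
    normal = stats::rnorm(n, m$mean, m$sd),
    lognormal = stats::rlnorm(n, m$meanlog, m$sdlog),
    categorical = sample(names(m$prob), n, replace = TRUE, prob = m$prob),
    bernoulli = stats::rbinom(n, 1L, m$prob),
    stop(sprintf("unknown distribution '%s'", m$dist), call. = FALSE)
  )
  if (!is.null(m$min)) x <- pmax(x, m$min)
  if (!is.null(m$max)) x <- pmin(x, m$max)
  x
}

#' Generate a synthetic cohort
#'
#' Draws `config$n` participants with the configured marginals and dependence
#' structure, evaluates the truth model on each, and adds Gaussian noise to
#' produce the "measured" free 25(OH)D (floored at `config$free_floor`).
#' Output is a cohort data frame in the canonical schema ([cohort_schema()]),
#' with the seed and generator description attached as attributes (and echoed
#' as header comments by [write_cohort()]).
#'
#' @param config A [generator_config()].
#' @return Data frame with one row per participant.
#' @examples
#' cohort <- generate_cohort(generator_config(n = 50, seed = 7))
#' mean(cohort$free25ohd_pg_ml)
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "free25d_generator_config"))
  n <- config$n
  m <- config$marginals
  with_seed(config$seed, {
    # correlated log-normal pair: 25(OH)D3 and iPTH share a latent factor
    z_d3 <- stats::rnorm(n)
    z_ipth <- config$ipth_d3_rho * z_d3 +
      sqrt(1 - config$ipth_d3_rho^2) * stats::rnorm(n)
    d25_3 <- exp(m$d25_3$meanlog + m$d25_3$sdlog * z_d3)
    ipth <- exp(m$ipth$meanlog + m$ipth$sdlog * z_ipth)
    vmr_draw <- draw_marginal(m$vmr, n)
    d24_25_3 <- vmr_draw * d25_3 / 100
    d25_2 <- pmax(draw_marginal(m$d25_2, n), config$d25_2_floor)
    cohort <- data.frame(
      albumin_g_dl = draw_marginal(m$albumin, n),
      d25_3_ng_ml = d25_3,
      d25_2_ng_ml = d25_2,
      vdbp_ug_ml = draw_marginal(m$vdbp, n),
      d1_25_3_pg_ml = draw_marginal(m$d1_25_3, n),
      d24_25_3_ng_ml = d24_25_3,
      ipth_pg_ml = ipth,
      ifgf23_pg_ml = draw_marginal(m$ifgf23, n),
      calcium_mg_dl = draw_marginal(m$calcium, n),
      phosphate_mg_dl = draw_marginal(m$phosphate, n),
      egfr_ml_min_173 = draw_marginal(m$egfr, n),
      age_years = draw_marginal(m$age, n),
      bmi_kg_m2 = draw_marginal(m$bmi, n),
      sex = draw_marginal(m$sex, n),
      race = draw_marginal(m$race, n),
      season = draw_marginal(m$season, n),
      site = draw_marginal(m$site, n),
      diabetes = draw_marginal(m$diabetes, n),
      phenotype = draw_marginal(m$phenotype, n),
      stringsAsFactors = FALSE
    )
    truth <- as.numeric(evaluate_equation(config$truth_model, cohort))
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd)
             else 0
    cohort$free25ohd_pg_ml <- pmax(truth + noise, config$free_floor)
    attr(cohort, "seed") <- config$seed
    attr(cohort, "provenance") <- sprintf(
      "synthetic cohort (freevitd generator): n=%d, seed=%d, truth=%s, noise_sd=%g",
      n, config$seed, config$truth_model$name, config$noise_sd)
    cohort
  })
}
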