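# Synthetic patient cohorts with a known logistic outcome model.

#' Default covariate distribution parameters for synthetic cohorts
#'
#' Marginal distributions of the clinicopathological variables of a primary
#' breast-cancer PDX cohort (age, subtype, Ki-67 labelling index, NAC status,
#' tumour size, lymphovascular invasion, positive lymph nodes, stromal TILs,
#' histologic grade, Miller-Payne grade and RCB for NAC cases) plus the six
#' intratumoral patch proportions (Dirichlet on the x10,000 simplex) and the
#' pathologist-assessed invasive fraction. Defaults reflect the published
#' whole-cohort marginals; covariates are drawn independently (correlations
#' are configurable only through replacement of this list).
#'
#' @return A named list of distribution parameters, suitable for the
#'   `covariate_params` argument of [cohort_gen_spec()].
#' @export
default_covariate_params <- function() {
  list(
    age = list(mean = 50.0, sd = 12.2, lower = 18, upper = 95),
    ki67 = list(mean = 44.7, sd = 29.1),     # floor-discretised to 10s
    size_cm = list(mean = 3.4, sd = 2.3, lower = 0.1, upper = 20),
    n_pos_ln = list(mu = 2.8, size = 0.12),  # negative binomial
    til_pct = list(mean = 10.7, sd = 17.9),  # floor-discretised to 10s
    subtype = list(levels = c("HER2+", "HR+", "HR+/HER2+", "TNBC"),
                   prob = c(0.0595, 0.4306, 0.0935, 0.4164)),
    nac = list(levels = c("no", "yes"), prob = c(0.558, 0.442)),
    diagnosis = list(levels = c("IDC", "other"), prob = c(0.892, 0.108)),
    lvi = list(levels = c("not identified", "present"), prob = c(0.567, 0.433)),
    hg = list(levels = c("2", "3"), prob = c(0.448, 0.552)),
    miller_payne = list(levels = 1:5, prob = c(0.288, 0.314, 0.366, 0.032, 0)),
    rcb_score = list(mean = 3.1, sd = 1.05, lower = 0, upper = 5.5),
    rcb_class = list(levels = c("I", "II", "III"), prob = c(0.026, 0.461, 0.513)),
    # mean fractions of adipose, background, necrosis, carcinoma, stroma, TDLU
    proportions = list(mean = c(0.060, 0.040, 0.087, 0.433, 0.334, 0.046),
                       concentration = 8)
  )
}

#' Default true outcome coefficients for synthetic cohorts
#'
#' A named coefficient vector on the [linear-predictor scale][fit_logistic]
#' loosely matched to published multivariate odds ratios (Ki-67 1.05/unit,
#' age 0.96/year, NAC 3.27, grade-3 4.34, size 1.20/cm, necrosis proportion
#' 1.927 and invasive carcinoma proportion 1.820 per 1,000 units); the
#' intercept is calibrated so that the expected prevalence under the default
#' covariate marginals matches the published primary-cohort engraftment rate
#' (59/353, about 16.7%). A configuration default, not a ground truth: the
#' generator records whatever vector is actually used.
#'
#' @return Named numeric vector of logistic coefficients.
#' @export
default_outcome_beta <- function() {
  c("(Intercept)" = -5.2,
    ki67 = log(1.05),
    age = log(0.96),
    "nac=yes" = log(3.27),
    "hg=3" = log(4.34),
    size_cm = log(1.20),
    NP = log(1.927) / 1000,
    ICP = log(1.820) / 1000)
}

#' Specification for a synthetic cohort
#'
#' @param n Cohort size (>= 1).
#' @param covariate_params Overrides merged into
#'   [default_covariate_params()] (partial lists allowed).
#' @param beta Named true logistic coefficient vector (see
#'   [default_outcome_beta()] for the naming convention); must be finite.
#' @param invasive_fraction_dist `c(shape1, shape2)` of the Beta distribution
#'   of the pathologist-assessed invasive carcinoma fraction; both > 0.
#' @param seed Integer seed.
#' @return An object of class `cohort_gen_spec`.
#' @export
cohort_gen_spec <- function(n,
                            covariate_params = list(),
                            beta = default_outcome_beta(),
                            invasive_fraction_dist = c(8, 2),
                            seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  params <- utils::modifyList(default_covariate_params(), covariate_params)
  for (v in c("age", "ki67", "size_cm", "til_pct", "rcb_score")) {
    if (!is.null(params[[v]]$sd) && params[[v]]$sd <= 0) {
      stop(sprintf("sd of `%s` must be positive", v), call. = FALSE)
    }
  }
  if (is.list(beta)) beta <- unlist(beta)
  if (!is.numeric(beta) || any(!is.finite(beta)) || is.null(names(beta))) {
    stop("`beta` must be a finite, named numeric vector", call. = FALSE)
  }
  if (length(invasive_fraction_dist) != 2L || any(invasive_fraction_dist <= 0)) {
    stop("`invasive_fraction_dist` must be two positive Beta parameters",
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n), covariate_params = params, beta = beta,
         invasive_fraction_dist = invasive_fraction_dist, seed = seed),
    class = "cohort_gen_spec"
  )
}

sample_cat <- function(n, spec) {
  factor(sample(spec$levels, n, replace = TRUE, prob = spec$prob),
         levels = spec$levels)
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` patient records with the covariate marginals of the cohort
#' specification, then draws the binary engraftment outcome from
#' `Bernoulli(plogis(beta . x))` using the true coefficient vector in the
#' spec. Continuous covariates come from truncated normals; Ki-67 and TIL
#' percentages are floor-discretised to the 10-step grid {0, 10, ..., 90};
#' positive-node counts are negative binomial; the six patch proportions are
#' Dirichlet on the x10,000 simplex (so they sum to 10,000 by construction),
#' with ICP = carcinoma proportion x invasive fraction. NAC-only fields
#' (Miller-Payne, RCB) are `NA` for chemo-naive records.
#'
#' The true coefficient vector is stored in `attr(cohort, "truth")` for
#' parameter-recovery checks.
#'
#' @param spec A [cohort_gen_spec()].
#' @return A `data.frame` with one row per patient.
#' @examples
#' coh <- generate_cohort(cohort_gen_spec(n = 200, seed = 1))
#' mean(coh$engrafted)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_gen_spec"))
  p <- spec$covariate_params
  n <- spec$n
  with_seed(spec$seed, {
    cohort <- data.frame(
      case_id = sprintf("case_%05d", seq_len(n)),
      age = rtruncnorm(n, p$age$mean, p$age$sd, p$age$lower, p$age$upper),
      subtype = sample_cat(n, p$subtype),
      ki67 = pmin(floor(rtruncnorm(n, p$ki67$mean, p$ki67$sd, 0, 100) / 10), 9) * 10,
      nac = sample_cat(n, p$nac),
      diagnosis = sample_cat(n, p$diagnosis),
      size_cm = rtruncnorm(n, p$size_cm$mean, p$size_cm$sd,
                           p$size_cm$lower, p$size_cm$upper),
      lvi = sample_cat(n, p$lvi),
      n_pos_ln = rnbinom(n, size = p$n_pos_ln$size, mu = p$n_pos_ln$mu),
      til_pct = pmin(floor(rtruncnorm(n, p$til_pct$mean, p$til_pct$sd, 0, 100) / 10), 9) * 10,
      hg = sample_cat(n, p$hg),
      stringsAsFactors = FALSE
    )
    nac_yes <- cohort$nac == "yes"
    cohort$miller_payne <- ifelse(
      nac_yes,
      sample(p$miller_payne$levels, n, replace = TRUE, prob = p$miller_payne$prob),
      NA_integer_)
    cohort$rcb_score <- ifelse(
      nac_yes,
      rtruncnorm(n, p$rcb_score$mean, p$rcb_score$sd,
                 p$rcb_score$lower, p$rcb_score$upper),
      NA_real_)
    rcb <- as.character(sample_cat(n, p$rcb_class))
    cohort$rcb_class <- ifelse(nac_yes, rcb, NA_character_)

    alpha <- p$proportions$mean * p$proportions$concentration
    g <- matrix(rgamma(n * 6L, shape = rep(alpha, each = n)), nrow = n)
    props <- 10000 * g / rowSums(g)
    colnames(props) <- c("AP", "BP", "NP", "TDLUP", "SP", "carcinomaP")
    cohort <- cbind(cohort, as.data.frame(props))
    cohort$invasive_fraction <- rbeta(n, spec$invasive_fraction_dist[1L],
                                      spec$invasive_fraction_dist[2L])
    cohort$ICP <- cohort$carcinomaP * cohort$invasive_fraction
    cohort$TILP <- 10000 * rbeta(n, 0.5, 0.5 * (10000 / 17.4 - 1)) # mean ~17

    lp <- linear_predictor(cohort, spec$beta)
    cohort$engrafted <- rbinom(n, 1L, plogis(lp))
    attr(cohort, "truth") <- list(beta = spec$beta, spec = spec)
    cohort
  })
}

#' Expand printed outcome-by-category counts into patient-level records
#'
#' Turns a contingency table of the kind printed in published cohort tables
#' (one row per category, failure and success counts) into one record per
#' counted patient, so that record-level methods (logistic regression, group
#' comparisons) can run on printed numbers alone.
#'
#' @param counts A `data.frame` with a `failure` and a `success` column of
#'   non-negative integer counts; every other column is treated as a
#'   categorical covariate and carried onto the expanded records as a factor
#'   whose level order follows the row order (first row = reference level).
#' @param outcome Name of the binary outcome column on the output
#'   (1 = success).
#' @return A `data.frame` with `sum(failure) + sum(success)` rows.
#' @examples
#' counts <- data.frame(subtype = c("HER2+", "HR+", "HR+/HER2+", "TNBC"),
#'                      failure = c(20, 130, 30, 90),
#'                      success = c(1, 4, 1, 44))
#' records <- expand_counts(counts)
#' nrow(records); sum(records$engrafted)
#' @export
expand_counts <- function(counts, outcome = "engrafted") {
  stopifnot(is.data.frame(counts))
  if (!all(c("failure", "success") %in% names(counts))) {
    stop("`counts` needs `failure` and `success` columns", call. = FALSE)
  }
  fc <- counts$failure; sc <- counts$success
  if (any(fc < 0) || any(sc < 0) ||
      any(fc != round(fc)) || any(sc != round(sc))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  covars <- setdiff(names(counts), c("failure", "success"))
  reps <- rep(seq_len(nrow(counts)), times = fc + sc)
  out <- counts[reps, covars, drop = FALSE]
  for (v in covars) {
    if (!is.numeric(counts[[v]])) {
      out[[v]] <- factor(out[[v]], levels = unique(as.character(counts[[v]])))
    }
  }
  y <- integer(0)
  for (i in seq_len(nrow(counts))) {
    y <- c(y, rep(0L, fc[i]), rep(1L, sc[i]))
  }
  out[[outcome]] <- y
  rownames(out) <- NULL
  out
}
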