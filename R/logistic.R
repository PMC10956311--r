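# Logistic regression by iteratively reweighted least squares, with Wald
# inference on the odds-ratio scale. Authored here (rather than wrapping
# glm) because the model chain built on top of it -- univariate screening,
# backward-AIC elimination, fixed-term bootstrap refits -- needs full control
# of term expansion, convergence and separation flags; glm serves as an
# independent cross-check in the test suite only.

#' Fit a logistic regression model by IRLS
#'
#' Maximum-likelihood logistic regression with an intercept. Categorical
#' terms are expanded against a reference level (the first factor level, or
#' the first value seen; overridable via `ref`), one coefficient per
#' non-reference level, named `"term=level"`. Iteration stops when the
#' largest coefficient change falls below `tol` (default 1e-8) or after
#' `max_iter` iterations. Standard errors come from the observed information
#' at the optimum; Wald 95% confidence intervals are
#' `exp(beta +/- z[0.975] se)` with the exact normal quantile (1.959964...),
#' which is what reproduces published interval endpoints at their printed
#' precision.
#'
#' Aliased (linearly dependent) columns are dropped with a warning before
#' fitting. Fits whose coefficients diverge (complete or quasi-complete
#' separation) are returned with `separable = TRUE` and a warning rather
#' than an error, matching how enormous Wald intervals are reported rather
#' than suppressed in applied work.
#'
#' @param data A `data.frame`.
#' @param outcome Name of the binary outcome column (0/1 or logical).
#' @param terms Character vector of predictor columns.
#' @param ref Optional named list of reference levels for categorical terms,
#'   e.g. `list(subtype = "HER2+")`.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `max |delta beta|`.
#' @return An object of class `logistic_fit`: coefficients, `se`, odds
#'   ratios `or` with `ci_low`/`ci_high`, Wald `p_value`, `loglik`,
#'   `aic` (= -2 loglik + 2k), `n`, `k`, `converged`, `separable`,
#'   `term_map` (term -> coefficient names) and the design `info` needed to
#'   score new data.
#' @examples
#' counts <- data.frame(hg = c("2", "3"), failure = c(139, 131),
#'                      success = c(3, 47))
#' fit <- fit_logistic(expand_counts(counts), "engrafted", "hg")
#' round(fit$or["hg=3"], 2)  # 16.62
#' @export
fit_logistic <- function(data, outcome, terms, ref = NULL,
                         max_iter = 50L, tol = 1e-8) {
  stopifnot(is.data.frame(data))
  terms <- as.character(terms)  # length 0 gives the intercept-only model
  y <- as_outcome01(data[[outcome]], outcome)
  if (length(unique(y)) < 2L) {
    stop("outcome has a single class; logistic fit is undefined", call. = FALSE)
  }
  info <- design_info(data, terms, ref)
  X <- build_design(data, info)
  term_map <- attr(X, "term_map")

  # drop aliased columns (keeps the fit identifiable for stepwise starts)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("dropping aliased column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
    term_map <- lapply(term_map, function(cn) intersect(cn, colnames(X)))
    term_map <- term_map[vapply(term_map, length, integer(1L)) > 0L]
  }
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than parameters", call. = FALSE)
  }

  beta <- rep(0, ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr(X * sw)
    beta_new <- qr.coef(fit, z * sw)
    if (anyNA(beta_new)) beta_new[is.na(beta_new)] <- beta[is.na(beta_new)]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  separable <- max(abs(beta)) > 15
  if (separable) {
    warning("coefficients very large; possible (quasi-)separation -- ",
            "Wald inference unreliable for the flagged fit", call. = FALSE)
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  infmat <- crossprod(X * sqrt(w))
  vcov <- tryCatch(solve(infmat), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vcov))
  names(beta) <- names(se) <- colnames(X)
  zval <- beta / se
  loglik <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  k <- ncol(X)
  zq <- qnorm(0.975)
  structure(
    list(coefficients = beta, se = se, vcov = vcov,
         or = exp(beta), ci_low = exp(beta - zq * se),
         ci_high = exp(beta + zq * se),
         p_value = 2 * pnorm(-abs(zval)),
         loglik = loglik, aic = -2 * loglik + 2 * k,
         n = nrow(X), k = k, converged = converged, separable = separable,
         terms = terms, term_map = term_map, info = info, outcome = outcome),
    class = "logistic_fit"
  )
}

#' Predicted success probabilities from a logistic fit
#'
#' @param fit A `logistic_fit`.
#' @param newdata A `data.frame` holding the fit's terms (levels must match
#'   the design the model was fitted on).
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(fit, newdata) {
  stopifnot(inherits(fit, "logistic_fit"))
  X <- build_design(newdata, fit$info)
  X <- X[, names(fit$coefficients), drop = FALSE]
  plogis(drop(X %*% fit$coefficients))
}

#' Odds ratio for a delta-unit change of a term
#'
#' Rescales a fitted coefficient to a stated unit change: odds ratio
#' `exp(beta * delta)` with Wald interval
#' `exp((beta +/- z[0.975] se) * delta)`. Used to report proportion effects
#' per 1,000 units of the x10,000 scale.
#'
#' @param fit A `logistic_fit`.
#' @param term A coefficient name of `fit`.
#' @param delta Unit change (e.g. 1000).
#' @return Named list `or`, `ci_low`, `ci_high`, `delta`.
#' @export
scaled_odds_ratio <- function(fit, term, delta = 1) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!term %in% names(fit$coefficients)) {
    stop(sprintf("unknown term `%s`", term), call. = FALSE)
  }
  b <- fit$coefficients[[term]]; s <- fit$se[[term]]
  zq <- qnorm(0.975)
  list(or = exp(b * delta),
       ci_low = exp((b - zq * s) * delta),
       ci_high = exp((b + zq * s) * delta),
       delta = delta)
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Logistic fit (IRLS): n = %d, k = %d, logLik = %.3f, AIC = %.3f\n",
              x$n, x$k, x$loglik, x$aic))
  if (!x$converged) cat("  ! not converged\n")
  if (x$separable) cat("  ! flagged: possible separation\n")
  tab <- data.frame(beta = x$coefficients, se = x$se, OR = x$or,
                    ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value)
  print(round(tab, digits))
  invisible(x)
}

#' Univariate logistic screen over candidate predictors
#'
#' Fits one single-predictor logistic model per variable and collects the
#' Wald results; variables whose smallest term p-value is below
#' `p_threshold` (default 0.2) form the candidate set for the multivariate
#' step. Per-variable failures (e.g. separation errors) are recorded in the
#' table, not raised.
#'
#' @param data,outcome,ref As in [fit_logistic()].
#' @param variables Character vector of predictors to screen.
#' @param p_threshold Candidacy threshold on the Wald p-value.
#' @return List with `fits` (named list of `logistic_fit` or `NULL`),
#'   `table` (variable, min p, candidate flag, error note) and `candidates`
#'   (character vector).
#' @export
univariate_screen <- function(data, outcome, variables, p_threshold = 0.2,
                              ref = NULL) {
  stopifnot(length(variables) >= 1L)
  fits <- list(); note <- character(length(variables))
  pmin_ <- rep(NA_real_, length(variables))
  for (i in seq_along(variables)) {
    v <- variables[i]
    f <- tryCatch(fit_logistic(data, outcome, v, ref = ref),
                  error = function(e) e)
    if (inherits(f, "error")) {
      fits[v] <- list(NULL)
      note[i] <- conditionMessage(f)
    } else {
      fits[[v]] <- f
      pmin_[i] <- min(f$p_value[names(f$p_value) != "(Intercept)"])
    }
  }
  tab <- data.frame(variable = variables, p = pmin_,
                    candidate = !is.na(pmin_) & pmin_ < p_threshold,
                    note = note)
  list(fits = fits, table = tab, candidates = variables[tab$candidate])
}

#' Backward stepwise elimination by AIC
#'
#' Starting from the model holding every candidate term, repeatedly refits
#' all single-term deletions and removes the term whose deletion lowers AIC
#' the most; stops when no deletion lowers AIC. Ties in AIC improvement are
#' broken by removing the term with the larger Wald p-value in the current
#' fit (a multi-level term is judged by the smallest p among its
#' coefficients). Pure backward search: removed terms are never
#' reconsidered.
#'
#' @param data,outcome,ref As in [fit_logistic()].
#' @param candidates Character vector of starting terms.
#' @return List with `fit` (the final `logistic_fit`), `kept` (terms
#'   retained) and `trace` (a `data.frame` of the elimination path; AIC is
#'   non-increasing down the rows).
#' @examples
#' coh <- generate_cohort(cohort_gen_spec(n = 500, seed = 4))
#' sel <- stepwise_backward_aic(coh, "engrafted", c("ki67", "age", "til_pct"))
#' sel$trace
#' @export
stepwise_backward_aic <- function(data, outcome, candidates, ref = NULL) {
  stopifnot(length(candidates) >= 1L)
  current <- candidates
  fit <- fit_logistic(data, outcome, current, ref = ref)
  trace <- data.frame(step = 0L, removed = "<start>", aic = fit$aic)
  step <- 0L
  repeat {
    if (length(current) == 0L) break
    aics <- vapply(current, function(tm) {
      fit_logistic(data, outcome, setdiff(current, tm), ref = ref)$aic
    }, numeric(1L))
    best <- min(aics)
    if (best >= fit$aic - 1e-12) break
    cand <- current[aics <= best + 1e-9]
    if (length(cand) > 1L) {
      termp <- vapply(cand, function(tm) {
        min(fit$p_value[fit$term_map[[tm]]])
      }, numeric(1L))
      drop_tm <- cand[which.max(termp)]
    } else {
      drop_tm <- cand
    }
    current <- setdiff(current, drop_tm)
    fit <- fit_logistic(data, outcome, current, ref = ref)
    step <- step + 1L
    trace <- rbind(trace, data.frame(step = step, removed = drop_tm,
                                     aic = fit$aic))
  }
  list(fit = fit, kept = current, trace = trace)
}
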