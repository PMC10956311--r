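# ROC/AUC, BCa bootstrap confidence intervals, Youden cutoff and predictive
# values.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that
#' a random success scores above a random failure, ties counting 1/2. Equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric risk scores (higher = more success-like).
#' @param labels Binary outcome (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  y <- as_outcome01(labels, "labels")
  if (length(scores) != length(y)) stop("length mismatch", call. = FALSE)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) {
    stop("both outcome classes must be present to compute an AUC",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return `data.frame` with `threshold` (score >= threshold called
#'   positive), `fpr`, `tpr`, from (1, 1) down to (0, 0).
#' @export
roc_points <- function(scores, labels) {
  y <- as_outcome01(labels, "labels")
  u <- sort(unique(scores))
  thr <- c(-Inf, u, Inf)
  n1 <- sum(y); n0 <- length(y) - n1
  tpr <- vapply(thr, function(t) sum(y == 1L & scores >= t) / n1, numeric(1L))
  fpr <- vapply(thr, function(t) sum(y == 0L & scores >= t) / n0, numeric(1L))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' BCa confidence interval from bootstrap replicates
#'
#' Bias-corrected and accelerated interval: the bias correction `z0` is the
#' normal quantile of the fraction of replicates below the original
#' estimate, the acceleration `a` is the jackknife skewness
#' `sum(d^3) / (6 sum(d^2)^1.5)` with `d = mean(jack) - jack`, and the
#' endpoints are order statistics of the replicate vector at the adjusted
#' probabilities. With `z0 = 0` and `a = 0` the interval equals the
#' percentile interval exactly. A degenerate replicate vector (all equal)
#' yields a zero-width interval at that value.
#'
#' @param original Original-sample estimate.
#' @param replicates Numeric vector of bootstrap estimates.
#' @param jackknife Leave-one-out estimates on the original sample (used for
#'   the acceleration; `NULL` sets `a = 0`).
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
bca_interval <- function(original, replicates, jackknife = NULL,
                         level = 0.95) {
  B <- length(replicates)
  stopifnot(B >= 2L, level > 0, level < 1)
  if (max(replicates) - min(replicates) == 0) {
    return(c(replicates[1L], replicates[1L]))
  }
  frac <- mean(replicates < original)
  frac <- min(max(frac, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(frac)
  a <- 0
  if (!is.null(jackknife)) jackknife <- jackknife[!is.na(jackknife)]
  if (!is.null(jackknife) && length(jackknife) > 1L) {
    d <- mean(jackknife) - jackknife
    s2 <- sum(d^2)
    if (s2 > 0) a <- sum(d^3) / (6 * s2^1.5)
  }
  alpha <- (1 - level) / 2
  z <- qnorm(c(alpha, 1 - alpha))
  padj <- if (z0 == 0 && a == 0) {
    c(alpha, 1 - alpha)  # exact percentile probabilities, no qnorm round trip
  } else {
    pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  }
  # inverse-ECDF order statistics, with a fuzz absorbing float error in padj
  k <- pmin(pmax(ceiling(B * padj - 1e-9), 1L), B)
  sort(replicates)[k]
}

finish_bootstrap <- function(original, reps, jack, level, B, seed, redrawn) {
  ci <- bca_interval(original, reps, jack, level)
  structure(
    list(original_auc = original, replicates = reps,
         bias = mean(reps) - original, se = sd(reps),
         bca_low = ci[1L], bca_high = ci[2L], level = level,
         B = B, seed = seed, n_redrawn = redrawn),
    class = "bootstrap_result"
  )
}

#' Bootstrap distribution of the AUC of a fixed score
#'
#' Resamples (score, label) pairs with replacement (unstratified) `B` times
#' and recomputes the AUC of the fixed scoring function on each replicate;
#' replicates whose outcome is single-class are redrawn (and counted). The
#' BCa interval uses the leave-one-out jackknife on the original sample for
#' the acceleration.
#'
#' @inheritParams roc_auc
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return An object of class `bootstrap_result`: `original_auc`,
#'   `replicates`, `bias` (= mean(replicates) - original), `se`
#'   (= sd(replicates)), `bca_low`, `bca_high`, `B`, `seed`, `n_redrawn`.
#' @export
bootstrap_auc <- function(scores, labels, B = 1000L, seed = NULL,
                          level = 0.95) {
  y <- as_outcome01(labels, "labels")
  n <- length(y)
  original <- roc_auc(scores, y)
  with_seed(seed, {
    reps <- numeric(B)
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        s <- sum(y[idx])
        if (s > 0L && s < n) break
        redrawn <- redrawn + 1L
        if (redrawn > 10000L) stop("too many degenerate replicates", call. = FALSE)
      }
      reps[b] <- roc_auc(scores[idx], y[idx])
    }
    jack <- vapply(seq_len(n), function(i) {
      # a leave-one-out subset can lose a class entirely at tiny n
      tryCatch(roc_auc(scores[-i], y[-i]), error = function(e) NA_real_)
    }, numeric(1L))
    finish_bootstrap(original, reps, jack, level, B, seed, redrawn)
  })
}

#' Bootstrap the apparent AUC of a logistic model with fixed terms
#'
#' Each replicate resamples patient rows with replacement, refits the fixed
#' term set (no re-screening, no re-selection) on the replicate and scores
#' the replicate itself (apparent AUC). The original AUC is the apparent AUC
#' on the full sample, so `bias = mean(replicates) - original` estimates the
#' resampling optimism of the apparent AUC. The acceleration comes from a
#' leave-one-out jackknife (refit + apparent AUC on n-1 rows).
#'
#' With `optimism = TRUE`, each replicate's model is additionally scored on
#' the original sample, and the Harrell-style optimism
#' `mean(apparent AUC on replicate - replicate model's AUC on the original)`
#' and the corrected AUC `original - optimism` are attached. Off by default:
#' the default report mirrors the apparent-AUC-on-replicate convention.
#'
#' @param data,outcome,ref As in [fit_logistic()].
#' @param terms Fixed model terms.
#' @param B,seed,level As in [bootstrap_auc()].
#' @param optimism Also compute the optimism-corrected AUC (default `FALSE`).
#' @return A `bootstrap_result` with the base `fit` attached (plus
#'   `optimism` and `auc_corrected` when requested).
#' @export
bootstrap_model_auc <- function(data, outcome, terms, B = 1000L,
                                seed = NULL, level = 0.95, ref = NULL,
                                optimism = FALSE) {
  fit <- fit_logistic(data, outcome, terms, ref = ref)
  y <- as_outcome01(data[[outcome]], outcome)
  n <- nrow(data)
  original <- roc_auc(predict_prob(fit, data), y)
  res <- with_seed(seed, {
    reps <- numeric(B)
    opt <- if (optimism) numeric(B) else NULL
    redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        s <- sum(y[idx])
        if (s > 0L && s < n) break
        redrawn <- redrawn + 1L
        if (redrawn > 10000L) stop("too many degenerate replicates", call. = FALSE)
      }
      d <- data[idx, , drop = FALSE]
      f <- suppressWarnings(fit_logistic(d, outcome, terms, ref = ref))
      reps[b] <- roc_auc(predict_prob(f, d), y[idx])
      if (optimism) {
        opt[b] <- reps[b] - roc_auc(predict_prob(f, data), y)
      }
    }
    jack <- vapply(seq_len(n), function(i) {
      tryCatch({
        d <- data[-i, , drop = FALSE]
        f <- suppressWarnings(fit_logistic(d, outcome, terms, ref = ref))
        roc_auc(predict_prob(f, d), y[-i])
      }, error = function(e) NA_real_)
    }, numeric(1L))
    out <- finish_bootstrap(original, reps, jack, level, B, seed, redrawn)
    if (optimism) {
      out$optimism <- mean(opt)
      out$auc_corrected <- original - mean(opt)
    }
    out
  })
  res$fit <- fit
  res
}

#' Optimal classification cutoff by Youden's J
#'
#' Scans every candidate cutoff -- midpoints between adjacent sorted unique
#' scores, plus -Inf and +Inf -- calling a case positive when
#' `score >= cutoff`, and returns the cutoff maximising
#' `J = sensitivity + specificity - 1`; ties are broken towards the smallest
#' cutoff. PPV and NPV at the chosen cutoff are included.
#'
#' @inheritParams roc_auc
#' @return An object of class `cutoff_metrics`: `cutoff`, `sensitivity`,
#'   `specificity`, `youden_j`, `ppv`, `npv` (with `ppv_defined`,
#'   `npv_defined` flags).
#' @export
youden_cutoff <- function(scores, labels) {
  y <- as_outcome01(labels, "labels")
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2, Inf)
  j <- vapply(cand, function(t) {
    sum(y == 1L & scores >= t) / n1 + sum(y == 0L & scores < t) / n0 - 1
  }, numeric(1L))
  best <- cand[which.max(j)]  # which.max keeps the first (smallest) maximiser
  ppv_npv(scores, y, best)
}

#' Sensitivity, specificity, PPV and NPV at a cutoff
#'
#' Calls a case positive when `score >= cutoff`. Empty denominators (no
#' positive or no negative calls) are reported as `NA` with the
#' corresponding `*_defined` flag set to `FALSE`, never silently as 0.
#'
#' @inheritParams roc_auc
#' @param cutoff Classification threshold (finite or +/-Inf).
#' @return An object of class `cutoff_metrics`.
#' @export
ppv_npv <- function(scores, labels, cutoff) {
  y <- as_outcome01(labels, "labels")
  pos <- scores >= cutoff
  tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
  tn <- sum(!pos & y == 0L); fn <- sum(!pos & y == 1L)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  structure(
    list(cutoff = cutoff,
         sensitivity = sens, specificity = spec,
         youden_j = sens + spec - 1,
         ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0L) tn / (tn + fn) else NA_real_,
         ppv_defined = (tp + fp) > 0L,
         npv_defined = (tn + fn) > 0L,
         counts = c(tp = tp, fp = fp, tn = tn, fn = fn)),
    class = "cutoff_metrics"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap AUC (B = %d): original %.4f, bias %.4f, se %.4f\n",
              x$B, x$original_auc, x$bias, x$se))
  cat(sprintf("  %.0f%% BCa interval: [%.4f, %.4f]", 100 * x$level,
              x$bca_low, x$bca_high))
  if (x$n_redrawn > 0L) cat(sprintf("  (%d degenerate replicate draws redrawn)",
                                    x$n_redrawn))
  cat("\n")
  invisible(x)
}

#' @export
print.cutoff_metrics <- function(x, ...) {
  cat(sprintf(paste0("Cutoff %.4g: sensitivity %.3f, specificity %.3f, ",
                     "J %.3f, PPV %s, NPV %s\n"),
              x$cutoff, x$sensitivity, x$specificity, x$youden_j,
              ifelse(x$ppv_defined, sprintf("%.3f", x$ppv), "undefined"),
              ifelse(x$npv_defined, sprintf("%.3f", x$npv), "undefined")))
  invisible(x)
}
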