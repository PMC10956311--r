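# Design-matrix construction shared by the logistic module and the cohort
# generator. Categorical terms expand to one indicator per non-reference
# level, named "term=level"; the reference is the first factor level (or
# first value seen), overridable per term.

design_info <- function(data, terms, ref = NULL) {
  info <- list()
  for (v in terms) {
    x <- data[[v]]
    if (is.null(x)) stop(sprintf("term `%s` not found in data", v), call. = FALSE)
    if (is.numeric(x) || is.logical(x)) {
      info[[v]] <- list(type = "numeric")
    } else {
      lev <- if (is.factor(x)) levels(x) else unique(as.character(x))
      if (length(lev) < 2L) {
        stop(sprintf("categorical term `%s` has a single level", v),
             call. = FALSE)
      }
      r <- ref[[v]]
      if (!is.null(r)) {
        if (!r %in% lev) {
          stop(sprintf("reference level `%s` not a level of `%s`", r, v),
               call. = FALSE)
        }
        lev <- c(r, setdiff(lev, r))
      }
      info[[v]] <- list(type = "factor", levels = lev)
    }
  }
  info
}

build_design <- function(data, info, intercept = TRUE) {
  n <- nrow(data)
  cols <- list()
  term_map <- list()
  if (intercept) {
    cols[["(Intercept)"]] <- rep(1, n)
    term_map[["(Intercept)"]] <- "(Intercept)"
  }
  for (v in names(info)) {
    inf <- info[[v]]
    if (inf$type == "numeric") {
      x <- data[[v]]
      if (is.logical(x)) x <- as.numeric(x)
      if (anyNA(x)) stop(sprintf("term `%s` contains missing values", v),
                         call. = FALSE)
      cols[[v]] <- as.numeric(x)
      term_map[[v]] <- v
    } else {
      x <- as.character(data[[v]])
      if (anyNA(x)) stop(sprintf("term `%s` contains missing values", v),
                         call. = FALSE)
      unseen <- setdiff(unique(x), inf$levels)
      if (length(unseen)) {
        stop(sprintf("term `%s` has level(s) not in the design: %s", v,
                     paste(unseen, collapse = ", ")), call. = FALSE)
      }
      nm <- character(0)
      for (lev in inf$levels[-1L]) {
        cn <- paste0(v, "=", lev)
        cols[[cn]] <- as.numeric(x == lev)
        nm <- c(nm, cn)
      }
      term_map[[v]] <- nm
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  attr(X, "term_map") <- term_map
  X
}

# Linear predictor from a named coefficient vector whose names follow the
# build_design() convention ("(Intercept)", "age", "subtype=TNBC", ...).
linear_predictor <- function(data, beta) {
  if (is.list(beta)) beta <- unlist(beta)
  if (is.null(names(beta)) || any(names(beta) == "")) {
    stop("`beta` must be fully named", call. = FALSE)
  }
  if (any(!is.finite(beta))) stop("`beta` must be finite", call. = FALSE)
  lp <- rep(0, nrow(data))
  for (nm in names(beta)) {
    if (nm == "(Intercept)") {
      lp <- lp + beta[[nm]]
    } else if (grepl("=", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "=", fixed = TRUE)[[1L]]
      v <- parts[1L]; lev <- paste(parts[-1L], collapse = "=")
      x <- data[[v]]
      if (is.null(x)) stop(sprintf("beta term `%s`: column `%s` missing", nm, v),
                           call. = FALSE)
      lp <- lp + beta[[nm]] * (as.character(x) == lev)
    } else {
      x <- data[[nm]]
      if (is.null(x)) stop(sprintf("beta term `%s` missing from data", nm),
                           call. = FALSE)
      lp <- lp + beta[[nm]] * as.numeric(x)
    }
  }
  lp
}
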