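# Classification tree (CART): greedy binary Gini splits, cost-complexity
# (weakest-link) pruning with a printcp-style CP table, 10-fold
# cross-validated error, and primary-split variable importance. Authored
# in-package; rpart (grown surrogate-free) is used only as an independent
# cross-check in the tests. Unlike rpart, importance here counts primary
# splits only -- there are no surrogate splits at all -- so importances can
# differ from rpart's surrogate-inclusive numbers by design.

count_gini <- function(n1, n) {
  # count-weighted Gini impurity: n * (1 - p1^2 - p0^2) = 2 n1 n0 / n
  ifelse(n > 0, 2 * n1 * (n - n1) / n, 0)
}

# Best single split of the cases in `idx`, searched over all variables and
# all admissible cutpoints. Continuous cutpoints are midpoints between
# adjacent distinct sorted values; categorical splits use the
# outcome-rate-ordering reduction (optimal for binary Gini). Ties between
# variables keep the first variable in `vars` order; ties within a variable
# keep the smallest cutpoint / left-set.
best_split <- function(data, y, idx, vars, minbucket) {
  n <- length(idx); n1 <- sum(y[idx])
  parent_imp <- count_gini(n1, n)
  best <- NULL
  best_dec <- 1e-9
  for (v in vars) {
    x <- data[[v]][idx]
    yy <- y[idx]
    if (is.numeric(x)) {
      o <- order(x)
      xs <- x[o]; ys <- yy[o]
      i <- seq_len(n - 1L)
      ok <- (xs[i] < xs[i + 1L]) & (i >= minbucket) & ((n - i) >= minbucket)
      if (!any(ok)) next
      cum1 <- cumsum(ys)
      nL <- i[ok]; n1L <- cum1[i][ok]
      dec <- parent_imp - count_gini(n1L, nL) - count_gini(n1 - n1L, n - nL)
      j <- which.max(dec)
      if (dec[[j]] > best_dec) {
        best_dec <- dec[[j]]
        cut <- (xs[nL[j]] + xs[nL[j] + 1L]) / 2
        best <- list(var = v, type = "num", cut = cut, improve = best_dec)
      }
    } else {
      x <- as.character(x)
      levs <- unique(x)
      if (length(levs) < 2L) next
      nl <- vapply(levs, function(l) sum(x == l), numeric(1L))
      n1l <- vapply(levs, function(l) sum(yy[x == l]), numeric(1L))
      o <- order(n1l / nl, seq_along(levs))
      levs <- levs[o]; nl <- nl[o]; n1l <- n1l[o]
      cn <- cumsum(nl); c1 <- cumsum(n1l)
      i <- seq_len(length(levs) - 1L)
      ok <- (cn[i] >= minbucket) & ((n - cn[i]) >= minbucket)
      if (!any(ok)) next
      dec <- parent_imp - count_gini(c1[i], cn[i]) -
        count_gini(n1 - c1[i], n - cn[i])
      dec[!ok] <- -Inf
      j <- which.max(dec)
      if (dec[[j]] > best_dec) {
        best_dec <- dec[[j]]
        best <- list(var = v, type = "cat", left_levels = levs[seq_len(j)],
                     levels_seen = levs, improve = best_dec)
      }
    }
  }
  best
}

split_goes_left <- function(split, x) {
  if (split$type == "num") {
    x < split$cut
  } else {
    as.character(x) %in% split$left_levels
  }
}

grow_node <- function(data, y, idx, depth, params, vars) {
  n <- length(idx); n1 <- sum(y[idx])
  node <- list(n = n, n1 = n1, prob = n1 / n,
               pred = as.integer(2L * n1 > n),
               risk = min(n1, n - n1), depth = depth)
  can_split <- n >= params$minsplit && depth < params$maxdepth &&
    n1 > 0L && n1 < n
  if (can_split) {
    sp <- best_split(data, y, idx, vars, params$minbucket)
    if (!is.null(sp)) {
      left <- split_goes_left(sp, data[[sp$var]][idx])
      node$split <- sp
      node$left <- grow_node(data, y, idx[left], depth + 1L, params, vars)
      node$right <- grow_node(data, y, idx[!left], depth + 1L, params, vars)
    }
  }
  node
}

is_leaf <- function(node) is.null(node$split)

subtree_stats <- function(node) {
  if (is_leaf(node)) return(c(risk = node$risk, leaves = 1))
  subtree_stats(node$left) + subtree_stats(node$right)
}

n_splits <- function(node) {
  if (is_leaf(node)) 0L else 1L + n_splits(node$left) + n_splits(node$right)
}

# Smallest g = (R(t) - R(subtree)) / (leaves - 1) over internal nodes: the
# weakest link.
min_g <- function(node) {
  if (is_leaf(node)) return(Inf)
  st <- subtree_stats(node)
  g <- (node$risk - st[["risk"]]) / (st[["leaves"]] - 1)
  min(g, min_g(node$left), min_g(node$right))
}

collapse_leq <- function(node, thr) {
  if (is_leaf(node)) return(node)
  node$left <- collapse_leq(node$left, thr)
  node$right <- collapse_leq(node$right, thr)
  st <- subtree_stats(node)
  g <- (node$risk - st[["risk"]]) / (st[["leaves"]] - 1)
  if (g <= thr + 1e-12) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
  }
  node
}

# Optimally pruned subtree at penalty alpha (keeps branches whose g equals
# alpha exactly, so cp = 0 is a no-op on the grown tree).
prune_alpha <- function(node, alpha) {
  if (is_leaf(node)) return(node)
  node$left <- prune_alpha(node$left, alpha)
  node$right <- prune_alpha(node$right, alpha)
  st <- subtree_stats(node)
  g <- (node$risk - st[["risk"]]) / (st[["leaves"]] - 1)
  if (g < alpha - 1e-12) {
    node$split <- NULL; node$left <- NULL; node$right <- NULL
  }
  node
}

# Weakest-link pruning sequence. Returns one row per distinct subtree in the
# nested sequence: the (root-risk-scaled) CP at which it becomes optimal,
# its split count and its relative training error.
prune_sequence <- function(root, root_risk) {
  rows <- list()
  node <- root
  st <- subtree_stats(node)
  rows[[1L]] <- data.frame(CP = 0, nsplit = n_splits(node),
                           rel_error = st[["risk"]] / root_risk)
  while (!is_leaf(node)) {
    amin <- min_g(node)
    node <- collapse_leq(node, amin)
    st <- subtree_stats(node)
    rows[[length(rows) + 1L]] <- data.frame(
      CP = amin / root_risk, nsplit = n_splits(node),
      rel_error = st[["risk"]] / root_risk)
  }
  tab <- do.call(rbind, rows)
  # a zero-g collapse shares CP = 0 with the full tree: keep the smaller tree
  tab <- tab[!duplicated(tab$CP, fromLast = TRUE), , drop = FALSE]
  tab <- tab[order(tab$nsplit), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

route_case <- function(node, row) {
  while (!is_leaf(node)) {
    sp <- node$split
    x <- row[[sp$var]]
    if (sp$type == "cat" && !(as.character(x) %in% sp$levels_seen)) {
      # level unseen at this split in training: follow the larger child
      node <- if (node$left$n >= node$right$n) node$left else node$right
    } else if (split_goes_left(sp, x)) {
      node <- node$left
    } else {
      node <- node$right
    }
  }
  node
}

tree_importance <- function(node, acc = NULL) {
  acc <- acc %||% new.env()
  if (!is_leaf(node)) {
    v <- node$split$var
    acc[[v]] <- (acc[[v]] %||% 0) + node$split$improve
    tree_importance(node$left, acc)
    tree_importance(node$right, acc)
  }
  vals <- unlist(as.list(acc))
  if (is.null(vals) || !length(vals)) return(numeric(0))
  100 * sort(vals, decreasing = TRUE) / sum(vals)
}

#' Fit a classification tree (CART)
#'
#' Grows a binary classification tree for a 0/1 outcome by greedy Gini
#' splitting (continuous splits at midpoints of sorted distinct values;
#' categorical splits via the outcome-rate-ordering reduction, which is
#' optimal for binary Gini), subject to `minsplit`, `minbucket` and
#' `maxdepth` stopping rules. The full cost-complexity (weakest-link)
#' pruning sequence is computed on the misclassification risk and reported
#' as a printcp-style `cp_table` with `xval`-fold cross-validated error:
#' each fold's tree is pruned at the geometric means of adjacent CP values
#' of the main sequence, and `xerror`/`xstd` are the cross-validated risk
#' (scaled by the root risk) and its binomial-style standard error. Variable
#' importance is the per-variable sum of realised Gini decreases at primary
#' splits, normalised to percent.
#'
#' @param data A `data.frame`.
#' @param outcome Binary outcome column name.
#' @param variables Predictor columns (numeric or categorical).
#' @param minsplit Minimum node size eligible for splitting (default 20).
#' @param minbucket Minimum child size (default 7).
#' @param maxdepth Maximum depth (root = 0; default 30).
#' @param xval Cross-validation folds for `xerror` (default 10; 0 disables).
#' @param seed Seed for the fold assignment.
#' @return An object of class `pdx_tree`: `root` (recursive node list),
#'   `cp_table` (`CP`, `nsplit`, `rel_error`, `xerror`, `xstd`),
#'   `variable_importance` (percent, summing to 100 over used variables),
#'   `root_risk`, `n`, `params`.
#' @examples
#' coh <- generate_cohort(cohort_gen_spec(n = 400, seed = 9))
#' tr <- fit_cart(coh, "engrafted", c("ki67", "age", "subtype"), seed = 1)
#' tr$cp_table
#' @export
fit_cart <- function(data, outcome, variables,
                     minsplit = 20L, minbucket = 7L, maxdepth = 30L,
                     xval = 10L, seed = NULL) {
  stopifnot(is.data.frame(data), length(variables) >= 1L)
  y <- as_outcome01(data[[outcome]], outcome)
  params <- list(minsplit = minsplit, minbucket = minbucket,
                 maxdepth = maxdepth)
  n <- nrow(data)
  single_class <- length(unique(y)) < 2L
  if (single_class) {
    warning("outcome has a single class; returning a root stump", call. = FALSE)
  }
  root <- grow_node(data, y, seq_len(n), 0L, params, variables)
  root_risk <- max(root$risk, 1L)  # guard the all-one-class stump
  cp_tab <- prune_sequence(root, root_risk)
  cp_tab$xerror <- NA_real_
  cp_tab$xstd <- NA_real_
  if (xval > 1L && !single_class && !is_leaf(root)) {
    cv <- with_seed(seed, cv_error(data, y, variables, params, cp_tab, xval))
    cp_tab$xerror <- cv$xerror
    cp_tab$xstd <- cv$xstd
  }
  structure(
    list(root = root, cp_table = cp_tab,
         variable_importance = tree_importance(root),
         root_risk = root_risk, n = n, outcome = outcome,
         variables = variables, params = params),
    class = "pdx_tree"
  )
}

cv_error <- function(data, y, variables, params, cp_tab, xval) {
  n <- nrow(data)
  fold <- sample(rep(seq_len(xval), length.out = n))
  cps <- sort(cp_tab$CP, decreasing = TRUE)
  # evaluation penalties: geometric means of adjacent CPs; above the top CP
  # any penalty gives the root, below the bottom (0) the full tree
  betas <- c(max(2 * cps[1L], 1.5),
             if (length(cps) > 1L) sqrt(cps[-length(cps)] * cps[-1L]))
  loss <- matrix(NA_real_, n, length(betas))
  for (f in seq_len(xval)) {
    test <- which(fold == f)
    if (length(test) == 0L || length(test) == n) next
    train <- setdiff(seq_len(n), test)
    tr_root <- grow_node(data, y, train, 0L, params, variables)
    tr_risk <- max(min(sum(y[train]), length(train) - sum(y[train])), 1L)
    for (b in seq_along(betas)) {
      pruned <- prune_alpha(tr_root, betas[b] * tr_risk)
      for (i in test) {
        leaf <- route_case(pruned, data[i, , drop = FALSE])
        loss[i, b] <- as.numeric(leaf$pred != y[i])
      }
    }
  }
  root_risk <- max(min(sum(y), n - sum(y)), 1L)
  xerr <- colSums(loss, na.rm = TRUE) / root_risk
  xstd <- apply(loss, 2L, function(l) {
    l <- l[!is.na(l)]
    sqrt(sum((l - mean(l))^2)) / root_risk
  })
  # betas follow cp_tab row order (nsplit ascending = CP descending)
  list(xerror = xerr, xstd = xstd)
}

#' Prune a fitted tree at a complexity parameter
#'
#' Collapses, in weakest-link order, every branch whose root-risk-scaled
#' per-split improvement is strictly below `cp`; `cp = 0` is a no-op and a
#' `cp` above the strongest split's improvement leaves only the root.
#' CP-table rows with `CP < cp` are removed; the row describing the pruned
#' tree itself is kept with its CP re-labelled to the requested `cp`, and
#' variable importance is recomputed from the surviving splits.
#'
#' @param tree A `pdx_tree` from [fit_cart()].
#' @param cp Non-negative complexity parameter (may be `Inf`).
#' @return A pruned `pdx_tree`.
#' @export
prune_tree <- function(tree, cp) {
  stopifnot(inherits(tree, "pdx_tree"), cp >= 0)
  if (cp == 0) return(tree)
  root <- prune_alpha(tree$root, cp * tree$root_risk)
  ns <- n_splits(root)
  tab <- tree$cp_table
  out <- tab[tab$CP >= cp & tab$nsplit <= ns, , drop = FALSE]
  # the boundary row keeps the pruned tree's error but is re-labelled with
  # the requested cp (so the table stays monotone)
  if (!any(out$nsplit == ns)) {
    bound <- tab[tab$nsplit == ns, , drop = FALSE]
    if (nrow(bound) == 0L) {
      st <- subtree_stats(root)
      bound <- data.frame(CP = 0, nsplit = ns,
                          rel_error = st[["risk"]] / tree$root_risk,
                          xerror = NA_real_, xstd = NA_real_)
    }
    bound$CP <- cp
    out <- rbind(out, bound)
  }
  rownames(out) <- NULL
  tree$root <- root
  tree$cp_table <- out
  tree$variable_importance <- tree_importance(root)
  tree
}

#' Predict from a fitted tree
#'
#' @param tree A `pdx_tree`.
#' @param newdata A `data.frame` holding the tree's variables.
#' @param type `"prob"` (leaf success probability) or `"class"`.
#' @return Numeric (prob) or integer (class) vector.
#' @export
predict_tree <- function(tree, newdata, type = c("prob", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(tree, "pdx_tree"))
  out <- vapply(seq_len(nrow(newdata)), function(i) {
    leaf <- route_case(tree$root, newdata[i, , drop = FALSE])
    if (type == "prob") leaf$prob else as.numeric(leaf$pred)
  }, numeric(1L))
  if (type == "class") as.integer(out) else out
}

#' Training misclassification risk of a tree (count scale)
#'
#' @param tree A `pdx_tree`.
#' @return Sum of leaf misclassification counts.
#' @export
tree_risk <- function(tree) {
  stopifnot(inherits(tree, "pdx_tree"))
  unname(subtree_stats(tree$root)[["risk"]])
}

#' @export
print.pdx_tree <- function(x, ...) {
  cat(sprintf("Classification tree: n = %d, %d split(s), root risk %d\n",
              x$n, n_splits(x$root), x$root_risk))
  cat("CP table:\n")
  print(round(x$cp_table, 4))
  if (length(x$variable_importance)) {
    cat("Variable importance (%):\n")
    print(round(x$variable_importance, 1))
  }
  invisible(x)
}
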