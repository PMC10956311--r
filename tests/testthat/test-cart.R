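# CART: Gini splitting, pruning sequence, cross-validated error, importance.

# split count via the public cp table
n_splits_public <- function(tree) max(tree$cp_table$nsplit)

toy_cohort <- function(n = 300, seed = 31) {
  set.seed(seed)
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  g = sample(c("a", "b", "c"), n, replace = TRUE))
  d$y <- rbinom(n, 1, plogis(-0.5 + 1.5 * d$x1 + (d$g == "c")))
  d
}

test_that("a perfectly separating variable yields one split and zero error", {
  d <- data.frame(x = c(1:20), y = rep(c(0L, 1L), each = 10))
  tr <- fit_cart(d, "y", "x", xval = 0)
  expect_equal(max(tr$cp_table$nsplit), 1L)
  expect_equal(tr$root$split$var, "x")
  expect_equal(tree_risk(tr), 0)
  expect_equal(unname(tr$variable_importance["x"]), 100)
})

test_that("the root split matches exhaustive search on n = 20 fixtures", {
  # minbucket = 1 so the rate-ordering reduction for categorical splits is
  # provably equivalent to the exhaustive subset scan
  for (s in 1:10) {
    set.seed(400 + s)
    d <- data.frame(u = rnorm(20), v = round(rnorm(20), 1),
                    g = sample(c("p", "q", "r"), 20, replace = TRUE),
                    y = rbinom(20, 1, 0.5))
    if (length(unique(d$y)) < 2) next
    tr <- fit_cart(d, "y", c("u", "v", "g"), minsplit = 10, minbucket = 1,
                   xval = 0)
    want <- oracle_root_split(d, d$y, c("u", "v", "g"), minbucket = 1)
    if (is.null(tr$root$split)) {
      expect_lt(want$dec, 1e-8)
    } else {
      expect_equal(tr$root$split$improve, want$dec, tolerance = 1e-10,
                   label = paste("seed", 400 + s))
    }
  }
})

test_that("pruning sequence matches rpart grown surrogate-free", {
  # Same splits, same nested subtrees, same relative training errors. CP
  # values are compared only on the first fixture: for branches collapsing
  # several splits at once rpart reports a conservative grown-in complexity
  # rather than the exact weakest-link alpha (its prune() then disagrees
  # with the cost-complexity optimum, which this package computes exactly).
  for (s in c(21, 33)) {
    coh <- generate_cohort(cohort_gen_spec(n = 400, seed = s))
    vars <- c("ki67", "age", "size_cm", "subtype", "NP")
    tr <- fit_cart(coh, "engrafted", vars, xval = 0)
    rp <- rpart::rpart(
      factor(engrafted) ~ ki67 + age + size_cm + subtype + NP, coh,
      method = "class", cp = 0, xval = 0, minsplit = 20, minbucket = 7,
      maxsurrogate = 0, usesurrogate = 0, maxcompete = 0)
    rtab <- rp$cptable
    expect_equal(tr$cp_table$nsplit, unname(rtab[, "nsplit"]))
    expect_equal(tr$cp_table$rel_error, unname(rtab[, "rel error"]),
                 tolerance = 1e-10)
    expect_true(all(diff(tr$cp_table$CP) <= 1e-12))
    if (s == 21) {
      expect_equal(tr$cp_table$CP, unname(rtab[, "CP"]), tolerance = 1e-10)
    }
  }
})

test_that("pruning: cp = 0 is a no-op, huge cp leaves the root", {
  tr <- fit_cart(toy_cohort(), "y", c("x1", "x2", "g"), xval = 0, seed = 1)
  same <- prune_tree(tr, 0)
  expect_equal(n_splits_public(same), n_splits_public(tr))
  expect_equal(tree_risk(same), tree_risk(tr))
  root_only <- prune_tree(tr, Inf)
  expect_equal(n_splits_public(root_only), 0L)
  expect_equal(tree_risk(root_only), tr$root_risk)
  above_root <- prune_tree(tr, max(tr$cp_table$CP) + 0.01)
  expect_equal(n_splits_public(above_root), 0L)
})

test_that("rel_error is nonincreasing and pruning never improves training error", {
  tr <- fit_cart(toy_cohort(seed = 35), "y", c("x1", "x2", "g"), xval = 0)
  expect_true(all(diff(tr$cp_table$rel_error) <= 1e-12))
  for (cp in c(0.005, 0.02, 0.05, 0.2)) {
    expect_gte(tree_risk(prune_tree(tr, cp)), tree_risk(tr))
  }
})

test_that("pruned trees agree with the recomputed weakest-link sequence", {
  tr <- fit_cart(toy_cohort(seed = 36), "y", c("x1", "x2", "g"), xval = 0)
  tab <- tr$cp_table
  for (i in seq_len(nrow(tab))) {
    # any cp strictly inside this row's optimality interval selects this
    # tree (rows are ordered by nsplit, so CP decreases down the rows)
    hi <- if (i == 1L) tab$CP[1L] + 0.01 else (tab$CP[i] + tab$CP[i - 1L]) / 2
    sel <- prune_tree(tr, hi)
    expect_equal(max(sel$cp_table$nsplit), tab$nsplit[i])
    expect_equal(tail(sel$cp_table$rel_error, 1), tab$rel_error[i],
                 tolerance = 1e-12)
    # pruning in two stages equals pruning once (nestedness)
    two_step <- prune_tree(prune_tree(tr, tab$CP[i]), hi)
    expect_equal(max(two_step$cp_table$nsplit), max(sel$cp_table$nsplit))
  }
})

test_that("importance percentages sum to 100 over used variables", {
  tr <- fit_cart(toy_cohort(seed = 37), "y", c("x1", "x2", "g"), xval = 0)
  expect_equal(sum(tr$variable_importance), 100, tolerance = 0.1)
  expect_true(all(tr$variable_importance > 0))
})

test_that("cross-validated errors are populated and sane", {
  tr <- fit_cart(toy_cohort(seed = 38), "y", c("x1", "x2", "g"),
                 xval = 10, seed = 5)
  expect_false(anyNA(tr$cp_table$xerror))
  expect_true(all(tr$cp_table$xstd >= 0))
  # the root row cross-validates the majority-class rule: xerror ~ 1
  expect_lt(abs(tr$cp_table$xerror[1] - 1), 0.35)
  # fold assignment is seeded
  tr2 <- fit_cart(toy_cohort(seed = 38), "y", c("x1", "x2", "g"),
                  xval = 10, seed = 5)
  expect_equal(tr$cp_table$xerror, tr2$cp_table$xerror)
})

test_that("single-class outcomes give a stump with a warning", {
  d <- data.frame(x = rnorm(30), y = rep(0L, 30))
  expect_warning(tr <- fit_cart(d, "y", "x", xval = 0), "single class")
  expect_equal(max(tr$cp_table$nsplit), 0L)
})

test_that("tree predictions route unseen categorical levels to the larger child", {
  d <- toy_cohort(seed = 39)
  tr <- fit_cart(d, "y", c("g", "x1"), xval = 0)
  new <- d[1:4, ]
  new$g <- "zebra"
  expect_silent(p <- predict_tree(tr, new))
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict_tree(tr, d, type = "class")
  expect_true(all(cls %in% c(0L, 1L)))
  expect_equal(sum(cls != d$y), tree_risk(tr))
})
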