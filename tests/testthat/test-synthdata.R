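# Synthetic label maps and cohorts: determinism, composition control,
# marginal recovery, count expansion.

test_that("label maps are bit-identical under a fixed spec and seed", {
  spec <- synth_map_spec(shape = c(60, 60), seed = 7)
  m1 <- generate_label_map(spec)
  m2 <- generate_label_map(spec)
  expect_identical(m1$labels, m2$labels)
  expect_identical(m1$lymph_fraction, m2$lymph_fraction)
})

test_that("pure-carcinoma composition fills the grid, lymph follows its mean", {
  spec <- synth_map_spec(shape = c(40, 55), composition = c(CARCINOMA = 1),
                         mean_lymph_fraction = 0.1, seed = 3)
  map <- generate_label_map(spec)
  expect_true(all(map$labels == TISSUE_CODES[["CARCINOMA"]]))
  expect_equal(mean(map$lymph_fraction), 0.1, tolerance = 0.05)
})

test_that("intratumoral necrosis hits its target on a 200x200 grid", {
  spec <- synth_map_spec(
    shape = c(200, 200),
    composition = c(CARCINOMA = 0.55, NECROSIS = 0.15, STROMA = 0.20,
                    ADIPOSE = 0.05, TDLU = 0.05),
    tumor_mass = 0.3, seed = 42)
  map <- generate_label_map(spec)
  region <- delineate_tumor(map)
  inside <- map$labels[region$mask]
  frac <- mean(inside == TISSUE_CODES[["NECROSIS"]])
  expect_lt(abs(frac - 0.15), 0.05)
})

test_that("composition recovery tightens with map size", {
  comp <- c(CARCINOMA = 0.5, NECROSIS = 0.12, STROMA = 0.28, ADIPOSE = 0.10)
  map <- generate_label_map(synth_map_spec(shape = c(500, 500),
                                           composition = comp,
                                           tumor_mass = 0.3, seed = 5))
  region <- delineate_tumor(map)
  inside <- map$labels[region$mask]
  for (cl in names(comp)) {
    expect_lt(abs(mean(inside == TISSUE_CODES[[cl]]) - comp[[cl]]), 0.05)
  }
})

test_that("map specs validate composition, shape and tumour capacity", {
  expect_error(synth_map_spec(composition = c(CARCINOMA = 0.7, STROMA = 0.4)),
               "sum to 1")
  expect_error(synth_map_spec(composition = c(CARCINOMA = 0.5, LESION = 0.5)),
               "tissue classes")
  expect_error(synth_map_spec(shape = c(0, 10)), "positive")
  expect_error(synth_map_spec(tumor_mass = 0), "tumor_mass")
  # a 3x3 grid cannot hold a closed tumour mass plus its interior quota
  expect_error(
    generate_label_map(synth_map_spec(
      shape = c(3, 3),
      composition = c(CARCINOMA = 0.5, STROMA = 0.5), tumor_mass = 0.9,
      seed = 1)),
    "too small")
})

test_that("label map container enforces its invariants", {
  lab <- matrix(TISSUE_CODES[["STROMA"]], 4, 4)
  expect_error(tissue_label_map(lab, matrix(0, 3, 4)), "identical shape")
  expect_error(tissue_label_map(matrix(9L, 4, 4), matrix(0, 4, 4)), "codes")
  expect_error(tissue_label_map(lab, matrix(2, 4, 4)), "\\[0, 1\\]")
  bg <- matrix(TISSUE_CODES[["BACKGROUND"]], 4, 4)
  expect_error(tissue_label_map(bg, matrix(0.5, 4, 4)), "BACKGROUND")
})

test_that("null outcome model gives ~50% successes", {
  spec <- cohort_gen_spec(n = 2000, beta = c("(Intercept)" = 0), seed = 8)
  coh <- generate_cohort(spec)
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(coh$engrafted) - 0.5), 3 * se)
})

test_that("cohort covariate marginals converge to the spec at n = 5000", {
  spec <- cohort_gen_spec(n = 5000, seed = 10)
  coh <- generate_cohort(spec)
  p <- spec$covariate_params
  # age: truncation at 18/95 barely moves the first two moments
  expect_lt(abs(mean(coh$age) - p$age$mean), 3 * p$age$sd / sqrt(5000))
  expect_lt(abs(sd(coh$age) - p$age$sd), 0.6)
  expect_lt(abs(mean(coh$subtype == "TNBC") - p$subtype$prob[4]),
            3 * sqrt(0.42 * 0.58 / 5000))
  expect_true(all(coh$ki67 %in% seq(0, 90, 10)))
  expect_true(all(is.na(coh$miller_payne[coh$nac == "no"])))
  expect_true(all(!is.na(coh$miller_payne[coh$nac == "yes"])))
  # six patch proportions live on the x10,000 simplex by construction
  expect_equal(rowSums(coh[, c("AP", "BP", "NP", "TDLUP", "SP", "carcinomaP")]),
               rep(10000, 5000), tolerance = 1e-9)
  expect_true(all(coh$ICP <= coh$carcinomaP))
})

test_that("true Ki-67 slope is recovered inside its Wald CI ~95% of the time", {
  beta <- c("(Intercept)" = -2, ki67 = log(1.05))
  hits <- vapply(1:100, function(s) {
    coh <- generate_cohort(cohort_gen_spec(n = 1000, beta = beta, seed = 1000 + s))
    truth <- attr(coh, "truth")$beta[["ki67"]]
    fit <- fit_logistic(coh, "engrafted", "ki67")
    b <- fit$coefficients[["ki67"]]; se <- fit$se[["ki67"]]
    (truth >= b - 1.96 * se) && (truth <= b + 1.96 * se)
  }, logical(1L))
  expect_gte(mean(hits), 0.90)
})

test_that("degenerate cohort specs are rejected", {
  expect_error(cohort_gen_spec(n = 0), "positive")
  expect_error(cohort_gen_spec(n = 10, beta = c(a = Inf)), "finite")
  expect_error(cohort_gen_spec(n = 10, covariate_params = list(age = list(
    mean = 50, sd = -1, lower = 18, upper = 95))), "sd")
  expect_error(cohort_gen_spec(n = 10, invasive_fraction_dist = c(1, 0)),
               "Beta")
})

test_that("expand_counts reproduces the printed all-patients subtype table", {
  counts <- printed_counts()$subtype_all
  rec <- expand_counts(counts)
  expect_equal(nrow(rec), 320L)
  expect_equal(sum(rec$engrafted), 50L)
  expect_equal(levels(rec$subtype), c("HER2+", "HR+", "HR+/HER2+", "TNBC"))
  # round trip: re-tabulation gives back the input counts exactly
  retab <- table(rec$subtype, rec$engrafted)
  expect_equal(unname(retab[, "0"]), counts$failure)
  expect_equal(unname(retab[, "1"]), counts$success)
})

test_that("expand_counts handles edges: tiny, empty and invalid tables", {
  rec <- expand_counts(data.frame(g = "A", failure = 2L, success = 1L))
  expect_equal(nrow(rec), 3L)
  expect_equal(mean(rec$engrafted), 1 / 3)
  empty <- expand_counts(data.frame(g = character(0), failure = integer(0),
                                    success = integer(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(expand_counts(data.frame(g = "A", failure = -1L, success = 2L)),
               "non-negative")
})
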