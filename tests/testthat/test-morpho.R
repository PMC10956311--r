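# Tumour delineation and intratumoral proportions.

solid_block_map <- function() {
  lab <- matrix(TISSUE_CODES[["STROMA"]], 50, 50)
  lab[21:30, 21:30] <- TISSUE_CODES[["CARCINOMA"]]
  make_map(lab)
}

test_that("a solid carcinoma block is delineated exactly", {
  region <- delineate_tumor(solid_block_map())
  expect_equal(region$n_patches, 100L)
  want <- matrix(FALSE, 50, 50); want[21:30, 21:30] <- TRUE
  expect_identical(region$mask, want)
  expect_true(all(region$mask[region$boundary]))
})

test_that("a carcinoma ring is filled: the stroma core is inside the perimeter", {
  lab <- matrix(TISSUE_CODES[["ADIPOSE"]], 40, 40)
  lab[11:30, 11:30] <- TISSUE_CODES[["CARCINOMA"]]
  lab[16:25, 16:25] <- TISSUE_CODES[["STROMA"]]
  region <- delineate_tumor(make_map(lab))
  expect_equal(region$n_patches, 400L)
  expect_true(all(region$mask[16:25, 16:25]))
  # flood-fill oracle agrees cell for cell
  expect_identical(region$mask, oracle_delineate(lab))
})

test_that("maps without carcinoma raise the dedicated no-tumour condition", {
  lab <- matrix(TISSUE_CODES[["STROMA"]], 20, 20)
  expect_error(delineate_tumor(make_map(lab)), class = "pdx_no_tumor")
})

test_that("delineation matches the brute-force flood-fill oracle on random maps", {
  for (s in 1:100) {
    set.seed(s)
    lab <- matrix(sample(unname(TISSUE_CODES), 30 * 30, replace = TRUE,
                         prob = c(0.1, 0.1, 0.1, 0.4, 0.2, 0.1)), 30, 30)
    got <- delineate_tumor(make_map(lab))
    expect_identical(got$mask, oracle_delineate(lab), label = paste("seed", s))
  }
})

test_that("delineation is idempotent on its own output", {
  for (s in 1:5) {
    map <- generate_label_map(synth_map_spec(shape = c(80, 80), seed = s))
    region <- delineate_tumor(map)
    relab <- matrix(TISSUE_CODES[["STROMA"]], 80, 80)
    relab[region$mask] <- TISSUE_CODES[["CARCINOMA"]]
    region2 <- delineate_tumor(make_map(relab))
    expect_identical(region2$mask, region$mask)
  }
})

test_that("region size never shrinks as the closing radius grows", {
  for (s in 1:10) {
    set.seed(100 + s)
    lab <- matrix(sample(unname(TISSUE_CODES), 900, replace = TRUE,
                         prob = c(0.1, 0.1, 0.1, 0.35, 0.25, 0.1)), 30, 30)
    map <- make_map(lab)
    sizes <- vapply(0:3, function(r) delineate_tumor(map, close_radius = r)$n_patches,
                    integer(1L))
    expect_true(all(diff(sizes) >= 0))
  }
})

test_that("proportions match a hand count and scale by the invasive fraction", {
  lab <- matrix(TISSUE_CODES[["CARCINOMA"]], 10, 10)
  lab[1:2, ] <- TISSUE_CODES[["NECROSIS"]]   # 20 patches
  lab[3:5, ] <- TISSUE_CODES[["STROMA"]]     # 30 patches
  map <- make_map(lab)
  region <- structure(list(mask = matrix(TRUE, 10, 10), n_patches = 100L,
                           boundary = cbind(row = 1L, col = 1L)),
                      class = "tumor_region")
  prof <- compute_proportions(map, region, invasive_fraction = 0.8)
  expect_equal(prof$NP, 2000)
  expect_equal(prof$SP, 3000)
  expect_equal(prof$carcinomaP, 5000)
  expect_equal(prof$ICP, 4000)
  expect_equal(prof$AP + prof$BP + prof$NP + prof$TDLUP + prof$SP +
                 prof$carcinomaP, 10000, tolerance = 1e-6)
  # zero invasive fraction kills ICP regardless of carcinoma content
  expect_equal(compute_proportions(map, region, 0)$ICP, 0)
  expect_error(compute_proportions(map, region, 1.2), "\\[0, 1\\]")
})

test_that("pure tumour region gives carcinomaP = ICP = 10000 and others 0", {
  map <- make_map(matrix(TISSUE_CODES[["CARCINOMA"]], 8, 8))
  region <- delineate_tumor(map)
  prof <- compute_proportions(map, region, 1)
  expect_equal(prof$carcinomaP, 10000)
  expect_equal(prof$ICP, 10000)
  expect_equal(prof$AP + prof$BP + prof$NP + prof$TDLUP + prof$SP, 0)
})

test_that("TILP is 10,000 times the mean in-region lymphocyte fraction", {
  lab <- matrix(TISSUE_CODES[["CARCINOMA"]], 10, 10)
  lf <- matrix(0, 10, 10)
  lf[1:5, ] <- 0.5  # half the region at 0.5, half at 0
  map <- tissue_label_map(lab, lf)
  region <- delineate_tumor(map)
  expect_equal(compute_tilp(map, region), 2500)
  expect_equal(compute_tilp(tissue_label_map(lab, matrix(0, 10, 10)), region), 0)
  expect_equal(compute_tilp(tissue_label_map(lab, matrix(1, 10, 10)), region),
               10000)
})

test_that("tissue-only denominator excludes background patches", {
  lab <- matrix(TISSUE_CODES[["CARCINOMA"]], 10, 10)
  lab[1, 1:5] <- TISSUE_CODES[["BACKGROUND"]]
  map <- make_map(lab)
  region <- structure(list(mask = matrix(TRUE, 10, 10), n_patches = 100L,
                           boundary = cbind(row = 1L, col = 1L)),
                      class = "tumor_region")
  all_mode <- compute_proportions(map, region, 1)
  tissue_mode <- compute_proportions(map, region, 1, denominator = "tissue")
  expect_equal(all_mode$carcinomaP, 9500)
  expect_equal(tissue_mode$carcinomaP, 10000)
})

test_that("profile_cohort excludes no-tumour cases and reports them", {
  m1 <- solid_block_map()
  m2 <- make_map(matrix(TISSUE_CODES[["STROMA"]], 20, 20))  # no carcinoma
  m3 <- make_map(matrix(TISSUE_CODES[["CARCINOMA"]], 12, 12))
  res <- profile_cohort(list(a = m1, b = m2, c = m3),
                        invasive_fractions = c(0.5, 0.5, 1))
  expect_equal(nrow(res$profiles), 2L)
  expect_equal(res$excluded$case_id, "b")
  expect_equal(res$profiles$case_id, c("a", "c"))
  # determinism over identical maps
  res2 <- profile_cohort(list(x = m3, y = m3))
  expect_equal(res2$profiles$NP[1], res2$profiles$NP[2])
  expect_equal(res2$profiles$carcinomaP[1], res2$profiles$carcinomaP[2])
  expect_error(profile_cohort(list(a = m1, a = m3)), "duplicate")
})

test_that("profiled synthetic maps recover the generator's necrosis target", {
  specs <- lapply(1:3, function(s) synth_map_spec(
    shape = c(120, 120),
    composition = c(CARCINOMA = 0.6, NECROSIS = 0.15, STROMA = 0.2,
                    ADIPOSE = 0.05),
    seed = s))
  maps <- lapply(specs, generate_label_map)
  names(maps) <- paste0("case", 1:3)
  res <- profile_cohort(maps)
  expect_true(all(abs(res$profiles$NP - 1500) < 500))
})
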