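# File formats: cohort CSV with validation, label-map rasters with sidecar
# header, run configuration defaults.

#' Run configuration defaults
#'
#' Container for the analysis-chain knobs: the univariate candidacy
#' threshold (`screen_p`, default 0.2), the tree pruning complexity
#' parameter (`cp`, default 0.03), the bootstrap replicate count (`boot_B`,
#' default 1000), the delineation closing radius (default 2 patches), the
#' proportion denominator mode and the positive-call convention.
#'
#' @param seed Integer seed.
#' @param screen_p Univariate screening p-value threshold, in (0, 1].
#' @param cp Tree pruning complexity parameter, >= 0.
#' @param boot_B Bootstrap replicates, >= 1.
#' @param close_radius Closing radius in patches, >= 0.
#' @param denominator_mode `"all"` or `"tissue"` (see
#'   [compute_proportions()]).
#' @param positive_convention Only `">="` is implemented: scores at or above
#'   the cutoff are called positive.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L, screen_p = 0.2, cp = 0.03, boot_B = 1000L,
                       close_radius = 2L, denominator_mode = "all",
                       positive_convention = ">=") {
  stopifnot(screen_p > 0, screen_p <= 1, cp >= 0, boot_B >= 1,
            close_radius >= 0, denominator_mode %in% c("all", "tissue"),
            positive_convention == ">=")
  structure(list(seed = as.integer(seed), screen_p = screen_p, cp = cp,
                 boot_B = as.integer(boot_B),
                 close_radius = as.integer(close_radius),
                 denominator_mode = denominator_mode,
                 positive_convention = positive_convention),
            class = "run_config")
}

cohort_validators <- local({
  vl <- list(
    ki67 = function(x) ifelse(!is.na(x) & !(x %in% seq(0, 90, 10)),
                              "ki67 must lie on the 10-step grid 0,10,...,90",
                              NA),
    engrafted = function(x) ifelse(!is.na(x) & !(x %in% c(0, 1)),
                                   "engrafted must be 0 or 1", NA),
    invasive_fraction = function(x) ifelse(!is.na(x) & (x < 0 | x > 1),
                                           "invasive_fraction must be in [0, 1]",
                                           NA)
  )
  range_check <- function(vv) {
    force(vv)
    function(x) ifelse(!is.na(x) & (x < 0 | x > 10000),
                       paste0(vv, " must be in [0, 10000] (x10,000 scale)"), NA)
  }
  for (v in c("AP", "BP", "NP", "TDLUP", "SP", "ICP", "TILP", "carcinomaP")) {
    vl[[v]] <- range_check(v)
  }
  vl
})

#' Validate a cohort table
#'
#' Checks the typed column rules for whichever documented columns are
#' present: Ki-67 on the 10-step grid, the outcome binary, morphometric
#' proportions within [0, 10000] and the invasive fraction within [0, 1].
#' Unknown columns are preserved untouched.
#'
#' @param cohort A `data.frame`.
#' @return `cohort` invisibly; on failure an error whose `data` field lists
#'   row, column and reason for every violation.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  bad <- list()
  for (col in intersect(names(cohort_validators), names(cohort))) {
    reason <- cohort_validators[[col]](cohort[[col]])
    hit <- which(!is.na(reason))
    if (length(hit)) {
      bad[[length(bad) + 1L]] <- data.frame(row = hit, column = col,
                                            reason = reason[hit])
    }
  }
  if (length(bad)) {
    report <- do.call(rbind, bad)
    cond <- structure(
      class = c("pdx_validation_error", "error", "condition"),
      list(message = paste0("cohort validation failed (", nrow(report),
                            " violation(s)); first: row ", report$row[1L],
                            ", column ", report$column[1L], ": ",
                            report$reason[1L]),
           call = NULL, data = report))
    stop(cond)
  }
  invisible(cohort)
}

#' Read / write a cohort table (CSV)
#'
#' RFC 4180 CSV with a header row. Reading validates the typed columns (see
#' [validate_cohort()]); writing is plain `write.csv` without row names, so
#' a write-read round trip is the identity up to column classes.
#'
#' @param path CSV file path.
#' @param validate Validate on read (default `TRUE`).
#' @return `read_cohort`: a `data.frame`. `write_cohort`: `path`, invisibly.
#' @export
read_cohort <- function(path, validate = TRUE) {
  cohort <- read.csv(path, stringsAsFactors = FALSE)
  if (validate) validate_cohort(cohort)
  cohort
}

#' @param cohort A `data.frame`.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a tissue label map
#'
#' The label grid is stored as an 8-bit grayscale PNG (pixel value = tissue
#' code), the lymphocyte fraction grid as a 16-bit grayscale TIFF (value /
#' 65535 = fraction; a write-read round trip is exact to 1/65535), and a
#' YAML header records `patch_px`, the grid shape and optional provenance
#' (e.g. the generator seed). `name` selects the file stem inside `dir`.
#'
#' @param map A [tissue_label_map()].
#' @param dir Output directory (created if missing).
#' @param name File stem; produces `<name>_labels.png`, `<name>_lymph.tif`,
#'   `<name>.yaml`.
#' @param provenance Optional list stored verbatim in the header.
#' @return `write_label_map`: the header path, invisibly. `read_label_map`:
#'   a [tissue_label_map()].
#' @export
write_label_map <- function(map, dir, name = "map", provenance = NULL) {
  validate_label_map(map)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(map$labels / 255, file.path(dir, paste0(name, "_labels.png")))
  tiff::writeTIFF(round(map$lymph_fraction * 65535) / 65535,
                  file.path(dir, paste0(name, "_lymph.tif")),
                  bits.per.sample = 16L)
  header <- list(patch_px = map$patch_px,
                 shape = as.integer(dim(map$labels)),
                 labels = paste0(name, "_labels.png"),
                 lymph = paste0(name, "_lymph.tif"),
                 codes = as.list(TISSUE_CODES))
  if (!is.null(provenance)) header$provenance <- provenance
  hp <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(header, hp)
  invisible(hp)
}

#' @param header_path Path to the YAML header written by
#'   [write_label_map()].
#' @rdname write_label_map
#' @export
read_label_map <- function(header_path) {
  header <- yaml::read_yaml(header_path)
  dir <- dirname(header_path)
  labels <- round(png::readPNG(file.path(dir, header$labels)) * 255)
  storage.mode(labels) <- "integer"
  lymph <- tiff::readTIFF(file.path(dir, header$lymph))
  # background quantisation jitter would violate the zero-on-background rule
  lymph[labels == TISSUE_CODES[["BACKGROUND"]]] <- 0
  tissue_label_map(labels, lymph, patch_px = header$patch_px)
}
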