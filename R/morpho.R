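# Tumour delineation on label grids and intratumoral tissue proportions.

no_tumor_error <- function(msg = "label map contains no carcinoma patch") {
  structure(class = c("pdx_no_tumor", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Delineate the largest tumour region on a label map
#'
#' Reconstructs the tumour boundary drawn around the carcinoma component of
#' a patch-classified slide: the binary carcinoma mask is morphologically
#' closed with a square structuring element of the given radius (bridging
#' small gaps), holes are filled (so enclosed necrosis, stroma or other
#' intratumoral pockets count as inside the perimeter), and the largest
#' connected component is returned. Size ties are broken towards the
#' component whose lexicographically smallest (row, col) cell comes first.
#'
#' @param map A [tissue_label_map()].
#' @param close_radius Radius, in patches, of the square closing element
#'   (default 2, i.e. a 5x5 box). 0 disables closing.
#' @param connectivity Pixel connectivity for components: 8 (default) or 4.
#' @return An object of class `tumor_region`: a list with `mask` (logical
#'   matrix), `n_patches`, and `boundary` (two-column matrix of rim patch
#'   coordinates, ordered lexicographically by row then column).
#' @section Errors: signals a condition of class `pdx_no_tumor` when the map
#'   has no carcinoma patch.
#' @export
delineate_tumor <- function(map, close_radius = 2L, connectivity = 8L) {
  validate_label_map(map)
  stopifnot(close_radius >= 0L)
  carc <- map$labels == TISSUE_CODES[["CARCINOMA"]]
  if (!any(carc)) stop(no_tumor_error())
  mask <- fill_holes(close_box(carc, as.integer(close_radius)))
  lab <- label_components(mask, connectivity = as.integer(connectivity))
  ids <- sort(unique(lab[lab != 0L]))
  sizes <- tabulate(lab, max(ids))[ids]
  best <- ids[sizes == max(sizes)]
  if (length(best) > 1L) {
    # tie: component whose top-left cell (min row, then col) comes first
    key <- vapply(best, function(id) {
      cells <- which(lab == id)
      r <- ((cells - 1L) %% nrow(mask)) + 1L
      cc <- ((cells - 1L) %/% nrow(mask)) + 1L
      o <- order(r, cc)[1L]
      r[o] * (ncol(mask) + 1) + cc[o]
    }, numeric(1L))
    best <- best[which.min(key)]
  }
  region_mask <- lab == best
  rim <- region_mask & !erode_box(region_mask, 1L)
  cells <- which(rim)
  r <- ((cells - 1L) %% nrow(mask)) + 1L
  cc <- ((cells - 1L) %/% nrow(mask)) + 1L
  o <- order(r, cc)
  structure(
    list(mask = region_mask, n_patches = sum(region_mask),
         boundary = cbind(row = r[o], col = cc[o])),
    class = "tumor_region"
  )
}

#' Intratumoral morphometric proportions
#'
#' For each tissue class, the proportion of patches of that class among all
#' patches inside the tumour perimeter, multiplied by 10,000. The carcinoma
#' proportion is additionally corrected by the pathologist-assessed invasive
#' fraction to give ICP (invasive carcinoma proportion); the six raw class
#' proportions sum exactly to 10,000. TILP, the intratumoral lymphocyte area
#' fraction (x10,000), is filled in from [compute_tilp()].
#'
#' @param map A [tissue_label_map()].
#' @param region A `tumor_region` from [delineate_tumor()] on the same map.
#' @param invasive_fraction Scalar in [0, 1]: fraction of the carcinoma
#'   patches that is invasive (rather than in situ) carcinoma.
#' @param denominator `"all"` (default) counts every patch inside the
#'   perimeter, background included; `"tissue"` excludes background patches
#'   from the denominator (the x10,000 sum identity then applies to the five
#'   tissue classes plus carcinoma over the reduced denominator).
#' @return An object of class `morph_profile`: list with `AP`, `BP`, `NP`,
#'   `TDLUP`, `SP`, `carcinomaP`, `ICP`, `TILP`, `invasive_fraction`,
#'   `n_patches`.
#' @examples
#' map <- generate_label_map(synth_map_spec(shape = c(80, 80), seed = 3))
#' reg <- delineate_tumor(map)
#' compute_proportions(map, reg, invasive_fraction = 0.8)
#' @export
compute_proportions <- function(map, region, invasive_fraction,
                                denominator = c("all", "tissue")) {
  validate_label_map(map)
  stopifnot(inherits(region, "tumor_region"))
  if (!identical(dim(region$mask), dim(map$labels))) {
    stop("region mask shape does not match the map", call. = FALSE)
  }
  if (!is.numeric(invasive_fraction) || length(invasive_fraction) != 1L ||
      is.na(invasive_fraction) || invasive_fraction < 0 || invasive_fraction > 1) {
    stop("`invasive_fraction` must be a scalar in [0, 1]", call. = FALSE)
  }
  denominator <- match.arg(denominator)
  inside <- map$labels[region$mask]
  counts <- vapply(TISSUE_CODES, function(code) sum(inside == code), integer(1L))
  denom <- if (denominator == "all") length(inside) else
    length(inside) - counts[["BACKGROUND"]]
  if (denom == 0L) stop("empty denominator for the requested mode", call. = FALSE)
  pr <- 10000 * counts / denom
  carcinomaP <- pr[["CARCINOMA"]]
  structure(
    list(AP = pr[["ADIPOSE"]], BP = pr[["BACKGROUND"]], NP = pr[["NECROSIS"]],
         TDLUP = pr[["TDLU"]], SP = pr[["STROMA"]], carcinomaP = carcinomaP,
         ICP = carcinomaP * invasive_fraction,
         TILP = compute_tilp(map, region),
         invasive_fraction = invasive_fraction,
         n_patches = region$n_patches, denominator = denominator),
    class = "morph_profile"
  )
}

#' Intratumoral lymphocyte area proportion (TILP)
#'
#' Lymphocyte area inside the tumour perimeter divided by the total area of
#' intratumoral patches, x10,000. Because every patch has equal area, this
#' equals 10,000 times the mean per-patch lymphocyte fraction inside the
#' region.
#'
#' @inheritParams compute_proportions
#' @return Scalar TILP on the x10,000 scale.
#' @export
compute_tilp <- function(map, region) {
  validate_label_map(map)
  stopifnot(inherits(region, "tumor_region"))
  10000 * mean(map$lymph_fraction[region$mask])
}

#' Morphometric profiles for a batch of cases
#'
#' Runs [delineate_tumor()] + [compute_proportions()] over a list of label
#' maps and joins the profiles into one table. Cases whose map holds no
#' carcinoma are excluded and reported, mirroring how slides a model cannot
#' delineate are dropped from a study rather than failing the batch.
#'
#' @param maps Named list of [tissue_label_map()] objects; names are case
#'   ids (must be unique).
#' @param invasive_fractions Numeric vector (recycled if length 1) of
#'   per-case invasive fractions, aligned with `maps`.
#' @param close_radius,connectivity,denominator Passed through to the
#'   per-case operations.
#' @return List with `profiles` (a `data.frame`, one row per delineated
#'   case, keyed by `case_id`) and `excluded` (a `data.frame` of case id +
#'   reason).
#' @export
profile_cohort <- function(maps, invasive_fractions = 1,
                           close_radius = 2L, connectivity = 8L,
                           denominator = "all") {
  stopifnot(is.list(maps), length(maps) >= 1L)
  ids <- names(maps) %||% sprintf("case_%05d", seq_along(maps))
  if (anyDuplicated(ids)) stop("duplicate case ids", call. = FALSE)
  if (length(invasive_fractions) == 1L) {
    invasive_fractions <- rep(invasive_fractions, length(maps))
  }
  stopifnot(length(invasive_fractions) == length(maps))
  rows <- list(); excl <- list()
  for (i in seq_along(maps)) {
    prof <- tryCatch(
      {
        reg <- delineate_tumor(maps[[i]], close_radius, connectivity)
        compute_proportions(maps[[i]], reg, invasive_fractions[i],
                            denominator = denominator)
      },
      pdx_no_tumor = function(e) e
    )
    if (inherits(prof, "pdx_no_tumor")) {
      excl[[length(excl) + 1L]] <- data.frame(case_id = ids[i],
                                              reason = conditionMessage(prof))
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = ids[i], AP = prof$AP, BP = prof$BP, NP = prof$NP,
        TDLUP = prof$TDLUP, SP = prof$SP, carcinomaP = prof$carcinomaP,
        ICP = prof$ICP, TILP = prof$TILP,
        invasive_fraction = prof$invasive_fraction,
        n_patches = prof$n_patches)
    }
  }
  list(
    profiles = if (length(rows)) do.call(rbind, rows) else
      data.frame(case_id = character(0)),
    excluded = if (length(excl)) do.call(rbind, excl) else
      data.frame(case_id = character(0), reason = character(0))
  )
}

#' @export
print.morph_profile <- function(x, ...) {
  cat("Intratumoral morphometric profile (x10,000 scale)\n")
  cat(sprintf("  patches in region: %d\n", x$n_patches))
  for (f in c("AP", "BP", "NP", "TDLUP", "SP", "carcinomaP", "ICP", "TILP")) {
    cat(sprintf("  %-10s %9.2f\n", f, x[[f]]))
  }
  cat(sprintf("  invasive fraction: %.3f\n", x$invasive_fraction))
  invisible(x)
}

#' @export
print.tumor_region <- function(x, ...) {
  cat(sprintf("Tumour region: %d patches on a %d x %d grid, %d rim patches\n",
              x$n_patches, nrow(x$mask), ncol(x$mask), nrow(x$boundary)))
  invisible(x)
}
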