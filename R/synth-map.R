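# Synthetic tissue-class label maps with controllable composition and a
# single dominant tumour mass.

#' Specification for a synthetic tissue label map
#'
#' Describes a synthetic whole-slide label grid: each cell stands for one
#' 112x112 px patch at 400x magnification, labelled with one of the six
#' tissue classes in [TISSUE_CODES]. The generator places a single, simply
#' connected tumour mass covering about `tumor_mass` of the grid; cells
#' inside the mass follow `composition` (the intratumoral mix, carcinoma
#' included), and the surround is filled with the non-carcinoma classes of
#' `composition`, renormalised.
#'
#' @param shape Integer vector `c(rows, cols)` of the patch grid.
#' @param composition Named numeric vector of intratumoral class fractions
#'   (names among `names(TISSUE_CODES)`), non-negative, summing to 1 within
#'   1e-9. Classes omitted get fraction 0.
#' @param tumor_mass Fraction of the grid covered by the tumour region,
#'   in (0, 1].
#' @param smoothness Gaussian kernel width (in patches) of the random fields
#'   that give the map its spatial coherence; larger values give larger,
#'   smoother tissue pockets.
#' @param mean_lymph_fraction Mean per-patch lymphocyte area fraction in
#'   [0, 1]. Stroma patches get double this mean (capped), mimicking
#'   stromal TILs; background patches always get 0.
#' @param patch_px Pixels per patch side (metadata only).
#' @param seed Integer seed; identical spec + seed gives identical maps.
#' @return An object of class `synth_map_spec`.
#' @seealso [generate_label_map()]
#' @export
synth_map_spec <- function(shape = c(200L, 200L),
                           composition = c(CARCINOMA = 0.55, NECROSIS = 0.10,
                                           STROMA = 0.25, ADIPOSE = 0.05,
                                           TDLU = 0.05),
                           tumor_mass = 0.30,
                           smoothness = 3,
                           mean_lymph_fraction = 0.02,
                           patch_px = 112L,
                           seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(!is.finite(shape)) || any(shape < 1L)) {
    stop("`shape` must be two positive integers", call. = FALSE)
  }
  if (is.null(names(composition)) ||
      !all(names(composition) %in% names(TISSUE_CODES))) {
    stop("`composition` must be named with tissue classes among: ",
         paste(names(TISSUE_CODES), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(composition))) {
    stop("duplicated class names in `composition`", call. = FALSE)
  }
  if (any(composition < 0)) stop("composition fractions must be non-negative",
                                 call. = FALSE)
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1 (tolerance 1e-9), got ",
         format(sum(composition), digits = 12), call. = FALSE)
  }
  if (!is.numeric(tumor_mass) || tumor_mass <= 0 || tumor_mass > 1) {
    stop("`tumor_mass` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(smoothness) || smoothness <= 0) {
    stop("`smoothness` must be positive", call. = FALSE)
  }
  if (mean_lymph_fraction < 0 || mean_lymph_fraction > 1) {
    stop("`mean_lymph_fraction` must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(shape = shape, composition = composition, tumor_mass = tumor_mass,
         smoothness = smoothness, mean_lymph_fraction = mean_lymph_fraction,
         patch_px = as.integer(patch_px), seed = seed),
    class = "synth_map_spec"
  )
}

#' Tissue label map container
#'
#' @param labels Integer matrix of tissue codes (see [TISSUE_CODES]).
#' @param lymph_fraction Numeric matrix, same shape, per-patch lymphocyte
#'   area fraction in [0, 1]; must be 0 on background patches.
#' @param patch_px Pixels per patch side.
#' @return An object of class `tissue_label_map`.
#' @export
tissue_label_map <- function(labels, lymph_fraction, patch_px = 112L) {
  map <- structure(
    list(labels = labels, lymph_fraction = lymph_fraction,
         patch_px = as.integer(patch_px)),
    class = "tissue_label_map"
  )
  validate_label_map(map)
  map
}

#' Validate a tissue label map
#'
#' Checks the container invariants: matching non-empty shapes, labels among
#' the six tissue codes, lymphocyte fractions in [0, 1] and zero on
#' background patches.
#'
#' @param map A `tissue_label_map`.
#' @return `map`, invisibly; errors describe the violated invariant.
#' @export
validate_label_map <- function(map) {
  stopifnot(inherits(map, "tissue_label_map"))
  lab <- map$labels; lf <- map$lymph_fraction
  if (!is.matrix(lab) || length(lab) == 0L) {
    stop("labels must be a non-empty matrix", call. = FALSE)
  }
  if (!is.matrix(lf) || !identical(dim(lab), dim(lf))) {
    stop("labels and lymph_fraction must have identical shape", call. = FALSE)
  }
  if (!all(lab %in% TISSUE_CODES)) {
    stop("labels contain codes outside 1..6", call. = FALSE)
  }
  if (any(lf < 0 | lf > 1)) {
    stop("lymph_fraction values must lie in [0, 1]", call. = FALSE)
  }
  if (any(lf[lab == TISSUE_CODES[["BACKGROUND"]]] != 0)) {
    stop("lymph_fraction must be 0 on BACKGROUND patches", call. = FALSE)
  }
  if (map$patch_px < 1L) stop("patch_px must be positive", call. = FALSE)
  invisible(map)
}

# Row/column Gaussian smoothing by explicit (row-normalised) kernel matrices;
# edges are renormalised rather than padded, so the field stays stationary in
# level near the border.
smoothing_matrix <- function(n, sigma) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-0.5 * (d / sigma)^2)
  K / rowSums(K)
}

smooth_field <- function(z, sigma) {
  f <- smoothing_matrix(nrow(z), sigma) %*% z %*%
    t(smoothing_matrix(ncol(z), sigma))
  (f - mean(f)) / max(sd(f), .Machine$double.eps)
}

# Best-first region growing: starting at the field maximum, repeatedly annex
# the frontier cell with the highest field value. The result is a connected
# blob of exactly `m` cells (holes, if any, are filled by the caller).
grow_blob <- function(field, m) {
  nr <- nrow(field); nc <- ncol(field)
  fval <- as.numeric(field)
  in_region <- logical(nr * nc)
  in_front <- logical(nr * nc)
  offs_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  offs_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  cur <- which.max(fval)
  in_region[cur] <- TRUE
  front <- integer(0)
  while (sum(in_region) < m) {
    r <- ((cur - 1L) %% nr) + 1L
    cc <- ((cur - 1L) %/% nr) + 1L
    rr <- r + offs_r; ccn <- cc + offs_c
    ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
    nb <- (ccn[ok] - 1L) * nr + rr[ok]
    nb <- nb[!in_region[nb] & !in_front[nb]]
    if (length(nb)) {
      in_front[nb] <- TRUE
      front <- c(front, nb)
    }
    if (!length(front)) break
    j <- which.max(fval[front])
    cur <- front[j]
    front <- front[-j]
    in_front[cur] <- FALSE
    in_region[cur] <- TRUE
  }
  matrix(in_region, nr, nc)
}

# Assign classes to `cells` by per-class smoothed fields plus additive
# offsets, iteratively calibrated so realised fractions approach `targets`.
calibrated_argmax <- function(fields, cells, targets,
                              iters = 120L, tol = 0.003) {
  K <- length(targets)
  if (K == 1L) return(rep(1L, length(cells)))
  F <- vapply(fields, function(f) f[cells], numeric(length(cells)))
  off <- rep(0, K)
  assign <- max.col(F, ties.method = "first")
  for (it in seq_len(iters)) {
    assign <- max.col(sweep(F, 2L, off, "+"), ties.method = "first")
    frac <- tabulate(assign, K) / length(cells)
    if (max(abs(frac - targets)) < tol) break
    off <- off + 0.8 * (log(targets + 1e-9) - log(frac + 1e-9))
  }
  assign
}

#' Generate a synthetic tissue label map
#'
#' Emulates a patch-classified whole-slide image: per-class Gaussian random
#' fields are smoothed with kernel width `smoothness` and assigned by
#' offset-calibrated argmax to hit the target composition; one simply
#' connected tumour mass (grown from a smoothed field, holes filled) hosts
#' the intratumoral mix, with all its non-carcinoma pockets placed strictly
#' in the mass interior so that they are recovered as holes by tumour
#' delineation. The surround is filled with the renormalised non-carcinoma
#' classes. With a pure-carcinoma composition the whole grid is carcinoma.
#'
#' @param spec A [synth_map_spec()].
#' @return A [tissue_label_map()]. Deterministic given `spec` (including its
#'   seed).
#' @examples
#' map <- generate_label_map(synth_map_spec(shape = c(60, 60), seed = 7))
#' table(factor(map$labels, TISSUE_CODES, names(TISSUE_CODES)))
#' @export
generate_label_map <- function(spec) {
  stopifnot(inherits(spec, "synth_map_spec"))
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  N <- nr * nc
  comp <- setNames(numeric(6L), names(TISSUE_CODES))
  comp[names(spec$composition)] <- spec$composition
  cC <- comp[["CARCINOMA"]]
  with_seed(spec$seed, {
    labels <- matrix(TISSUE_CODES[["CARCINOMA"]], nr, nc)
    if (cC < 1 - 1e-12) {
      noncar <- comp[names(comp) != "CARCINOMA"]
      use <- names(noncar)[noncar > 0]
      fields <- lapply(setNames(use, use), function(cl) {
        smooth_field(matrix(rnorm(N), nr, nc), spec$smoothness)
      })
      if (cC <= 1e-12) {
        # No tumour at all: the whole grid follows the composition.
        assign <- calibrated_argmax(fields, seq_len(N), noncar[use] / sum(noncar[use]))
        labels[] <- TISSUE_CODES[use][assign]
      } else {
        m <- round(spec$tumor_mass * N)
        if (m < 1L) {
          stop("grid too small to host `tumor_mass`", call. = FALSE)
        }
        region <- fill_holes(grow_blob(
          smooth_field(matrix(rnorm(N), nr, nc), spec$smoothness * 2), m))
        m_real <- sum(region)
        interior <- erode_box(region, 1L)
        quota <- round(noncar[use] * m_real)
        n_int <- sum(interior)
        if (sum(quota) > n_int) {
          stop("grid too small to host `tumor_mass` with the requested ",
               "composition (interior of the tumour mass cannot hold the ",
               "non-carcinoma quota)", call. = FALSE)
        }
        # Surround first, then overwrite the mass. Necrosis is intratumoral
        # in real slides, so it is kept out of the surround when any other
        # non-carcinoma class is available.
        surround <- setdiff(use, "NECROSIS")
        if (!length(surround)) surround <- use
        out_cells <- which(!region)
        if (length(out_cells)) {
          assign <- calibrated_argmax(fields[surround], out_cells,
                                      noncar[surround] / sum(noncar[surround]))
          labels[out_cells] <- TISSUE_CODES[surround][assign]
        }
        labels[region] <- TISSUE_CODES[["CARCINOMA"]]
        if (sum(quota) > 0 && n_int > 0L) {
          int_cells <- which(interior)
          pocket_cls <- names(quota)[quota > 0]
          targets <- c(quota[pocket_cls] / n_int, 1 - sum(quota) / n_int)
          pfields <- c(fields[pocket_cls],
                       list(smooth_field(matrix(rnorm(N), nr, nc),
                                         spec$smoothness)))
          assign <- calibrated_argmax(pfields, int_cells, targets)
          keep <- assign <= length(pocket_cls)
          labels[int_cells[keep]] <- TISSUE_CODES[pocket_cls][assign[keep]]
        }
      }
    }
    lf <- matrix(0, nr, nc)
    mlf <- spec$mean_lymph_fraction
    if (mlf > 0) {
      mu <- matrix(mlf, nr, nc)
      mu[labels == TISSUE_CODES[["STROMA"]]] <- min(2 * mlf, 0.95)
      mu[labels == TISSUE_CODES[["BACKGROUND"]]] <- 0
      pos <- mu > 0
      kappa <- 15
      lf[pos] <- rbeta(sum(pos), mu[pos] * kappa, (1 - mu[pos]) * kappa)
    }
    tissue_label_map(labels, lf, spec$patch_px)
  })
}
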