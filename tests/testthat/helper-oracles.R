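# Brute-force oracles, written independently of the package internals:
# per-cell loops and flood fills instead of vectorised morphology, pair
# counting instead of ranks, exhaustive scans instead of reductions.

oracle_dilate <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- any(mask[max(1, i - r):min(nr, i + r),
                            max(1, j - r):min(nc, j + r)])
    }
  }
  out
}

oracle_erode <- function(mask, r) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      # a window clipped by the border counts the outside as background
      full <- (i - r >= 1) && (i + r <= nr) && (j - r >= 1) && (j + r <= nc)
      out[i, j] <- full && all(mask[(i - r):(i + r), (j - r):(j + r)])
    }
  }
  out
}

# BFS flood fill over `open` cells starting from `starts` (matrix of row/col).
oracle_flood <- function(open, starts, connectivity = 4L) {
  nr <- nrow(open); nc <- ncol(open)
  offs <- if (connectivity == 4L) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))[-5, ]
  }
  seen <- matrix(FALSE, nr, nc)
  queue <- starts[open[starts], , drop = FALSE]
  seen[queue] <- TRUE
  while (nrow(queue) > 0L) {
    nxt <- list()
    for (q in seq_len(nrow(queue))) {
      for (o in seq_len(nrow(offs))) {
        i <- queue[q, 1] + offs[o, 1]; j <- queue[q, 2] + offs[o, 2]
        if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
            open[i, j] && !seen[i, j]) {
          seen[i, j] <- TRUE
          nxt[[length(nxt) + 1L]] <- c(i, j)
        }
      }
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else
      matrix(integer(0), 0, 2)
  }
  seen
}

oracle_fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  border <- rbind(cbind(1, seq_len(nc)), cbind(nr, seq_len(nc)),
                  cbind(seq_len(nr), 1), cbind(seq_len(nr), nc))
  outside <- oracle_flood(!mask, border, connectivity = 4L)
  mask | (!mask & !outside)
}

oracle_components <- function(mask, connectivity = 8L) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        k <- k + 1L
        comp <- oracle_flood(mask, cbind(i, j), connectivity)
        lab[comp] <- k
      }
    }
  }
  lab
}

# Closing computed on a grid padded by the radius, as the definition
# requires (dilation may spill past the border).
oracle_close <- function(mask, r) {
  if (r == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  big[r + seq_len(nr), r + seq_len(nc)] <- mask
  big <- oracle_erode(oracle_dilate(big, r), r)
  big[r + seq_len(nr), r + seq_len(nc)]
}

# Full delineation oracle: closing by per-cell window scans, BFS hole fill,
# BFS components, largest-with-top-left-tie-break.
oracle_delineate <- function(labels, close_radius = 2L, connectivity = 8L) {
  carc <- labels == pdxms::TISSUE_CODES[["CARCINOMA"]]
  if (!any(carc)) return(NULL)
  mask <- oracle_fill_holes(oracle_close(carc, close_radius))
  lab <- oracle_components(mask, connectivity)
  sizes <- tabulate(lab)
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    key <- sapply(best, function(id) {
      w <- which(lab == id, arr.ind = TRUE)
      w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
      w[1, 1] * (ncol(labels) + 1) + w[1, 2]
    })
    best <- best[which.min(key)]
  }
  lab == best
}

oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  total <- 0
  for (a in s1) for (b in s0) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(s1) * length(s0))
}

oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    sens <- sum(labels == 1 & scores >= t) / sum(labels == 1)
    spec <- sum(labels == 0 & scores < t) / sum(labels == 0)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-15) best <- list(cutoff = t, j = j)
  }
  best
}

# Exhaustive best binary split: every midpoint for numeric variables, every
# proper subset for categorical ones (no rate-ordering shortcut).
oracle_root_split <- function(data, y, vars, minbucket = 7L) {
  gini_cnt <- function(n1, n) if (n == 0) 0 else 2 * n1 * (n - n1) / n
  n <- length(y); n1 <- sum(y)
  parent <- gini_cnt(n1, n)
  best <- list(dec = 0)
  for (v in vars) {
    x <- data[[v]]
    if (is.numeric(x)) {
      u <- sort(unique(x))
      if (length(u) < 2) next
      for (cut in (u[-1] + u[-length(u)]) / 2) {
        L <- x < cut
        if (sum(L) < minbucket || sum(!L) < minbucket) next
        dec <- parent - gini_cnt(sum(y[L]), sum(L)) -
          gini_cnt(sum(y[!L]), sum(!L))
        if (dec > best$dec + 1e-12) best <- list(dec = dec, var = v, cut = cut)
      }
    } else {
      levs <- unique(as.character(x))
      if (length(levs) < 2) next
      for (mask in seq_len(2^length(levs) - 2)) {
        left <- levs[bitwAnd(mask, 2^(seq_along(levs) - 1)) > 0]
        L <- as.character(x) %in% left
        if (sum(L) < minbucket || sum(!L) < minbucket) next
        dec <- parent - gini_cnt(sum(y[L]), sum(L)) -
          gini_cnt(sum(y[!L]), sum(!L))
        if (dec > best$dec + 1e-12) best <- list(dec = dec, var = v, left = left)
      }
    }
  }
  best
}

# 2x2 contingency oracle for the saturated logistic model: counts are
# (failure, success) for the reference and the index level.
oracle_or_2x2 <- function(fail_ref, succ_ref, fail_idx, succ_idx) {
  beta <- log((succ_idx / fail_idx) / (succ_ref / fail_ref))
  se <- sqrt(1 / fail_ref + 1 / succ_ref + 1 / fail_idx + 1 / succ_idx)
  list(beta = beta, se = se, or = exp(beta))
}

# Two-sided Fisher p for a 2x2 table by hypergeometric enumeration.
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  p <- dhyper(support, m, n, k)
  sum(p[p <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
}

# Small helper: build a map from a label matrix (uniform lymph fraction).
make_map <- function(labels, lymph = 0) {
  lf <- matrix(lymph, nrow(labels), ncol(labels))
  lf[labels == pdxms::TISSUE_CODES[["BACKGROUND"]]] <- 0
  tissue_label_map(labels, lf)
}
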