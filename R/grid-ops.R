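# Binary morphology and labelling on logical patch grids.
#
# Semantics are pinned down deliberately: cells outside the grid count as
# background (FALSE) for both dilation and erosion, connected components use
# 8-connectivity by default (4 available), and holes are background regions
# of the 4-connected complement that do not touch the grid border. These
# conventions are what the delineation contract and its brute-force test
# oracle assume.

shift_mat <- function(m, dr, dc, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- seq_len(nr) - dr
  cs <- seq_len(nc) - dc
  ok_r <- rs >= 1L & rs <= nr
  ok_c <- cs >= 1L & cs <= nc
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

dilate_box <- function(mask, radius) {
  if (radius == 0L) return(mask)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      out <- out | shift_mat(mask, dr, dc, fill = FALSE)
    }
  }
  out
}

erode_box <- function(mask, radius) {
  if (radius == 0L) return(mask)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      out <- out & shift_mat(mask, dr, dc, fill = FALSE)
    }
  }
  out
}

# Morphological closing on a grid padded by `radius` (the canonical
# treatment: dilation may extend past the border, so erosion must see it;
# without padding, closing would not be extensive near edges and would not
# be monotone in the radius).
close_box <- function(mask, radius) {
  if (radius == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  big <- matrix(FALSE, nr + 2L * radius, nc + 2L * radius)
  big[radius + seq_len(nr), radius + seq_len(nc)] <- mask
  big <- erode_box(dilate_box(big, radius), radius)
  big[radius + seq_len(nr), radius + seq_len(nc)]
}

neighbour_offsets <- function(connectivity) {
  if (connectivity == 4L) {
    list(c(1L, 0L), c(0L, 1L))
  } else if (connectivity == 8L) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  } else {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
}

# Label connected components of a logical matrix. Returns an integer matrix
# with 0 for background; component ids are arbitrary but deterministic.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  edges <- list()
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  k <- 0L
  for (off in neighbour_offsets(connectivity)) {
    r2 <- rows + off[1L]; c2 <- cols + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    j <- (c2[ok] - 1L) * nr + r2[ok]
    both <- mask[j]
    if (any(both)) {
      k <- k + 1L
      edges[[k]] <- cbind(vid[idx[ok][both]], vid[j[both]])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (k > 0L) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Fill holes: background regions (4-connected) not reachable from the border.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  border <- border[border != 0L]
  mask | (lab != 0L & !(lab %in% border))
}
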