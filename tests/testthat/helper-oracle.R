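# Independent, unoptimized reference implementations used as oracles.

# Per-pixel loop erosion/dilation with a 3x3 neighbourhood, zero outside.
oracle_erode <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    ok <- TRUE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !mask[ii, jj])
        ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

oracle_dilate <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    any_nb <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj])
        any_nb <- TRUE
    }
    out[i, j] <- any_nb
  }
  out
}

# Straightforward reimplementation of the n-layer division step:
# loop-based morphology, explicit per-cell processing. Shares the RNG call
# pattern of the packaged implementation (one shuffle per layer, one
# placement draw per layer) so that identical seeds permit bitwise
# comparison of the resulting grids.
oracle_grow_step <- function(grid, n_layers) {
  g <- grid
  tum <- g == 1L | g == 2L | g == 5L
  ero <- vector("list", n_layers + 1L)
  ero[[1L]] <- tum
  for (k in seq_len(n_layers)) ero[[k + 1L]] <- oracle_erode(ero[[k]])
  grown <- tum
  for (k in seq_len(n_layers)) grown <- oracle_dilate(grown)
  free_pool <- which(grown & g == 0L)
  for (k in seq_len(n_layers)) {
    cells <- which(ero[[k]] & !ero[[k + 1L]])
    nc <- length(cells)
    if (nc == 0L) next
    nf <- length(free_pool)
    if (nf == 0L) break
    ord <- cells[sample.int(nc)]
    consumed <- 0L
    divs <- integer(0)
    deaths <- integer(0)
    for (cell in ord) {
      if (consumed >= nf) next
      if (g[cell] == 5L) {
        deaths <- c(deaths, cell)
      } else {
        divs <- c(divs, cell)
        consumed <- consumed + 1L
      }
    }
    if (length(divs) > 0L) {
      pick <- free_pool[sample.int(length(free_pool), length(divs))]
      g[pick] <- 1L
      free_pool <- free_pool[!(free_pool %in% pick)]
    }
    if (length(deaths) > 0L) g[deaths] <- 0L
  }
  g
}

# brute-force closed-disk site count by exhaustive enumeration
oracle_disk_count <- function(radius) {
  cnt <- 0L
  for (dx in -radius:radius) for (dy in -radius:radius)
    if (dx * dx + dy * dy <= radius * radius) cnt <- cnt + 1L
  cnt
}

# small tissue used across tests where full 600^2 scale is unnecessary
scaled_geometry <- function(grid_side = 150L, tumour_radius_px = 12L, ...) {
  geometry_params(grid_side = grid_side, tumour_radius_px = tumour_radius_px,
                  ...)
}

# bare tissue_state with a given grid and no vessels (for controlled setups)
bare_state <- function(grid, leak_sites = integer(0), leak_values = NULL) {
  leak <- if (length(leak_sites) > 0) {
    v <- if (is.null(leak_values)) rep(1, length(leak_sites)) else leak_values
    names(v) <- as.character(leak_sites)
    v
  } else {
    structure(numeric(0), names = character(0))
  }
  structure(list(grid = grid, leak = leak, arrest_hours = 0, day = 0L,
                 o2 = NULL),
            class = "tissue_state")
}
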