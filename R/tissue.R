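#' Rasterize a closed disk on the lattice
#'
#' Returns all lattice sites whose centre lies at Euclidean distance
#' `<= radius_px` from the grid centre site (closed inequality
#' `dx^2 + dy^2 <= r^2` on integer offsets). For radius 50 this yields
#' exactly 7845 sites, the cell count of the initial 1.5 mm tumour disk.
#'
#' @param radius_px Disk radius in pixels (integer, >= 0).
#' @param grid_side Lattice side length in pixels.
#' @return Integer vector of (column-major) linear site indices.
#' @export
rasterize_disk <- function(radius_px, grid_side) {
  radius_px <- as.integer(radius_px)
  grid_side <- as.integer(grid_side)
  if (radius_px < 0) stop("radius_px must be >= 0")
  if (radius_px >= grid_side / 2)
    stop("disk of radius ", radius_px, " does not fit in a ", grid_side,
         "-pixel grid")
  ctr <- (grid_side + 1L) %/% 2L
  off <- seq.int(-radius_px, radius_px)
  dx <- rep(off, times = length(off))
  dy <- rep(off, each = length(off))
  keep <- dx * dx + dy * dy <= radius_px * radius_px
  rows <- ctr + dx[keep]
  cols <- ctr + dy[keep]
  sort((cols - 1L) * grid_side + rows)
}

#' Initialize the tissue lattice
#'
#' Places the tumour disk at the grid centre, scatters quiescent normal
#' cells over the remaining space at `normal_fraction`, then overlays
#' vessels uniformly at random over the whole domain (including the tumour)
#' at `vessel_density`, overwriting whatever occupies those sites. All leak
#' multipliers start at 1 and the growth-arrest timer at 0.
#'
#' @param geom A [geometry_params()] object.
#' @param seed Optional integer seed; if supplied, `set.seed(seed)` is
#'   called first so initialization is reproducible. If `NULL` the ambient
#'   RNG stream is used (as [run_simulation()] does after seeding once).
#' @return An object of class `tissue_state`: list with `grid` (integer
#'   matrix of pixel states), `leak` (named numeric vector, one entry per
#'   vessel site, values >= 1), `arrest_hours` (global growth-arrest timer),
#'   `day`, and an internal cached oxygen field.
#' @export
init_tissue <- function(geom, seed = NULL) {
  stopifnot(inherits(geom, "geometry_params"))
  if (!is.null(seed)) set.seed(seed)
  G <- geom$grid_side
  grid <- matrix(PIXEL_STATES[["EMPTY"]], G, G)
  disk <- rasterize_disk(geom$tumour_radius_px, G)
  grid[disk] <- PIXEL_STATES[["TUMOUR_NORMOXIC"]]
  outside <- which(grid == PIXEL_STATES[["EMPTY"]])
  if (geom$normal_fraction > 0 && length(outside) > 0) {
    take <- stats::runif(length(outside)) < geom$normal_fraction
    grid[outside[take]] <- PIXEL_STATES[["NORMAL"]]
  }
  if (geom$vessel_density > 0) {
    vs <- which(stats::runif(G * G) < geom$vessel_density)
    grid[vs] <- PIXEL_STATES[["VESSEL"]]
  } else {
    vs <- integer(0)
  }
  leak <- rep(1, length(vs))
  names(leak) <- as.character(vs)
  structure(list(grid = grid, leak = leak, arrest_hours = 0,
                 day = 0L, o2 = NULL),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cs <- count_states(x)
  cat(sprintf(
    "tissue_state: %d x %d grid, day %d, arrest %g h\n",
    nrow(x$grid), ncol(x$grid), x$day, x$arrest_hours))
  cat("  viable tumour:", cs[["TUMOUR_NORMOXIC"]] + cs[["TUMOUR_HYPOXIC"]],
      "| lethal:", cs[["LETHAL"]], "| vessels:", cs[["VESSEL"]],
      "| normal:", cs[["NORMAL"]], "\n")
  invisible(x)
}

# 3x3 box structuring element (8-connectivity)
.brush3 <- function() EBImage::makeBrush(3L, shape = "box")

# logical masks as numeric 0/1 matrices for EBImage
.tumour_mask <- function(grid) {
  m <- matrix(0, nrow(grid), ncol(grid))
  m[grid == 1L | grid == 2L | grid == 5L] <- 1
  m
}

#' One day of n-layer tumour growth
#'
#' Morphological division step. The tumour mask (viable plus lethal cells)
#' is eroded `n_layers` times to find the non-dividing core; the growth area
#' is the `n_layers`-fold dilation of the mask minus occupied sites (normal
#' cells, vessels and the tumour itself). Layers are processed from the
#' outermost inwards: cells of each layer attempt division in random order
#' while free growth-area sites remain. A viable cell places one daughter at
#' a uniformly random free growth-area site; a lethal (type 5) cell selected
#' to divide instead dies of mitotic catastrophe - its site is cleared and
#' no daughter appears.
#'
#' The caller gates on the growth-arrest timer; this function assumes the
#' tissue is free to grow.
#'
#' @param state A `tissue_state`.
#' @param geom A [geometry_params()] (supplies `n_layers`).
#' @return Updated `tissue_state`.
#' @export
grow_step <- function(state, geom) {
  full <- state$grid
  n <- geom$n_layers
  G <- nrow(full)
  # all morphology happens within the tumour bounding box (padded by the
  # dilation reach); sites outside it cannot change. Column-major site
  # ordering inside the box matches the full grid, so sampling is
  # identical to operating on the whole lattice.
  occ <- full == 1L | full == 2L | full == 5L
  if (!any(occ)) return(state)
  ri <- range(which(rowSums(occ) > 0L))
  ci <- range(which(colSums(occ) > 0L))
  rows <- max(1L, ri[1] - n - 1L):min(G, ri[2] + n + 1L)
  cols <- max(1L, ci[1] - n - 1L):min(ncol(full), ci[2] + n + 1L)
  g <- full[rows, cols, drop = FALSE]
  # zero-pad before the morphology: outside the lattice there is no
  # tissue, whereas EBImage's erode treats out-of-image pixels as
  # foreground at borders
  pad <- n + 1L
  nr <- nrow(g); nc <- ncol(g)
  tum_p <- matrix(0, nr + 2L * pad, nc + 2L * pad)
  core_r <- pad + seq_len(nr)
  core_c <- pad + seq_len(nc)
  tum_p[core_r, core_c] <- .tumour_mask(g)
  kern <- .brush3()
  ero_p <- vector("list", n + 1L)
  ero_p[[1L]] <- tum_p
  for (k in seq_len(n)) ero_p[[k + 1L]] <- EBImage::erode(ero_p[[k]], kern)
  grown_p <- tum_p
  for (k in seq_len(n)) grown_p <- EBImage::dilate(grown_p, kern)
  ero <- lapply(ero_p, function(m) m[core_r, core_c, drop = FALSE])
  grown <- grown_p[core_r, core_c, drop = FALSE]
  free_pool <- which(grown == 1 & g == PIXEL_STATES[["EMPTY"]])
  for (k in seq_len(n)) {
    cells <- which(ero[[k]] == 1 & ero[[k + 1L]] == 0)
    nc <- length(cells)
    if (nc == 0L) next
    nf <- length(free_pool)
    if (nf == 0L) break
    ord <- cells[sample.int(nc)]
    viable <- g[ord] != PIXEL_STATES[["LETHAL"]]
    consumed_before <- cumsum(viable) - viable
    acts <- consumed_before < nf
    divs <- ord[acts & viable]
    deaths <- ord[acts & !viable]
    if (length(divs) > 0L) {
      pick <- free_pool[sample.int(length(free_pool), length(divs))]
      g[pick] <- PIXEL_STATES[["TUMOUR_NORMOXIC"]]
      free_pool <- free_pool[!(free_pool %in% pick)]
    }
    if (length(deaths) > 0L) g[deaths] <- PIXEL_STATES[["EMPTY"]]
  }
  full[rows, cols] <- g
  state$grid <- full
  state
}

#' Reclassify tumour cells by local oxygen
#'
#' Viable tumour cells are relabelled normoxic (type 1) or hypoxic (type 2)
#' by comparing the local O2 fraction against the threshold. The split is
#' purely a visual/metric aid: radiation kill always uses the continuous O2
#' value, never the discrete label.
#'
#' @param state A `tissue_state`.
#' @param o2 Oxygen matrix, same shape as the grid (see
#'   [compute_oxygen_map()]).
#' @param hypoxia_threshold O2 fraction separating the two labels.
#' @return Updated `tissue_state`.
#' @export
reclassify_oxygen_types <- function(state, o2, hypoxia_threshold = 0.002) {
  if (!all(dim(o2) == dim(state$grid)))
    stop("oxygen map shape does not match the grid")
  g <- state$grid
  vi <- which(g == 1L | g == 2L)
  g[vi] <- ifelse(o2[vi] < hypoxia_threshold,
                  PIXEL_STATES[["TUMOUR_HYPOXIC"]],
                  PIXEL_STATES[["TUMOUR_NORMOXIC"]])
  state$grid <- g
  state
}

#' Census of pixel states
#'
#' @param state A `tissue_state`.
#' @return Named integer vector (one entry per pixel state) summing to the
#'   number of lattice sites.
#' @export
count_states <- function(state) {
  cs <- tabulate(state$grid + 1L, nbins = 6L)
  names(cs) <- names(PIXEL_STATES)
  cs
}

#' Number of viable tumour cells (types 1 and 2)
#' @param state A `tissue_state`.
#' @return Integer count.
#' @export
viable_count <- function(state) {
  sum(state$grid == 1L | state$grid == 2L)
}

# linear indices of sites occupied by tumour (viable or lethal)
tumour_site_index <- function(state) {
  which(state$grid == 1L | state$grid == 2L | state$grid == 5L)
}
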