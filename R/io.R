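# palette used in snapshots: empty black, normoxic red, hypoxic green,
# normal yellow, vessel dark blue, lethal cyan
.state_palette <- matrix(c(
  0, 0, 0,      # 0 EMPTY
  1, 0, 0,      # 1 TUMOUR_NORMOXIC
  0, 0.8, 0,    # 2 TUMOUR_HYPOXIC
  1, 1, 0,      # 3 NORMAL
  0, 0, 0.55,   # 4 VESSEL
  0, 1, 1       # 5 LETHAL
), ncol = 3, byrow = TRUE)

#' Write a colour snapshot of the tissue state
#'
#' @param state A `tissue_state`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_snapshot_png <- function(state, path) {
  g <- state$grid
  img <- array(0, dim = c(nrow(g), ncol(g), 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(.state_palette[g + 1L, ch], nrow(g), ncol(g))
  png::writePNG(img, target = path)
  invisible(path)
}

#' Write an oxygen map as a greyscale PNG
#'
#' Values are scaled by the cap so full saturation renders white.
#'
#' @param o2 Oxygen matrix.
#' @param path Output PNG path.
#' @param cap Saturation level used for scaling.
#' @return `path`, invisibly.
#' @export
write_oxygen_png <- function(o2, path, cap = 0.05) {
  png::writePNG(pmin(o2 / cap, 1), target = path)
  invisible(path)
}

#' Serialize / restore the lattice as a plain integer CSV grid
#'
#' Writes only the pixel-state grid (not leak multipliers or timers);
#' intended for fixtures and regression comparisons.
#'
#' @param state A `tissue_state` (or bare integer matrix).
#' @param path CSV path.
#' @return `path` invisibly for the writer; an integer matrix for the
#'   reader.
#' @export
write_state_grid <- function(state, path) {
  g <- if (inherits(state, "tissue_state")) state$grid else state
  utils::write.table(g, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_state_grid
#' @export
read_state_grid <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              colClasses = "integer"))
}

#' Write a trajectory as tidy CSV (one row per day)
#'
#' @param traj A `trajectory` from [run_simulation()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
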