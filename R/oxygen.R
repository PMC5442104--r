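# Peak-normalized isotropic Gaussian kernel, truncated at 4 sigma.
# Kernel value 1 at zero lag so that an isolated unit source reproduces
# O2(x) = exp(-x^2 / (2 sigma^2)) radially.
.gauss_kernel <- function(sigma) {
  r <- ceiling(4 * sigma)
  g1 <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  outer(g1, g1)
}

# The isotropic kernel is separable (outer product of the 1D profile), so
# the convolution with zero boundary is two banded-Toeplitz products:
# B %*% src %*% B with B symmetric. Cached per (sigma, grid side).
.conv_cache <- new.env(parent = emptyenv())

.gauss_band <- function(sigma, G) {
  key <- paste0(format(sigma, digits = 12), ":", G)
  B <- .conv_cache[[key]]
  if (is.null(B)) {
    r <- ceiling(4 * sigma)
    g1 <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
    B <- Matrix::bandSparse(G, G, k = seq.int(-r, r),
                            diagonals = lapply(seq.int(-r, r), function(k)
                              rep(g1[k + r + 1L], G - abs(k))))
    .conv_cache[[key]] <- B
  }
  B
}

# Unit-amplitude (s = 1), uncapped oxygen field: the vessel indicator image,
# scaled per site by its leak multiplier, convolved with the Gaussian
# kernel. Zero boundary (no sources outside the domain).
.oxygen_field_unit <- function(state, sigma) {
  G <- nrow(state$grid)
  src <- matrix(0, G, ncol(state$grid))
  if (length(state$leak) > 0)
    src[as.integer(names(state$leak))] <- state$leak
  if (all(src == 0)) return(src)
  B <- .gauss_band(sigma, G)
  as.matrix(B %*% src %*% B)
}

#' Steady-state oxygen map
#'
#' Computes the oxygen fraction at every lattice site by Gaussian filtering
#' of the vessel map: each vessel contributes a radial profile
#' `s * leak * exp(-x^2 / (2 sigma^2))` (peak-normalized kernel, so `s` is
#' the O2 fraction at an unhit vessel wall); overlapping contributions sum,
#' and the summed field is clipped to `[0, cap]`.
#'
#' @param state A `tissue_state`.
#' @param ox An [oxygen_params()] object.
#' @return Numeric matrix of O2 fractions, same shape as the grid.
#' @export
compute_oxygen_map <- function(state, ox) {
  stopifnot(inherits(ox, "oxygen_params"))
  u <- .oxygen_field_unit(state, ox$sigma)
  pmin(pmax(ox$s * u, 0), ox$cap)
}

# cached accessor: the field only changes when vessels (positions or leak
# multipliers) change, so fractions invalidate it and growth days reuse it
.ensure_o2 <- function(state, ox) {
  if (is.null(state$o2)) state$o2 <- compute_oxygen_map(state, ox)
  state
}

#' Hypoxic fraction of the tumour
#'
#' Fraction of tumour sites (viable or lethal) whose O2 lies below the
#' threshold.
#'
#' @param o2 Oxygen matrix from [compute_oxygen_map()].
#' @param state A `tissue_state`.
#' @param threshold O2 fraction (default 0.002, i.e. 0.2%).
#' @return Proportion in `[0, 1]`.
#' @export
hypoxic_fraction <- function(o2, state, threshold = 0.002) {
  if (!all(dim(o2) == dim(state$grid)))
    stop("oxygen map shape does not match the grid")
  ts <- tumour_site_index(state)
  if (length(ts) == 0L)
    stop("hypoxic fraction is undefined: no tumour sites")
  mean(o2[ts] < threshold)
}

#' Mean oxygen over tumour sites
#'
#' @inheritParams hypoxic_fraction
#' @return Arithmetic mean O2 fraction over tumour sites.
#' @export
mean_tumour_oxygen <- function(o2, state) {
  if (!all(dim(o2) == dim(state$grid)))
    stop("oxygen map shape does not match the grid")
  ts <- tumour_site_index(state)
  if (length(ts) == 0L)
    stop("mean tumour oxygen is undefined: no tumour sites")
  mean(o2[ts])
}
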