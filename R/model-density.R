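#' Compute model electron density on a grid
#'
#' Places an isotropic normalized Gaussian at every atom, with amplitude
#' `occupancy * Z` (Z = electron count) and variance
#' `sigma^2 = B / (8 pi^2) + core` where `core` (default 0.9 A^2) is a fixed
#' atomic width. The numeric integral of one atom's density over the grid
#' is `occupancy * Z` electrons (to well under 1% at default spacings), and
#' the field is exactly linear in occupancy and additive over atoms. This
#' is a single-width desk-scale stand-in for map synthesis from scattering
#' factors, intended for metric computation and simulation.
#'
#' @param model A [struct_model()].
#' @param spacing Voxel size in angstrom (used when `grid` is NULL).
#' @param grid Optional [density_grid()] supplying the target geometry;
#'   its values are ignored.
#' @param altlocs Optional character vector restricting which conformers
#'   contribute (blank `""` selects single-conformer atoms). Default: all.
#' @param occupancy_weighted Multiply each atom by its occupancy (default
#'   TRUE); FALSE treats every atom as fully occupied.
#' @param origin Grid origin when building the grid from `spacing`.
#' @param core_width Fixed variance added to the B-derived width, A^2.
#' @param cutoff Gaussian evaluation cutoff in standard deviations.
#' @return A [density_grid()] in e/A^3.
#' @export
compute_model_density <- function(model, spacing = 0.5, grid = NULL,
                                  altlocs = NULL, occupancy_weighted = TRUE,
                                  origin = c(0, 0, 0), core_width = 0.9,
                                  cutoff = 6) {
  atoms <- as_tibble(model)
  if (!is.null(altlocs)) atoms <- atoms[atoms$altloc %in% altlocs, ]
  if (is.null(grid)) {
    cell <- model_cell(model)[1:3]
    if (any(abs(model_cell(model)[4:6] - 90) > 1e-6)) {
      abort("only orthorhombic (90 degree) cells are supported")
    }
    dims <- pmax(2L, as.integer(ceiling(cell / spacing)))
    grid <- density_grid(array(0, dims), spacing = spacing, origin = origin,
                         cell = cell)
  }
  ax <- grid_axes(grid)
  lo <- c(ax$x[1], ax$y[1], ax$z[1]) - grid$spacing / 2
  hi <- c(ax$x[length(ax$x)], ax$y[length(ax$y)], ax$z[length(ax$z)]) +
    grid$spacing / 2
  if (max(grid$spacing) > 1.5) {
    warn("grid spacing is coarse relative to the atomic widths; density will be undersampled")
  }
  vals <- array(0, dim(grid$values))
  if (nrow(atoms) > 0) {
    pos <- as.matrix(atoms[, c("x", "y", "z")])
    out <- pos[, 1] < lo[1] | pos[, 1] > hi[1] |
      pos[, 2] < lo[2] | pos[, 2] > hi[2] |
      pos[, 3] < lo[3] | pos[, 3] > hi[3]
    if (any(out)) {
      abort(sprintf("%d atom(s) fall outside the grid (periodic wrap is not supported)",
                    sum(out)))
    }
    zc <- electron_count(atoms$element)
    amp <- zc * (if (occupancy_weighted) atoms$occ else 1)
    s2 <- atoms$b / (8 * pi^2) + core_width
    for (i in seq_len(nrow(atoms))) {
      s <- sqrt(s2[i])
      g1 <- function(t, t0) {
        r <- which(abs(t - t0) <= cutoff * s)
        list(idx = r, g = exp(-(t[r] - t0)^2 / (2 * s2[i])) / sqrt(2 * pi * s2[i]))
      }
      gx <- g1(ax$x, pos[i, 1]); gy <- g1(ax$y, pos[i, 2]); gz <- g1(ax$z, pos[i, 3])
      if (!length(gx$idx) || !length(gy$idx) || !length(gz$idx)) next
      xy <- amp[i] * outer(gx$g, gy$g)
      for (k in seq_along(gz$idx)) {
        vals[gx$idx, gy$idx, gz$idx[k]] <-
          vals[gx$idx, gy$idx, gz$idx[k]] + xy * gz$g[k]
      }
    }
  }
  density_grid(vals, spacing = grid$spacing, origin = grid$origin,
               cell = grid$cell)
}
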