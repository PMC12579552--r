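#' Density grid on an orthorhombic cell
#'
#' A 3-D scalar field sampled on a regular grid with 90-degree cell angles.
#' `values[i, j, k]` is the density at the voxel whose centre sits at
#' `origin + (c(i, j, k) - 1) * spacing` in orthogonal angstrom coordinates;
#' x is the fastest-varying axis, matching the CCP4/MRC convention used by
#' [read_ccp4()] / [write_ccp4()].
#'
#' @param values 3-D numeric array of densities.
#' @param spacing Voxel size per axis, angstrom (scalar or length 3).
#' @param origin Cartesian position of the first voxel centre, default
#'   `c(0, 0, 0)`.
#' @param cell Optional cell edges `c(a, b, c)`; defaults to
#'   `dim(values) * spacing` and must agree with it to within one voxel.
#' @return A `density_grid` object.
#' @export
density_grid <- function(values, spacing, origin = c(0, 0, 0), cell = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3) abort("values must be a 3-D array")
  if (any(!is.finite(values))) abort("density values must be finite")
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(spacing <= 0)) abort("spacing must be > 0")
  if (is.null(cell)) cell <- dim(values) * spacing
  if (any(abs(cell - dim(values) * spacing) > spacing)) {
    abort("cell disagrees with shape * spacing by more than one voxel")
  }
  structure(list(values = values, cell = as.numeric(cell), spacing = spacing,
                 origin = rep_len(as.numeric(origin), 3)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid> %s voxels, spacing %s A, origin %s, range [%.4g, %.4g]\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing, digits = 4), collapse = " "),
              paste(format(x$origin, digits = 4), collapse = " "),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_axes <- function(grid) {
  d <- dim(grid$values)
  list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
}

same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Voxelwise difference of two grids
#'
#' Computes `a - b`, the isomorphous-difference analogue for grids on
#' identical geometry (triggered minus reference).
#'
#' @param a,b [density_grid()]s with identical shape, spacing and origin.
#' @return A [density_grid()].
#' @export
difference_grid <- function(a, b) {
  if (!same_geometry(a, b)) abort("grid geometries differ")
  density_grid(a$values - b$values, spacing = a$spacing, origin = a$origin,
               cell = a$cell)
}

#' Estimate the noise level of a map
#'
#' @param grid A [density_grid()].
#' @param method `"rms"` (standard deviation about the mean over all voxels,
#'   the default) or `"mad"` (1.4826 x median absolute deviation, robust to
#'   outlier peaks).
#' @return List with `sigma`, `method`, and logical `degenerate` (TRUE with
#'   a warning when the grid is constant, in which case `sigma` is 0 and
#'   downstream Z-scores are undefined).
#' @export
estimate_sigma <- function(grid, method = c("rms", "mad")) {
  method <- match.arg(method)
  v <- as.numeric(grid$values)
  sigma <- switch(method,
                  rms = sqrt(mean((v - mean(v))^2)),
                  mad = mad(v, constant = 1.4826))
  degenerate <- sigma <= 0
  if (degenerate) warn("constant grid: sigma is 0; Z metrics are undefined")
  structure(list(sigma = sigma, method = method, degenerate = degenerate),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.6g (%s)%s\n", x$sigma, x$method,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

sigma_value <- function(sigma) {
  s <- if (inherits(sigma, "noise_estimate")) sigma$sigma else as.numeric(sigma)
  if (!is.finite(s) || s <= 0) abort("sigma must be > 0 for Z metrics")
  s
}

# ---- CCP4/MRC mode-2 map input/output -------------------------------------
# Minimal single-volume reader/writer: 1024-byte header, float32 data,
# column axis = x, row = y, section = z (MAPC/MAPR/MAPS = 1/2/3), origin
# carried in the MRC ORIGIN fields (words 50-52).

#' Read a CCP4/MRC density map (mode 2)
#'
#' @param path Path to a `.ccp4`/`.mrc` map file.
#' @return A [density_grid()].
#' @export
read_ccp4 <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hi <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hf <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hi[1:3]; mode <- hi[4]
  if (mode != 2) abort(sprintf("unsupported MRC mode %d (only mode 2)", mode))
  mxyz <- hi[8:10]; cell <- hf[11:16]
  mapcrs <- hi[17:19]
  if (!identical(mapcrs, 1:3)) {
    abort("unsupported axis order (only MAPC/MAPR/MAPS = 1/2/3)")
  }
  if (any(abs(cell[4:6] - 90) > 1e-3)) abort("non-orthorhombic cell in map")
  origin <- hf[50:52]
  nsymbt <- hi[24]
  seek(con, 1024 + nsymbt)
  v <- readBin(con, "numeric", n = prod(nxyz), size = 4, endian = "little")
  density_grid(array(v, dim = nxyz), spacing = cell[1:3] / mxyz,
               origin = origin, cell = cell[1:3])
}

#' Write a density grid as a CCP4/MRC map (mode 2)
#'
#' @param grid A [density_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ccp4 <- function(grid, path) {
  d <- dim(grid$values)
  hi <- integer(256); hf <- numeric(256)
  hi[1:3] <- d; hi[4] <- 2L
  hi[5:7] <- 0L
  hi[8:10] <- d
  hf[11:13] <- d * grid$spacing; hf[14:16] <- 90
  hi[17:19] <- 1:3
  hf[20] <- min(grid$values); hf[21] <- max(grid$values)
  hf[22] <- mean(grid$values)
  hi[23] <- 1L   # space group P1
  hi[24] <- 0L   # no symmetry records
  hf[50:52] <- grid$origin
  hi[53] <- readBin(charToRaw("MAP "), "integer", size = 4)
  hi[54] <- readBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), "integer", size = 4)
  hf[55] <- sd(as.numeric(grid$values))
  con <- file(path, "wb"); on.exit(close(con))
  float_words <- c(11:16, 20:22, 50:52, 55)
  for (w in 1:256) {
    if (w %in% float_words) {
      writeBin(hf[w], con, size = 4, endian = "little")
    } else {
      writeBin(hi[w], con, size = 4, endian = "little")
    }
  }
  writeBin(as.numeric(grid$values), con, size = 4, endian = "little")
  invisible(path)
}
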