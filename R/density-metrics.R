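#' Voxel mask around a residue
#'
#' Selects the voxels whose centres lie within `radius` of any chosen atom
#' of the residue. The 2.0 A default matches the clipping radius
#' conventionally used when inspecting density around a residue.
#'
#' @param model A [struct_model()].
#' @param residue One-row residue selection (`chain`, `resno`, `ins`).
#' @param grid A [density_grid()] supplying the geometry.
#' @param radius Capture radius in angstrom, default 2.0.
#' @param altlocs Optional altloc filter for the generating atoms (e.g.
#'   `"B"` for the triggered conformer).
#' @return A `residue_mask`: list with `index` (linear voxel indices into
#'   the grid), `radius`, `residue`, `altlocs`.
#' @export
residue_mask <- function(model, residue, grid, radius = 2.0, altlocs = NULL) {
  if (radius <= 0) abort("radius must be > 0")
  residue <- as_tibble(residue)
  if (!"ins" %in% names(residue)) residue$ins <- ""
  stopifnot(nrow(residue) == 1)
  a <- as_tibble(model)
  a <- a[a$chain == residue$chain & a$resno == residue$resno &
           a$ins == residue$ins, ]
  if (nrow(a) == 0) {
    abort(sprintf("residue %s:%d%s not found in model", residue$chain,
                  residue$resno, residue$ins))
  }
  if (!is.null(altlocs)) a <- a[a$altloc %in% altlocs, ]
  if (nrow(a) == 0) abort("no atoms left after altloc filtering")
  ax <- grid_axes(grid)
  d <- dim(grid$values)
  sel <- logical(prod(d))
  for (i in seq_len(nrow(a))) {
    rx <- which(abs(ax$x - a$x[i]) <= radius)
    ry <- which(abs(ax$y - a$y[i]) <= radius)
    rz <- which(abs(ax$z - a$z[i]) <= radius)
    if (!length(rx) || !length(ry) || !length(rz)) next
    dx2 <- (ax$x[rx] - a$x[i])^2
    dy2 <- (ax$y[ry] - a$y[i])^2
    dz2 <- (ax$z[rz] - a$z[i])^2
    within <- outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
    idx <- which(within, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      lin <- rx[idx[, 1]] + (ry[idx[, 2]] - 1L) * d[1] +
        (rz[idx[, 3]] - 1L) * d[1] * d[2]
      sel[lin] <- TRUE
    }
  }
  index <- which(sel)
  if (length(index) == 0) {
    abort("empty mask: residue atoms lie outside the grid or radius too small")
  }
  structure(list(index = index, radius = radius,
                 residue = residue[, c("chain", "resno", "ins")],
                 altlocs = altlocs),
            class = "residue_mask")
}

#' Real-space correlation coefficient over a mask
#'
#' Pearson correlation of observed vs calculated density over the masked
#' voxels; values above 0.7 indicate a strong model-to-map match.
#'
#' @param obs,calc [density_grid()]s on identical geometry.
#' @param mask A [residue_mask()].
#' @return Correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   grid has zero variance within the mask.
#' @export
rscc <- function(obs, calc, mask) {
  if (!same_geometry(obs, calc)) abort("grid geometries differ")
  if (length(mask$index) < 2) abort("mask must contain at least 2 voxels")
  o <- obs$values[mask$index]
  c_ <- calc$values[mask$index]
  if (sd(o) == 0 || sd(c_) == 0) {
    warn("zero variance within mask: RSCC undefined")
    return(NA_real_)
  }
  cor(o, c_)
}

#' Real-space Z-observed score over a mask
#'
#' Mean observed density over the residue mask divided by the map noise;
#' values above 2 indicate well-resolved density.
#'
#' @param obs A [density_grid()].
#' @param mask A [residue_mask()].
#' @param sigma A noise estimate from [estimate_sigma()] (or a number).
#' @return Dimensionless Z value.
#' @export
rszo <- function(obs, mask, sigma) {
  mean(obs$values[mask$index]) / sigma_value(sigma)
}

#' Real-space Z-difference scores over a mask
#'
#' Peak-Z summary of residual difference density around a residue:
#' `rszd_plus` is the largest positive difference-map Z within the mask and
#' `rszd_minus` the magnitude of the most negative one (both clamped at 0).
#' Scores below 3 indicate no significant unmodelled difference density.
#'
#' @param diff Difference [density_grid()].
#' @param mask A [residue_mask()].
#' @param sigma Noise estimate for the difference map.
#' @return Named list `rszd_plus`, `rszd_minus` (both >= 0).
#' @export
rszd <- function(diff, mask, sigma) {
  s <- sigma_value(sigma)
  v <- diff$values[mask$index] / s
  list(rszd_plus = max(0, max(v)), rszd_minus = max(0, -min(v)))
}

#' Per-residue density metrics for a model
#'
#' Convenience wrapper computing RSCC, RSZO and RSZD+/- for every residue
#' in a selection, using the triggered conformer's atoms (altloc `"B"`,
#' falling back to all atoms when the residue has no altloc `"B"`) to
#' generate the masks.
#'
#' @param model A [struct_model()].
#' @param obs Observed map ([density_grid()]).
#' @param calc Calculated model map.
#' @param diff Difference map for the RSZD terms.
#' @param selection Residues to evaluate.
#' @param radius Mask radius, angstrom.
#' @param sigma_method Noise convention for [estimate_sigma()].
#' @param mask_altlocs Altloc filter for mask generation, default `"B"`.
#' @return Tibble with one row per residue: `chain`, `resno`, `ins`,
#'   `rscc`, `rszo`, `rszd_plus`, `rszd_minus`.
#' @export
residue_density_metrics <- function(model, obs, calc, diff, selection,
                                    radius = 2.0,
                                    sigma_method = c("rms", "mad"),
                                    mask_altlocs = "B") {
  selection <- check_selection(model, selection)
  sig_obs <- estimate_sigma(obs, match.arg(sigma_method))
  sig_diff <- estimate_sigma(diff, match.arg(sigma_method))
  a <- as_tibble(model)
  rows <- purrr::pmap(selection, function(chain, resno, ins) {
    has_b <- any(a$chain == chain & a$resno == resno & a$ins == ins &
                   a$altloc %in% mask_altlocs)
    m <- residue_mask(model, tibble(chain = chain, resno = resno, ins = ins),
                      obs, radius = radius,
                      altlocs = if (has_b) mask_altlocs else NULL)
    zd <- rszd(diff, m, sig_diff)
    tibble(chain = chain, resno = resno, ins = ins,
           rscc = rscc(obs, calc, m),
           rszo = rszo(obs, m, sig_obs),
           rszd_plus = zd$rszd_plus, rszd_minus = zd$rszd_minus)
  })
  bind_rows(rows)
}

#' Per-residue isomorphous difference-density weights
#'
#' Flags every voxel whose absolute difference-map Z meets `z_threshold`
#' (3 by default, the conventional contouring level), assigns it to the
#' selected residue owning the nearest atom, and accumulates the positive
#' and negative density sums per residue. Voxels nearer to an unselected
#' residue, or farther than `capture_radius` from every selected atom, are
#' discarded. The sums weight the per-residue RSZD terms in the composite
#' density score.
#'
#' @param diff Difference [density_grid()].
#' @param model A [struct_model()] giving atom positions.
#' @param selection Residues eligible to receive weight.
#' @param z_threshold Minimum |Z| for a voxel to carry weight, default 3.
#' @param sigma Noise estimate for the difference map (default: rms).
#' @param capture_radius Maximum voxel-to-atom distance, angstrom.
#' @return Tibble with `chain`, `resno`, `ins`, `rho_pos`, `rho_neg` (one
#'   row per selected residue; all-zero rows kept), with attribute `"m"` =
#'   number of weighted residues. All-zero output triggers a warning.
#' @export
residue_difference_weights <- function(diff, model, selection,
                                       z_threshold = 3.0, sigma = NULL,
                                       capture_radius = 3.5) {
  selection <- check_selection(model, selection)
  if (is.null(sigma)) sigma <- estimate_sigma(diff)
  s <- sigma_value(sigma)
  a <- as_tibble(model)
  akey <- paste(a$chain, a$resno, a$ins, sep = "\r")
  skey <- paste(selection$chain, selection$resno, selection$ins, sep = "\r")
  sel_atom <- akey %in% skey

  zero <- tibble(chain = selection$chain, resno = selection$resno,
                 ins = selection$ins, rho_pos = 0, rho_neg = 0)
  hot <- which(abs(diff$values) / s >= z_threshold)
  if (length(hot) == 0) {
    warn("no voxel exceeds the Z threshold: all difference-density weights are zero")
    attr(zero, "m") <- nrow(selection)
    return(zero)
  }
  d <- dim(diff$values)
  ijk <- arrayInd(hot, d)
  ax <- grid_axes(diff)
  vx <- cbind(ax$x[ijk[, 1]], ax$y[ijk[, 2]], ax$z[ijk[, 3]])
  pos <- as.matrix(a[, c("x", "y", "z")])
  # nearest atom over the whole model; ties cannot matter for ownership sums
  d2 <- outer(rowSums(vx^2), rep(1, nrow(pos))) +
    outer(rep(1, nrow(vx)), rowSums(pos^2)) - 2 * vx %*% t(pos)
  nearest <- max.col(-d2, ties.method = "first")
  ndist <- sqrt(pmax(0, d2[cbind(seq_len(nrow(vx)), nearest)]))
  keep <- sel_atom[nearest] & ndist <= capture_radius
  out <- zero
  if (any(keep)) {
    owner <- akey[nearest[keep]]
    val <- diff$values[hot[keep]]
    pos_sum <- tapply(pmax(val, 0), owner, sum)
    neg_sum <- tapply(pmax(-val, 0), owner, sum)
    okey <- paste(out$chain, out$resno, out$ins, sep = "\r")
    out$rho_pos <- as.numeric(pos_sum[okey]); out$rho_pos[is.na(out$rho_pos)] <- 0
    out$rho_neg <- as.numeric(neg_sum[okey]); out$rho_neg[is.na(out$rho_neg)] <- 0
  } else {
    warn("no voxel exceeds the Z threshold: all difference-density weights are zero")
  }
  attr(out, "m") <- nrow(selection)
  out
}
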