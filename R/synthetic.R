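#' Specification for a synthetic two-state dataset
#'
#' Bundles the study conditions for the desk-scale simulator: a toy
#' protein, a triggered-residue selection, the true triggered-state
#' occupancy, the map noise level, and the decoy-ensemble composition.
#' Defaults mirror the canonical workflow conditions: triggered occupancy
#' 0.25, 200 decoy conformers of which 10 are near-truth.
#'
#' @param n_residues Residues in the toy structure, default 20.
#' @param motif Backbone motif, `"helix"` or `"strand"`.
#' @param spacing Map voxel size in angstrom, default 0.6.
#' @param selection Triggered residues; default the three central residues.
#' @param q_true True triggered-conformer occupancy in (0, 1), default 0.25.
#' @param noise Map noise sigma as a fraction of the reference map rms,
#'   default 0.05.
#' @param n_decoys Total decoy conformers, default 200.
#' @param n_near Number of near-truth decoys among them, default 10.
#' @param near_scale Per-atom Gaussian sd added to the truth for near
#'   decoys, angstrom, default 0.05.
#' @param far_scale Per-atom Gaussian sd added to the reference for far
#'   decoys, angstrom, default 0.5.
#' @param truth_shift Rigid displacement of each triggered residue defining
#'   the planted truth, angstrom, default 1.0.
#' @param seed Integer seed recorded in every derived output.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(n_residues = 20, motif = "helix", spacing = 0.6,
                            selection = NULL, q_true = 0.25, noise = 0.05,
                            n_decoys = 200, n_near = 10, near_scale = 0.05,
                            far_scale = 0.5, truth_shift = 1.0, seed = 1) {
  if (!(q_true > 0 && q_true < 1)) abort("q_true must lie in (0, 1)")
  if (noise < 0) abort("noise must be >= 0")
  if (n_near > n_decoys) abort("n_near cannot exceed n_decoys")
  if (is.null(selection)) {
    mid <- ceiling(n_residues / 2)
    selection <- residue_selection("A", (mid - 1):(mid + 1))
  }
  structure(list(n_residues = n_residues, motif = motif, spacing = spacing,
                 selection = selection, q_true = q_true, noise = noise,
                 n_decoys = n_decoys, n_near = n_near,
                 near_scale = near_scale, far_scale = far_scale,
                 truth_shift = truth_shift, seed = as.integer(seed)),
            class = "simulation_spec")
}

# internal-coordinate atom placement (NeRF): D bonded to C, with bond
# length r, angle theta at C (deg), torsion phi about B-C (deg)
place_atom <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2], ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2], n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  C + r * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

#' Build an ideal-geometry poly-alanine toy structure
#'
#' Constructs a poly-alanine chain (N, CA, C, O, CB per residue) with every
#' bond length and angle exactly at the packaged ideal values, backbone
#' torsions set by the chosen motif (helix: phi -57, psi -47; strand:
#' phi -120, psi 120). The structure is fully determined by its arguments,
#' so repeated calls are identical; the seed is accepted for manifest
#' uniformity. Coordinates are shifted into a padded P1 box.
#'
#' @param n_residues Number of residues (>= 3).
#' @param motif `"helix"` or `"strand"`.
#' @param seed Recorded seed (the builder itself is deterministic).
#' @param b_factor Uniform B-factor assigned to every atom, default 15.
#' @return A [struct_model()].
#' @export
make_toy_structure <- function(n_residues, motif = c("helix", "strand"),
                               seed = 1, b_factor = 15) {
  motif <- match.arg(motif)
  if (n_residues < 3) abort("n_residues must be >= 3")
  tbl <- ideal_geometry_table()
  bl <- function(a1, a2) tbl$bonds$length[tbl$bonds$atom1 == a1 &
                                            tbl$bonds$atom2 == a2][1]
  an <- function(a1, a2, a3) {
    tbl$angles$angle[tbl$angles$atom1 == a1 & tbl$angles$atom2 == a2 &
                       tbl$angles$atom3 == a3][1]
  }
  tors <- if (motif == "helix") c(phi = -57, psi = -47) else
    c(phi = -120, psi = 120)
  r_NCA <- bl("N", "CA"); r_CAC <- bl("CA", "C"); r_CO <- bl("C", "O")
  r_CACB <- bl("CA", "CB"); r_CN <- bl("C", "N+")
  a_NCAC <- an("N", "CA", "C"); a_CACO <- an("CA", "C", "O")
  a_NCACB <- an("N", "CA", "CB"); a_CACN <- an("CA", "C", "N+")
  a_CNCA <- an("C", "N+", "CA+")

  N <- CA <- C <- O <- CB <- matrix(NA_real_, n_residues, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(r_NCA, 0, 0)
  ang <- a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + r_CAC * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], r_CN,
                           a_CACN, tors["psi"])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], r_NCA,
                            a_CNCA, 180)  # omega trans
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], r_CAC,
                           a_NCAC, tors["phi"])
    }
    # carbonyl O anti to the next N across the planar peptide group
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], r_CO, a_CACO,
                         tors["psi"] + 180)
    # L-configuration branch: the improper torsion C-N-CA-CB is -122.6 deg
    CB[i, ] <- place_atom(C[i, ], N[i, ], CA[i, ], r_CACB, a_NCACB, -122.6)
  }
  per_res <- function(i) {
    tibble(chain = "A", resno = i, ins = "", resname = "ALA",
           atom = c("N", "CA", "C", "O", "CB"),
           altloc = "", element = c("N", "C", "C", "O", "C"),
           x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1], CB[i, 1]),
           y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2], CB[i, 2]),
           z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3], CB[i, 3]),
           occ = 1, b = b_factor)
  }
  atoms <- bind_rows(lapply(seq_len(n_residues), per_res))
  pad <- 6
  for (col in c("x", "y", "z")) atoms[[col]] <- atoms[[col]] -
      min(atoms[[col]]) + pad
  span <- vapply(atoms[, c("x", "y", "z")], max, numeric(1)) + pad
  m <- struct_model(atoms, cell = c(span, 90, 90, 90))
  attr(m, "seed") <- as.integer(seed)
  m
}

# displace the selected residues' atoms of `model`; each residue gets one
# rigid translation of length `shift` in a seeded random direction
displace_selection <- function(model, selection, shift, rng_offset = 0) {
  a <- as_tibble(model)
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  sel <- as_tibble(selection)
  if (!"ins" %in% names(sel)) sel$ins <- ""
  skey <- paste(sel$chain, sel$resno, sel$ins, sep = "\r")
  for (k in skey) {
    v <- rnorm(3)
    v <- v / sqrt(sum(v^2)) * shift
    rows <- key == k
    a$x[rows] <- a$x[rows] + v[1]
    a$y[rows] <- a$y[rows] + v[2]
    a$z[rows] <- a$z[rows] + v[3]
  }
  rebuild_model(a, model)
}

jitter_selection <- function(model, selection, sd) {
  if (sd <= 0) return(model)
  a <- as_tibble(model)
  key <- paste(a$chain, a$resno, a$ins, sep = "\r")
  sel <- as_tibble(selection)
  if (!"ins" %in% names(sel)) sel$ins <- ""
  rows <- key %in% paste(sel$chain, sel$resno, sel$ins, sep = "\r")
  n <- sum(rows)
  a$x[rows] <- a$x[rows] + rnorm(n, 0, sd)
  a$y[rows] <- a$y[rows] + rnorm(n, 0, sd)
  a$z[rows] <- a$z[rows] + rnorm(n, 0, sd)
  rebuild_model(a, model)
}

sel_rmsd <- function(a, b, selection) {
  at <- as_tibble(a); bt <- as_tibble(b)
  sel <- as_tibble(selection)
  if (!"ins" %in% names(sel)) sel$ins <- ""
  at <- inner_join(at, sel[, c("chain", "resno", "ins")],
                   by = c("chain", "resno", "ins"))
  bt <- inner_join(bt, sel[, c("chain", "resno", "ins")],
                   by = c("chain", "resno", "ins"))
  j <- inner_join(at, bt, by = c("chain", "resno", "ins", "atom"),
                  suffix = c("_a", "_b"))
  sqrt(mean((j$x_a - j$x_b)^2 + (j$y_a - j$y_b)^2 + (j$z_a - j$z_b)^2))
}

#' Generate a decoy conformer ensemble with a planted truth
#'
#' Defines the true triggered conformer as the reference with each
#' triggered residue rigidly displaced by `truth_shift`, then draws
#' `n_decoys` candidate conformers: `n_near` of them are the truth plus
#' per-atom Gaussian noise at `near_scale`, the rest are the reference
#' perturbed at `far_scale` (reference-like decoys). Only the triggered
#' residues differ between frames; the remainder of the chain is the
#' reference in every frame.
#'
#' @param reference Reference [struct_model()].
#' @param spec A [simulation_spec()] (supplies the selection and scales).
#' @return List: `truth` (the planted conformer), `frames` (named list of
#'   models), `manifest` (tibble `frame`, `class`, `rmsd_to_truth`), and
#'   `seed`.
#' @export
make_decoy_ensemble <- function(reference, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  sel <- check_selection(reference, spec$selection)
  truth <- displace_selection(reference, sel, spec$truth_shift)
  classes <- sample(rep(c("near", "far"),
                        c(spec$n_near, spec$n_decoys - spec$n_near)))
  frames <- vector("list", spec$n_decoys)
  names(frames) <- sprintf("frame_%04d", seq_len(spec$n_decoys))
  for (i in seq_len(spec$n_decoys)) {
    frames[[i]] <- if (classes[i] == "near") {
      jitter_selection(truth, sel, spec$near_scale)
    } else {
      jitter_selection(reference, sel, spec$far_scale)
    }
  }
  manifest <- tibble(frame = names(frames), class = classes,
                     rmsd_to_truth = map_dbl(frames, sel_rmsd, b = truth,
                                             selection = sel))
  list(truth = truth, frames = frames, manifest = manifest, seed = spec$seed)
}

#' Simulate reference and triggered two-state mixture maps
#'
#' The reference map is the reference model's density plus voxel noise;
#' the triggered map is the occupancy-weighted mixture
#' `(1 - q_true) * rho_A + q_true * rho_B` plus an independent noise draw.
#' Noise is i.i.d. Gaussian per voxel with sd `noise * rms(rho_A)`
#' (spatially uncorrelated -- adequate for metric testing, not a model of
#' real map error). With zero noise the returned difference map equals
#' `q_true * (rho_B - rho_A)` identically.
#'
#' @param reference Reference model (conformer A).
#' @param truth Triggered-state model (conformer B), same atom inventory.
#' @param spec A [simulation_spec()].
#' @return List: `map_ref`, `map_trig`, `diff` (trig - ref), `rho_A`,
#'   `rho_B` (noise-free model densities), `sigma_noise`, `spec`.
#' @export
simulate_two_state_maps <- function(reference, truth, spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (nrow(reference) != nrow(truth)) {
    abort("reference and truth atom inventories differ")
  }
  rho_A <- compute_model_density(reference, spacing = spec$spacing)
  rho_B <- compute_model_density(truth, grid = rho_A)
  sigma_noise <- spec$noise * sqrt(mean(rho_A$values^2))
  set.seed(spec$seed + 1L)
  noise1 <- if (spec$noise > 0) array(rnorm(length(rho_A$values), 0, sigma_noise),
                                      dim(rho_A$values)) else 0
  noise2 <- if (spec$noise > 0) array(rnorm(length(rho_A$values), 0, sigma_noise),
                                      dim(rho_A$values)) else 0
  map_ref <- density_grid(rho_A$values + noise1, spacing = rho_A$spacing,
                          origin = rho_A$origin, cell = rho_A$cell)
  map_trig <- density_grid((1 - spec$q_true) * rho_A$values +
                             spec$q_true * rho_B$values + noise2,
                           spacing = rho_A$spacing, origin = rho_A$origin,
                           cell = rho_A$cell)
  list(map_ref = map_ref, map_trig = map_trig,
       diff = difference_grid(map_trig, map_ref),
       rho_A = rho_A, rho_B = rho_B, sigma_noise = sigma_noise, spec = spec)
}

#' Closed-form mock occupancy refinement
#'
#' Stands in for external reciprocal-space occupancy refinement: finds the
#' occupancy q minimizing `sum((map_trig - (1-q) rho_A - q rho_B)^2)` over
#' all voxels. The minimizer is linear least squares in q, solved in closed
#' form and clamped to `[0, 1]`; coordinates are not adjusted (coordinate
#' refinement is the externalized step, pluggable via
#' [run_external_refiner()]).
#'
#' @param merged Merged two-state model whose occupancies are updated.
#' @param map_trig Observed triggered-state map.
#' @param rho_A,rho_B Conformer model densities on the same grid.
#' @param labels Altloc labels `c(A, B)` of the merged model.
#' @return List: `q_hat` and `model` (merged model with occupancies
#'   `1 - q_hat` / `q_hat` on the two conformers).
#' @export
mock_refine_occupancy <- function(merged, map_trig, rho_A, rho_B,
                                  labels = c("A", "B")) {
  if (!same_geometry(map_trig, rho_A) || !same_geometry(map_trig, rho_B)) {
    abort("grids must share geometry")
  }
  delta <- rho_B$values - rho_A$values
  ss <- sum(delta^2)
  if (ss == 0) abort("rho_A and rho_B are identical: occupancy unidentifiable")
  q_hat <- sum((map_trig$values - rho_A$values) * delta) / ss
  q_hat <- min(1, max(0, q_hat))
  a <- as_tibble(merged)
  a$occ[a$altloc == labels[1]] <- 1 - q_hat
  a$occ[a$altloc == labels[2]] <- q_hat
  list(q_hat = q_hat, model = rebuild_model(a, merged))
}
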