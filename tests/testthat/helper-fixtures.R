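# shared fixtures: built in code, never stored on disk

# minimal hand-built model: atoms at given coordinates, one residue per
# `resno`, all carbons unless stated
atom_row <- function(chain = "A", resno = 1, atom = "CA", x = 0, y = 0,
                     z = 0, altloc = "", element = "C", occ = 1, b = 10,
                     resname = "ALA") {
  tibble::tibble(chain = chain, resno = resno, ins = "", resname = resname,
                 atom = atom, altloc = altloc, element = element,
                 x = x, y = y, z = z, occ = occ, b = b)
}

tiny_model <- function(rows, cell = c(30, 30, 30, 90, 90, 90)) {
  struct_model(dplyr::bind_rows(rows), cell = cell)
}

# random density grid on a small box
random_grid <- function(dims = c(12, 10, 11), spacing = 0.7, seed = 1) {
  set.seed(seed)
  density_grid(array(rnorm(prod(dims)), dims), spacing = spacing)
}

# brute-force Pearson correlation over masked voxels
bf_pearson <- function(obs, calc, idx) {
  o <- obs$values[idx]; c_ <- calc$values[idx]
  mo <- mean(o); mc <- mean(c_)
  sum((o - mo) * (c_ - mc)) /
    sqrt(sum((o - mo)^2) * sum((c_ - mc)^2))
}

# brute-force mask: scan every voxel centre against every atom
bf_mask <- function(model, residue, grid, radius, altlocs = NULL) {
  a <- tibble::as_tibble(model)
  a <- a[a$chain == residue$chain & a$resno == residue$resno &
           a$ins == (residue$ins %||% ""), ]
  if (!is.null(altlocs)) a <- a[a$altloc %in% altlocs, ]
  d <- dim(grid$values)
  ax <- list(x = grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1],
             y = grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2],
             z = grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3])
  keep <- integer(0)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- c(ax$x[i], ax$y[j], ax$z[k])
    dmin <- min(sqrt((p[1] - a$x)^2 + (p[2] - a$y)^2 + (p[3] - a$z)^2))
    if (dmin <= radius) keep <- c(keep, i + (j - 1) * d[1] +
                                    (k - 1) * d[1] * d[2])
  }
  sort(keep)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small protein-like model built from the toy generator plus noise
noisy_toy <- function(n = 6, sd = 0.3, seed = 1) {
  m <- make_toy_structure(n)
  set.seed(seed)
  a <- tibble::as_tibble(m)
  a$x <- a$x + rnorm(nrow(a), 0, sd)
  a$y <- a$y + rnorm(nrow(a), 0, sd)
  a$z <- a$z + rnorm(nrow(a), 0, sd)
  struct_model(a, cell = attr(m, "cell"))
}

# 3-model metric batch exercising every scoring column
batch_metrics <- function() {
  tibble::tibble(
    model_id = c("m1", "m2", "m3"),
    r_work = c(0.18, 0.19, 0.20), r_free = c(0.20, 0.25, 0.30),
    molprobity_score = c(1.0, 1.5, 2.0),
    ramachandran_outliers = c(0, 1, 2), rotamer_outliers = c(0, 2, 4),
    cbeta_outliers = c(0, 0.5, 1), rms_bond = c(0.01, 0.02, 0.03),
    rms_angle = c(1.0, 1.5, 2.0), clashscore = c(0, 10, 20),
    rmsd_ab = c(0.5, 1.0, 1.5))
}

batch_residue_metrics <- function() {
  tidyr::expand_grid(model_id = c("m1", "m2", "m3"),
                     tibble::tibble(chain = "A", resno = c(10L, 11L),
                                    ins = "")) |>
    dplyr::mutate(rscc = c(0.9, 0.8, 0.8, 0.7, 0.7, 0.6),
                  rszo = c(3, 2.5, 2.5, 2, 2, 1.5),
                  rszd_plus = c(0.5, 0.2, 1.5, 0.0, 2.5, 1.0),
                  rszd_minus = c(0.1, 0.3, 0.0, 3.0, 1.0, 2.0))
}

batch_weights <- function() {
  w <- tibble::tibble(chain = "A", resno = c(10L, 11L), ins = "",
                      rho_pos = c(2, 0), rho_neg = c(0, 1))
  attr(w, "m") <- 2L
  w
}
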