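test_that("residue masks capture exactly the voxels within the radius", {
  g <- random_grid(dims = c(15, 14, 13), spacing = 0.5, seed = 2)
  # atom sitting exactly on a voxel centre
  m <- tiny_model(list(atom_row(x = 2.0, y = 1.5, z = 2.5)),
                  cell = c(7.5, 7, 6.5, 90, 90, 90))
  res <- residue_selection("A", 1)
  tinym <- residue_mask(m, res, g, radius = 0.04)
  expect_equal(length(tinym$index), 1L)
  # doubling the radius gives a superset
  m1 <- residue_mask(m, res, g, radius = 1.2)
  m2 <- residue_mask(m, res, g, radius = 2.4)
  expect_true(all(m1$index %in% m2$index))
  # brute-force all-voxel scan oracle, several radii and residues
  mod <- noisy_toy(4, sd = 0.1, seed = 3)
  gg <- compute_model_density(mod, spacing = 0.7)
  for (r in c(1.0, 2.0, 3.1)) {
    got <- residue_mask(mod, residue_selection("A", 2), gg, radius = r)
    want <- bf_mask(mod, list(chain = "A", resno = 2, ins = ""), gg, r)
    expect_equal(sort(got$index), want)
  }
  expect_error(residue_mask(m, residue_selection("A", 9), g), "not found")
  expect_error(residue_mask(m, res, g, radius = -1), "radius")
})

test_that("RSCC matches brute-force Pearson and handles degeneracy", {
  obs <- random_grid(seed = 10); calc <- random_grid(seed = 11)
  idx <- sort(sample(length(obs$values), 50))
  mask <- structure(list(index = idx), class = "residue_mask")
  expect_equal(rscc(obs, obs, mask), 1.0)
  neg <- density_grid(-obs$values, obs$spacing)
  expect_equal(rscc(obs, neg, mask), -1.0)
  expect_lt(abs(rscc(obs, calc, mask) - bf_pearson(obs, calc, idx)), 1e-12)
  flat <- density_grid(array(1, dim(obs$values)), obs$spacing)
  expect_warning(v <- rscc(obs, flat, mask), "zero variance")
  expect_true(is.na(v))
})

test_that("RSZO is the masked mean in noise units", {
  g <- random_grid(seed = 12)
  idx <- sort(sample(length(g$values), 40))
  mask <- structure(list(index = idx), class = "residue_mask")
  zero <- density_grid(array(0, dim(g$values)), g$spacing)
  expect_equal(rszo(zero, mask, 1.3), 0)
  const <- density_grid(array(2 * 0.8, dim(g$values)), g$spacing)
  expect_equal(rszo(const, mask, 0.8), 2.0)
  expect_lt(abs(rszo(g, mask, 0.7) - mean(g$values[idx]) / 0.7), 1e-12)
})

test_that("RSZD reports signed peak Z magnitudes", {
  dims <- c(10, 10, 10)
  zero <- density_grid(array(0, dims), 0.5)
  idx <- 101:160
  mask <- structure(list(index = idx), class = "residue_mask")
  z <- rszd(zero, mask, 1)
  expect_equal(c(z$rszd_plus, z$rszd_minus), c(0, 0))
  v <- array(0, dims); v[120] <- 5
  z <- rszd(density_grid(v, 0.5), mask, 1)
  expect_equal(c(z$rszd_plus, z$rszd_minus), c(5, 0))
  g <- random_grid(dims = dims, seed = 13)
  z <- rszd(g, mask, 0.9)
  expect_lt(abs(z$rszd_plus - max(0, max(g$values[idx] / 0.9))), 1e-12)
  expect_lt(abs(z$rszd_minus - max(0, -min(g$values[idx] / 0.9))), 1e-12)
})

test_that("difference weights localize to the residue owning the signal", {
  ref <- make_toy_structure(8)
  sel <- residue_selection("A", c(3, 6))
  grid <- compute_model_density(ref, spacing = 0.6)
  # blob 1 A from residue 3's CA, far from residue 6
  a <- tibble::as_tibble(ref)
  ca3 <- a[a$resno == 3 & a$atom == "CA", ]
  v <- array(0, dim(grid$values))
  ax <- trxscore:::grid_axes(grid)
  i <- which.min(abs(ax$x - (ca3$x + 1)))
  j <- which.min(abs(ax$y - ca3$y)); k <- which.min(abs(ax$z - ca3$z))
  v[i, j, k] <- 10
  blob <- density_grid(v, grid$spacing, origin = grid$origin)
  w <- residue_difference_weights(blob, ref, sel, z_threshold = 3, sigma = 1)
  expect_gt(w$rho_pos[w$resno == 3], 0)
  expect_equal(w$rho_pos[w$resno == 6], 0)
  expect_equal(sum(w$rho_neg), 0)
  # zero map: all-zero weights plus a warning
  zero <- density_grid(array(0, dim(v)), grid$spacing, origin = grid$origin)
  expect_warning(w0 <- residue_difference_weights(zero, ref, sel, sigma = 1),
                 "zero")
  expect_equal(sum(w0$rho_pos) + sum(w0$rho_neg), 0)
  expect_equal(attr(w0, "m"), 2L)
})

test_that("weight assignment matches a brute-force nearest-atom scan", {
  ref <- make_toy_structure(6)
  sel <- residue_selection("A", c(2, 4))
  a <- tibble::as_tibble(ref)
  a$x[a$resno %in% c(2, 4)] <- a$x[a$resno %in% c(2, 4)] + 1
  truth <- struct_model(a, cell = model_cell(ref))
  rho_A <- compute_model_density(ref, spacing = 0.6)
  rho_B <- compute_model_density(truth, grid = rho_A)
  diff <- density_grid(0.25 * (rho_B$values - rho_A$values), rho_A$spacing,
                       origin = rho_A$origin)
  sig <- estimate_sigma(diff)
  zt <- 3; cap <- 3.5
  w <- residue_difference_weights(diff, ref, sel, z_threshold = zt,
                                  sigma = sig, capture_radius = cap)
  # oracle: per-voxel scan over every atom of the model
  at <- tibble::as_tibble(ref)
  d <- dim(diff$values)
  ax <- trxscore:::grid_axes(diff)
  rp <- rn <- setNames(numeric(2), c(2, 4))
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    val <- diff$values[i, j, k]
    if (abs(val) / sig$sigma < zt) next
    p <- c(ax$x[i], ax$y[j], ax$z[k])
    dist <- sqrt((p[1] - at$x)^2 + (p[2] - at$y)^2 + (p[3] - at$z)^2)
    b <- which.min(dist)
    if (dist[b] > cap) next
    if (!at$resno[b] %in% c(2, 4)) next
    key <- as.character(at$resno[b])
    if (val > 0) rp[key] <- rp[key] + val else rn[key] <- rn[key] - val
  }
  expect_equal(w$rho_pos, unname(rp), tolerance = 1e-12)
  expect_equal(w$rho_neg, unname(rn), tolerance = 1e-12)
})

test_that("weights are monotone in the threshold and scale invariant", {
  ref <- make_toy_structure(6)
  sel <- residue_selection("A", 2:5)
  g <- compute_model_density(ref, spacing = 0.7)
  set.seed(8)
  diff <- density_grid(g$values - mean(g$values) +
                         rnorm(length(g$values), 0, 0.01),
                       g$spacing, origin = g$origin)
  sig <- estimate_sigma(diff)
  prev <- NULL
  for (zt in c(1, 2, 4, 8)) {
    w <- suppressWarnings(residue_difference_weights(diff, ref, sel,
                                                     z_threshold = zt,
                                                     sigma = sig))
    if (!is.null(prev)) {
      expect_true(all(w$rho_pos <= prev$rho_pos + 1e-12))
      expect_true(all(w$rho_neg <= prev$rho_neg + 1e-12))
    }
    prev <- w
  }
  # scaling diff and sigma together keeps voxel membership (weights scale)
  w1 <- residue_difference_weights(diff, ref, sel, z_threshold = 2,
                                   sigma = sig$sigma)
  diff7 <- density_grid(7 * diff$values, diff$spacing, origin = diff$origin)
  w7 <- residue_difference_weights(diff7, ref, sel, z_threshold = 2,
                                   sigma = 7 * sig$sigma)
  expect_equal(w7$rho_pos, 7 * w1$rho_pos, tolerance = 1e-9)
  expect_equal(w7$rho_neg, 7 * w1$rho_neg, tolerance = 1e-9)
})

test_that("self-density is the perfect-model limit", {
  ref <- make_toy_structure(5)
  g <- compute_model_density(ref, spacing = 0.6)
  for (rn in 1:5) {
    mask <- residue_mask(ref, residue_selection("A", rn), g, radius = 2.0)
    expect_equal(rscc(g, g, mask), 1.0)
    zd <- rszd(difference_grid(g, g), mask, 1)
    expect_equal(c(zd$rszd_plus, zd$rszd_minus), c(0, 0))
  }
})
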