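test_that("min-max scaling maps the pool onto [0, 1]", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(7, 7, 7)), c(0, 0, 0))
  set.seed(1)
  v <- rnorm(100)
  nv <- minmax_normalize(v)
  expect_equal(nv, (v - min(v)) / (max(v) - min(v)), tolerance = 1e-15)
  expect_equal(min(nv), 0); expect_equal(max(nv), 1)
  # affine invariance of the normalized values
  expect_equal(minmax_normalize(3 * v + 10), nv, tolerance = 1e-12)
  expect_equal(minmax_normalize(c(1, NA, 3)), c(0, NA, 1))
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("the R-factor term sums two normalized columns", {
  m <- batch_metrics()
  rf <- r_factor_term(m)
  expect_equal(rf$r_factor_term, c(0, 1, 2))  # middle model 0.5 + 0.5
  expect_error(r_factor_term(m[1, ]), "at least 2")
  m2 <- m; m2$r_free <- NA_real_; m2$r_work <- NA_real_
  expect_error(r_factor_term(m2), "missing for every model")
})

test_that("the geometry score spans 0 to 8 and follows the missing policy", {
  m <- batch_metrics()
  gs <- geometry_score(m)
  expect_equal(gs$geometry_score, c(0, 4, 8), tolerance = 1e-12)
  # only clashscore varies: [0, 10, 20] -> [0, 0.5, 1]
  mc <- m
  for (col in setdiff(trxscore:::.geometry_terms, "clashscore")) {
    mc[[col]] <- 1
  }
  expect_equal(geometry_score(mc)$geometry_score, c(0, 0.5, 1))
  # wholly absent column drops out with a warning
  ma <- m; ma$molprobity_score <- NULL
  expect_warning(gsa <- geometry_score(ma), "molprobity_score")
  expect_equal(attr(gsa, "dropped_terms"), "molprobity_score")
  expect_equal(gsa$geometry_score, c(0, 3.5, 7), tolerance = 1e-12)
  # partially missing value gets the worst normalized score and a flag
  mp <- m; mp$clashscore[1] <- NA
  gsp <- geometry_score(mp)
  flags <- attr(gsp, "flags")
  expect_equal(flags$model_id, "m1")
  expect_equal(flags$column, "clashscore")
  expect_gt(gsp$geometry_score[1], 0)  # m1 no longer best everywhere
})

test_that("weighted RSZD reproduces the worked per-residue example", {
  w <- batch_weights()
  rm_ <- tibble::tibble(
    model_id = "m", chain = "A", resno = c(10L, 11L), ins = "",
    rszd_plus = c(1.5, 0), rszd_minus = c(0, 3),
    rscc = 0.8, rszo = 2)
  expect_equal(weighted_rszd(rm_, w)$weighted_rszd, 3.0)
  # all-zero RSZD or all-zero weights both give 0
  rm0 <- rm_; rm0$rszd_plus <- 0; rm0$rszd_minus <- 0
  expect_equal(weighted_rszd(rm0, w)$weighted_rszd, 0)
  w0 <- w; w0$rho_pos <- 0; w0$rho_neg <- 0
  expect_equal(weighted_rszd(rm_, w0)$weighted_rszd, 0)
  # weight residues must exist in the metrics
  expect_error(weighted_rszd(rm_[1, ], w), "missing from residue metrics")
})

test_that("residue averages are plain means with missing values excluded", {
  rm_ <- batch_residue_metrics()
  ra <- residue_average(rm_, "rscc")
  expect_equal(ra$rscc_bar, c(0.85, 0.75, 0.65))
  one <- rm_[rm_$model_id == "m1" & rm_$resno == 10, ]
  expect_equal(residue_average(one, "rszo")$rszo_bar, 3)
  set.seed(2)
  rm_$rscc <- runif(nrow(rm_))
  want <- as.numeric(tapply(rm_$rscc, rm_$model_id, mean))
  expect_equal(residue_average(rm_, "rscc")$rscc_bar, want,
               tolerance = 1e-15)
  rm_$rscc[1] <- NA
  ra2 <- residue_average(rm_, "rscc")
  expect_equal(attr(ra2, "flags")$model_id, "m1")
})

test_that("the density score inverts the quality metrics", {
  ds <- density_score(batch_residue_metrics(), batch_weights())
  # m1 has the best rscc/rszo averages; check hand arithmetic end to end
  wz <- weighted_rszd(batch_residue_metrics(), batch_weights())
  expect_equal(ds$weighted_rszd, wz$weighted_rszd)
  expect_equal(ds$density_score,
               minmax_normalize(ds$weighted_rszd) +
                 (1 - minmax_normalize(ds$rscc_bar)) +
                 (1 - minmax_normalize(ds$rszo_bar)))
  expect_true(all(ds$density_score >= 0 & ds$density_score <= 3))
})

test_that("composite scores are the exact sum of their three terms", {
  sc <- composite_score(batch_metrics(), batch_residue_metrics(),
                        batch_weights())
  expect_s3_class(sc, "score_breakdown")
  expect_equal(sc$composite,
               sc$r_factor_term + sc$geometry_score + sc$density_score,
               tolerance = 1e-12)
  # m1 is batch-best in every raw input -> composite 0
  expect_equal(sc$model_id[sc$rank == 1], "m1")
  expect_equal(sc$composite[sc$rank == 1], 0)
  # m3 is batch-worst in every raw input -> composite 13 = 2 + 8 + 3
  expect_equal(sc$composite[sc$model_id == "m3"], 13, tolerance = 1e-12)
  expect_true(all(sc$composite >= 0 & sc$composite <= 13))
})

test_that("ranking is ascending with R-free and id tie-breaks", {
  b <- tibble::tibble(model_id = c("a", "b", "c"), composite = c(3, 1, 2),
                      r_free = c(0.2, 0.2, 0.2))
  expect_equal(rank_models(b)$model_id, c("b", "c", "a"))
  t2 <- tibble::tibble(model_id = c("a", "b"), composite = c(1, 1),
                       r_free = c(0.21, 0.20))
  expect_equal(rank_models(t2)$model_id[1], "b")
  t3 <- tibble::tibble(model_id = c("b", "a"), composite = c(1, 1),
                       r_free = c(0.2, 0.2))
  expect_equal(rank_models(t3)$model_id, c("a", "b"))
  set.seed(3)
  r <- tibble::tibble(model_id = sprintf("m%02d", 1:20),
                      composite = runif(20), r_free = runif(20))
  expect_equal(rank_models(r)$model_id,
               r$model_id[order(r$composite, r$r_free, r$model_id)])
})

test_that("worsening one raw metric never improves a composite score", {
  m <- batch_metrics(); rm_ <- batch_residue_metrics(); w <- batch_weights()
  base <- composite_score(m, rm_, w)
  for (col in c("r_free", "clashscore", "rms_bond", "rmsd_ab")) {
    m2 <- m
    m2[[col]][2] <- m2[[col]][2] + diff(range(m2[[col]])) * 0.5
    sc2 <- composite_score(m2, rm_, w)
    expect_gte(sc2$composite[sc2$model_id == "m2"] + 1e-12,
               base$composite[base$model_id == "m2"])
  }
})

test_that("composite scores are invariant to column affine maps and row order", {
  m <- batch_metrics(); rm_ <- batch_residue_metrics(); w <- batch_weights()
  base <- composite_score(m, rm_, w)
  m2 <- m
  m2$clashscore <- 2.5 * m2$clashscore + 7
  m2$r_free <- 0.1 * m2$r_free + 0.9
  sc2 <- composite_score(m2, rm_, w)
  expect_equal(sc2$composite, base$composite, tolerance = 1e-12)
  # permutation invariance
  perm <- c(3, 1, 2)
  sc3 <- composite_score(m[perm, ], rm_, w)
  expect_equal(sc3[order(sc3$model_id), ]$composite,
               base[order(base$model_id), ]$composite, tolerance = 1e-12)
})

test_that("score breakdowns expose tidy, glance and autoplot methods", {
  sc <- composite_score(batch_metrics(), batch_residue_metrics(),
                        batch_weights())
  td <- generics::tidy(sc)
  expect_equal(sort(unique(td$term)),
               sort(c("r_factor_term", "geometry_score", "density_score",
                      "composite")))
  gl <- generics::glance(sc)
  expect_equal(gl$n_models, 3L)
  expect_equal(gl$best_model, "m1")
  p <- ggplot2::autoplot(sc)
  expect_s3_class(p, "ggplot")
})
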