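test_that("Kabsch superposition recovers exact rigid transforms", {
  s <- toy_trace(20)
  xyz <- calpha_matrix(s)$xyz

  fit0 <- kabsch_superpose(xyz, xyz)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_equal(fit0$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)

  fit_t <- kabsch_superpose(xyz, sweep(xyz, 2, c(5, 0, 0), "+"))
  expect_equal(fit_t$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(fit_t$rmsd, 0, tolerance = 1e-9)

  rot <- rotation_matrix(0.3, -1.1, 2.2)
  moved <- sweep(xyz %*% rot, 2, c(1, -2, 3), "+")
  fit_r <- kabsch_superpose(xyz, moved)
  expect_equal(sqrt(sum((fit_r$rotation - rot)^2)), 0, tolerance = 1e-6)
  expect_equal(det(fit_r$rotation), 1, tolerance = 1e-9)
  expect_equal(fit_r$rmsd, 0, tolerance = 1e-9)
})

test_that("Kabsch agrees with the bio3d fitting oracle on noisy pairs", {
  set.seed(42)
  xyz <- matrix(rnorm(60), ncol = 3)
  rot <- rotation_matrix(1.0, 0.4, -0.7)
  noisy <- sweep(xyz %*% rot, 2, c(2, 2, 2), "+") + matrix(rnorm(60, sd = 0.2), ncol = 3)
  mine <- kabsch_superpose(xyz, noisy)
  fitted_oracle <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(noisy)), mobile = as.vector(t(xyz))))
  oracle_rmsd <- sqrt(mean(rowSums(
    (matrix(fitted_oracle, ncol = 3, byrow = TRUE) - noisy)^2)))
  expect_equal(mine$rmsd, oracle_rmsd, tolerance = 1e-6)
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(1:6, ncol = 3), matrix(1:6, ncol = 3)),
               "degenerate")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("iterative mean alignment is exact on copies and symmetric for pairs", {
  s <- toy_trace(12)
  e <- validate_ensemble(rep(list(s), 5))
  al <- iterative_mean_align(e)
  expect_true(all(abs(sweep(al$coords, 2, al$coords[1, ])) < 1e-9))

  b <- shift_structure(s, c(0, 0, 4), residues = 1:6)
  al2 <- iterative_mean_align(validate_ensemble(list(s, b), ids = c("a", "b")))
  xa <- matrix(al2$coords[1, ], ncol = 3, byrow = TRUE)
  xb <- matrix(al2$coords[2, ], ncol = 3, byrow = TRUE)
  # the converged mean is the midpoint: equidistant from both members
  da <- sqrt(mean(rowSums((xa - al2$mean)^2)))
  db <- sqrt(mean(rowSums((xb - al2$mean)^2)))
  expect_equal(da, db, tolerance = 1e-6)
  expect_equal(al2$mean, (xa + xb) / 2, tolerance = 1e-6)
})

test_that("alignment removes arbitrary per-member rigid transforms", {
  b <- make_bundle(residues_per_helix = 8)
  sim <- make_transition_ensemble(b, displacement = 5, n_frames = 6,
                                  noise = 0.2, seed = 3)
  e <- sim$ensemble
  rots <- list(rotation_matrix(0.1, 0.2, 0.3), rotation_matrix(-1, 0.5, 0),
               rotation_matrix(2, -2, 1), rotation_matrix(0, 3, 0.7),
               rotation_matrix(0.9, 0.9, -0.9), rotation_matrix(-0.4, 1.2, 2.5))
  moved <- validate_ensemble(lapply(seq_along(e$members), function(i) {
    rotate_structure(e$members[[i]], rots[[i]], c(i, -i, 2 * i))
  }), ids = e$ids)
  al_ref <- iterative_mean_align(e)
  al_mov <- iterative_mean_align(moved)
  pd <- function(al) as.matrix(stats::dist(al$coords))
  expect_equal(pd(al_ref), pd(al_mov), tolerance = 1e-6)
  # landscape projections are unchanged too (sign fixed by member ids)
  expect_equal(landscape_pca(al_ref)$projections,
               landscape_pca(al_mov)$projections, tolerance = 1e-6)
})

test_that("PCA matches the brute-force covariance eigendecomposition", {
  set.seed(7)
  m <- 8; n <- 15
  coords <- matrix(rnorm(m * 3 * n), nrow = m)
  lr <- landscape_pca(coords)
  cv <- stats::cov(coords)           # oracle route: explicit covariance
  eo <- eigen(cv, symmetric = TRUE)
  kmax <- m - 1
  expect_equal(lr$eigenvalues[seq_len(kmax)], eo$values[seq_len(kmax)],
               tolerance = 1e-8)
  for (j in seq_len(kmax)) {
    expect_equal(abs(sum(lr$eigenvectors[, j] * eo$vectors[, j])), 1,
                 tolerance = 1e-8)
  }
  # orthonormality, centred projections, variance conservation
  gram <- crossprod(lr$eigenvectors)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-8)
  expect_true(all(abs(colMeans(lr$projections)) < 1e-9))
  expect_equal(sum(lr$eigenvalues), lr$total_variance, tolerance = 1e-6)
  expect_true(all(diff(lr$eigenvalues) < 1e-9))
  expect_true(all(lr$eigenvalues > -1e-9))
})

test_that("a noise-free linear interpolation is rank one with endpoint extremes", {
  s <- toy_trace(12)
  b <- shift_structure(s, c(0, 0, 6), residues = 1:6)
  e <- morph(s, b, n_frames = 40)
  lr <- landscape_pca(iterative_mean_align(e))
  expect_equal(lr$eigenvalues[1] / lr$total_variance, 1, tolerance = 1e-9)
  ext <- extract_extremes(lr)
  expect_equal(unname(ext), c(1L, 40L))
  expect_true(lr$extreme_low < lr$extreme_high)

  # identical members: zero eigenvalues and a flagged degenerate landscape
  e0 <- validate_ensemble(rep(list(s), 4))
  lr0 <- landscape_pca(iterative_mean_align(e0))
  expect_true(all(abs(lr0$eigenvalues) < 1e-12))
  expect_warning(ext0 <- extract_extremes(lr0), "degenerate")
  expect_equal(unname(ext0), c(1L, 1L))
})

test_that("morph endpoints are exact and intermediates are linear", {
  s <- toy_trace(10)
  b <- shift_structure(s, c(0, 0, 6), residues = 10)  # one atom moved 6 A
  # (single-atom shifts perturb the superposition; fit is on all CA)
  m3 <- morph(s, b, n_frames = 3)
  a1 <- m3$members[[1]]$atom
  expect_identical(a1[, c("x", "y", "z")], s$atom[, c("x", "y", "z")])
  # midpoint displaces the moved atom by half the (superposed) endpoint gap
  end_gap <- as.matrix(m3$members[[3]]$atom[, c("x", "y", "z")]) -
    as.matrix(s$atom[, c("x", "y", "z")])
  mid_gap <- as.matrix(m3$members[[2]]$atom[, c("x", "y", "z")]) -
    as.matrix(s$atom[, c("x", "y", "z")])
  expect_equal(mid_gap, end_gap / 2, tolerance = 1e-9)
  expect_equal(attr(m3$members[[2]], "t"), 0.5)

  m2 <- morph(s, b, n_frames = 2)
  fit <- kabsch_superpose(calpha_matrix(b)$xyz, calpha_matrix(s)$xyz)
  expect_equal(as.matrix(m2$members[[2]]$atom[, c("x", "y", "z")]),
               apply_transform(as.matrix(b$atom[, c("x", "y", "z")]), fit),
               tolerance = 1e-12, ignore_attr = TRUE)

  id10 <- morph(s, s, n_frames = 10)
  for (f in id10$members) {
    expect_equal(as.matrix(f$atom[, c("x", "y", "z")]),
                 as.matrix(s$atom[, c("x", "y", "z")]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }

  expect_error(morph(s, toy_trace(9), 3), "topology")
})
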