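test_that("displacement field isolates a planted rigid translation", {
  s <- toy_trace(40)
  expect_true(all(displacement_field(s, s)$mag < 1e-9))

  b <- shift_structure(s, c(0, 0, 7), residues = 1:20)
  f <- displacement_field(s, b, frame = "subset", frame_residues = 21:40)
  moved <- f$resno <= 20
  expect_equal(as.matrix(f[moved, c("dx", "dy", "dz")]),
               matrix(rep(c(0, 0, 7), each = 20), ncol = 3),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(f$mag[!moved] < 1e-9))

  expect_error(displacement_field(s, b, frame = "subset", frame_residues = 1:2),
               "degenerate")
})

test_that("displacement recovery tracks the generator truth within noise", {
  sim <- make_transition_ensemble(make_bundle(), displacement = 6,
                                  n_frames = 2, noise = 0.3, seed = 11)
  tr <- sim$truth
  a <- sim$ensemble$members[[1]]
  b <- sim$ensemble$members[[2]]
  scaffold <- tr$domains$resno[tr$domains$domain == "scaffold"]
  f <- displacement_field(a, b, frame = "subset", frame_residues = scaffold)
  tmean <- mean(f$mag[f$resno %in% tr$domains$resno[tr$domains$domain == "transport"]])
  n_t <- sum(tr$domains$domain == "transport")
  expect_lt(abs(tmean - 6), 3 * 0.3 * sqrt(2) / sqrt(n_t) + 0.1)
})

test_that("two-domain decomposition separates mobile from static residues", {
  f <- data.frame(chain = "A", resno = 1:100,
                  dx = 0, dy = 0, dz = rep(c(0, 7), each = 50))
  f$mag <- abs(f$dz)
  asg <- domain_decompose(f)
  expect_false(attr(asg, "indeterminate"))
  expect_equal(asg$domain, rep(c("scaffold", "transport"), each = 50))
  expect_equal(attr(asg, "translation"), c(0, 0, 7), tolerance = 1e-12)

  uni <- data.frame(chain = "A", resno = 1:10, dx = 1, dy = 1, dz = 1,
                    mag = sqrt(3))
  expect_true(attr(domain_decompose(uni), "indeterminate"))
})

test_that("membrane axis is the bundle inertia axis and is rotation-equivariant", {
  b <- make_bundle()
  segs <- Map(c, attr(b, "helices")$start, attr(b, "helices")$end)
  ax <- membrane_axis(b, segs)
  expect_equal(abs(ax[3]), 1, tolerance = 1e-3)

  rot <- rotation_matrix(0.5, 1.2, -0.8)
  ax_rot <- membrane_axis(rotate_structure(b, rot), segs)
  expect_equal(abs(sum(ax_rot * drop(ax %*% rot))), 1, tolerance = 1e-3)

  helix <- toy_trace(20)
  ax_h <- membrane_axis(helix, list(c(1, 20)))
  expect_equal(abs(ax_h[3]), 1, tolerance = 1e-2)

  # near-isotropic point cloud: no defined axis
  cube <- expand.grid(x = c(0, 10), y = c(0, 10), z = c(0, 10))
  s_cube <- zip_structure(data.frame(chain = "A", resno = 1:8, resid = "ALA",
                                     elety = "CA", elesy = "C",
                                     x = cube$x, y = cube$y, z = cube$z,
                                     o = 1, het = FALSE))
  expect_error(membrane_axis(s_cube, list(c(1, 8))), "axis indeterminate")
})

test_that("site displacement projects exactly on the axis", {
  s <- toy_trace(30)
  expect_equal(unname(site_displacement(s, s, 5:10, c(0, 0, 1))), c(0, 0))
  b <- shift_structure(s, c(0, 0, 7), residues = 5:10)
  expect_equal(site_displacement(s, b, 5:10, c(0, 0, 1)),
               c(total = 7, along_axis = 7), tolerance = 1e-9)
  expect_error(site_displacement(s, b, integer(0), c(0, 0, 1)), "empty site")
})

test_that("plug contact state follows the contact-graph definition", {
  spread <- zip_structure(data.frame(chain = "A", resno = 1:5, resid = "LEU",
                                     elety = "CA", elesy = "C",
                                     x = seq(0, 40, by = 10), y = 0, z = 0,
                                     o = 1, het = FALSE))
  ps <- plug_state(spread, 1:5, cutoff = 4.5, formation_threshold = 0.8)
  expect_false(ps$formed)
  expect_equal(nrow(ps$edges), 0)
  expect_equal(max(table(ps$membership)), 1)

  chain <- zip_structure(data.frame(chain = "A", resno = 1:5, resid = "LEU",
                                    elety = "CA", elesy = "C",
                                    x = seq(0, 16, by = 4), y = 0, z = 0,
                                    o = 1, het = FALSE))
  pc <- plug_state(chain, 1:5, cutoff = 4.5, formation_threshold = 0.8)
  expect_true(pc$formed)
  expect_equal(pc$largest_fraction, 1)
  expect_equal(nrow(pc$edges), 4)

  expect_error(plug_state(chain, c(1, 99)), "absent")
})

test_that("conformation classification covers the full plug truth table", {
  tight <- zip_structure(data.frame(chain = "A", resno = 1:3, resid = "LEU",
                                    elety = "CA", elesy = "C",
                                    x = c(0, 3, 6), y = 0, z = 0, o = 1,
                                    het = FALSE))
  apart <- shift_structure(tight, c(100, 0, 0), residues = 2)
  formed <- plug_state(tight, 1:3)
  open <- plug_state(apart, 1:3)
  expect_true(formed$formed)
  expect_false(open$formed)
  expect_equal(classify_conformation(formed, open), "inward")
  expect_equal(classify_conformation(open, formed), "outward")
  expect_equal(classify_conformation(formed, formed), "occluded")
  expect_equal(classify_conformation(open, open), "open-both")
})

test_that("elevator verdict separates elevator, rocker and identity cases", {
  sim <- make_transition_ensemble(make_bundle(), displacement = 7,
                                  n_frames = 2, noise = 0.3, seed = 5)
  tr <- sim$truth
  a <- sim$ensemble$members[[1]]
  b <- sim$ensemble$members[[2]]
  rep_el <- mechanism_report(a, b, tm_segments = tr$tm_segments,
                             sites = tr$sites, plug_ec = tr$plug_ec,
                             plug_ic = tr$plug_ic)
  expect_equal(rep_el$verdict$verdict, "elevator")

  # rocker: both domains rotate rigidly about a mid-membrane hinge; the
  # site barely travels along the axis
  bun <- make_bundle()
  doms <- attr(bun, "domains")
  rock <- function(s, angle_t, angle_s) {
    at <- s$atom
    for (dd in list(list(sel = at$resno %in% doms$resno[doms$domain == "transport"],
                         th = angle_t),
                    list(sel = at$resno %in% doms$resno[doms$domain == "scaffold"],
                         th = angle_s))) {
      x <- at$x[dd$sel]; z <- at$z[dd$sel]
      at$x[dd$sel] <- x * cos(dd$th) - z * sin(dd$th)
      at$z[dd$sel] <- x * sin(dd$th) + z * cos(dd$th)
    }
    zip_structure(at, id = paste0(s$id, "_rocked"))
  }
  rocked <- rock(bun, 4 * pi / 180, -4 * pi / 180)
  f <- displacement_field(bun, rocked)
  asg <- domain_decompose(f)
  attr(asg, "rmsd") <- domain_rmsd(bun, rocked, asg)
  segs <- Map(c, attr(bun, "helices")$start, attr(bun, "helices")$end)
  sim_sites <- tr$sites$m1
  axv <- membrane_axis(bun, segs)
  sd_rock <- site_displacement(bun, rocked, sim_sites, axv)
  v_rock <- elevator_verdict(asg, sd_rock["along_axis"])
  expect_equal(v_rock$verdict, "non-elevator")
  expect_lt(abs(sd_rock[["along_axis"]]), 3)

  rep_id <- mechanism_report(a, a, tm_segments = tr$tm_segments,
                             sites = tr$sites, plug_ec = tr$plug_ec,
                             plug_ic = tr$plug_ic)
  expect_equal(rep_id$verdict$verdict, "indeterminate")
})

test_that("the mechanism report is invariant under a common rigid transform", {
  sim <- make_transition_ensemble(make_bundle(), displacement = 7,
                                  n_frames = 2, noise = 0.3, seed = 9)
  tr <- sim$truth
  a <- sim$ensemble$members[[1]]
  b <- sim$ensemble$members[[2]]
  rot <- rotation_matrix(1.1, -0.6, 0.4)
  a2 <- rotate_structure(a, rot, c(10, -5, 3))
  b2 <- rotate_structure(b, rot, c(10, -5, 3))
  r1 <- mechanism_report(a, b, tm_segments = tr$tm_segments, sites = tr$sites,
                         plug_ec = tr$plug_ec, plug_ic = tr$plug_ic)
  r2 <- mechanism_report(a2, b2, tm_segments = tr$tm_segments, sites = tr$sites,
                         plug_ec = tr$plug_ec, plug_ic = tr$plug_ic)
  expect_equal(r1$verdict$verdict, r2$verdict$verdict)
  expect_equal(r1$states, r2$states)
  expect_equal(r1$assignment$domain, r2$assignment$domain)
  for (nm in names(r1$site_displacements)) {
    expect_equal(abs(r1$site_displacements[[nm]]),
                 abs(r2$site_displacements[[nm]]), tolerance = 1e-6)
  }
  expect_equal(r1$verdict$scores$site_travel, r2$verdict$scores$site_travel,
               tolerance = 1e-6)
})
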