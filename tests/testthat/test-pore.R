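test_that("pore radius of a ring of spheres follows the closed form", {
  ring <- make_analytic_shape("ring", n = 10L, R = 8, rho = 1, z = 5)
  at_plane <- pore_radius_at(ring, 5)
  expect_equal(at_plane$radius, 7, tolerance = 1e-12)
  expect_false(at_plane$blocked)
  for (d in c(0.5, 2, -3)) {
    off <- pore_radius_at(ring, 5 + d)
    expect_equal(off$radius, sqrt(64 + d^2) - 1, tolerance = 1e-12)
  }
  # an atom centred on the axis blocks it
  blocker <- make_analytic_shape("sphere", R = 2, center = c(0, 0, 5))
  bl <- pore_radius_at(blocker, 5)
  expect_true(bl$blocked)
  expect_equal(bl$radius, 0)
})

test_that("pore radius agrees with the binary-search clash oracle", {
  for (seed in 1:5) {
    a <- random_assembly(n_atoms = 30L, seed = seed)
    for (z in c(-5, 0, 3.3)) {
      got <- pore_radius_at(a, z)
      want <- pore_radius_oracle(a, z)
      expect_equal(got$blocked, want$blocked)
      expect_lt(abs(got$radius - want$radius), 1e-6)
    }
  }
})

test_that("the radius profile is 1-Lipschitz and hits ring minima", {
  # two stacked rings with different radii
  r1 <- make_analytic_shape("ring", n = 24L, R = 8, rho = 1, z = -4)
  r2 <- make_analytic_shape("ring", n = 24L, R = 6, rho = 1, z = 4)
  a2 <- r2$atoms
  a2$serial <- a2$serial + 100L
  a2$resno <- a2$resno + 100L
  both <- molecular_assembly(rbind(r1$atoms, a2))
  prof <- radius_profile(both, -8, 8, 161L)
  expect_equal(prof$radius[prof$z == -4], 7, tolerance = 1e-12)
  expect_equal(prof$radius[prof$z == 4], 5, tolerance = 1e-12)
  # 1-Lipschitz in z
  dz <- diff(prof$z)
  expect_true(all(abs(diff(prof$radius)) <= dz + 1e-12))
  # minimal call: endpoints only
  p2 <- radius_profile(both, -8, 8, 2L)
  expect_identical(p2$z, c(-8, 8))
  expect_length(p2$radius, 2L)
})

test_that("slice contours close on dense rings and open between subunits", {
  dense <- make_analytic_shape("ring", n = 72L, R = 8, rho = 1, z = 0)
  ct <- slice_contour(dense, 0, n_theta = 90L)
  expect_true(ct$closed)
  expect_lt(max(abs(ct$radius - 7)), 0.05) # dense-ring limit R - rho
  # boundary radius can never undercut the inscribed pore radius
  expect_true(all(ct$radius >= pore_radius_at(dense, 0)$radius - 1e-9))

  five <- make_analytic_shape("ring", n = 5L, R = 8, rho = 1, z = 0)
  ct5 <- slice_contour(five, 0, n_theta = 360L)
  expect_false(ct5$closed)
  open <- is.na(ct5$radius)
  # exactly 5 contiguous open sectors (circular run count)
  runs <- rle(open)
  n_open_runs <- sum(runs$values)
  if (open[1] && open[length(open)]) n_open_runs <- n_open_runs - 1L
  expect_identical(n_open_runs, 5L)

  blocker <- make_analytic_shape("sphere", R = 2)
  expect_error(slice_contour(blocker, 0), "inside an atom")

  ct3 <- slice_contour(dense, 0, n_theta = 3L)
  expect_length(ct3$radius, 3L)
  expect_true(ct3$closed)
})

test_that("constriction detection enumerates strict local minima", {
  prof <- structure(list(z = 1:5, radius = c(5, 3, 5, 2, 5),
                         blocked = rep(FALSE, 5)), class = "PoreProfile")
  cons <- find_constrictions(prof, k = 2L)
  expect_equal(cons$radius, c(2, 3))
  expect_equal(cons$z, c(4, 2))
  # k larger than the number of minima returns them all
  expect_equal(nrow(find_constrictions(prof, k = 10L)), 2L)

  mono <- structure(list(z = 1:5, radius = as.numeric(1:5),
                         blocked = rep(FALSE, 5)), class = "PoreProfile")
  expect_error(find_constrictions(mono), "no interior local minimum")

  # plateau counts once, at its leftmost sample
  plat <- structure(list(z = 1:6, radius = c(5, 2, 2, 2, 5, 6),
                         blocked = rep(FALSE, 6)), class = "PoreProfile")
  cp <- find_constrictions(plat, k = 1L)
  expect_equal(cp$z, 2)
  expect_equal(cp$radius, 2)
})

test_that("the generator's built-in constrictions are recovered", {
  res <- full_pentamer()
  gt <- res$ground_truth$constrictions
  prof <- radius_profile(res$assembly, -9.5, 9.5, 191L) # 0.1 A bins
  cons <- find_constrictions(prof, k = 2L)
  for (i in 1:2) {
    expect_lt(abs(cons$z[i] - gt$z[i]), 0.1 + 1e-9)
    expect_lt(abs(cons$radius[i] - gt$radius[i]), 0.05)
  }
})

test_that("constriction tracking follows the opening gate", {
  spec <- synthetic_spec(atoms_per_subunit = 80L, pore_open_frac = 0.3)
  stack <- make_twist_trajectory(spec, 6L)
  gt <- attr(stack, "ground_truth")
  z_key <- gt$z[1]
  tr <- track_constriction(stack, c(z_key - 3, z_key + 3), 61L)
  expect_true(all(diff(tr$radius) > 0))
  bin <- 6 / 60
  expect_true(all(abs(tr$z - gt$z) <= bin + 1e-9))
  expect_true(all(abs(tr$radius - gt$radius) < 0.05))

  # a static stack tracks identically in every frame
  frames <- rep(list(stack$frames[[1]]), 3L)
  st <- trajectory_stack(frames)
  tr_static <- track_constriction(st, c(z_key - 3, z_key + 3), 31L)
  expect_equal(tr_static$radius, rep(tr_static$radius[1], 3))
  expect_equal(tr_static$z, rep(tr_static$z[1], 3))

  # single-frame stack equals the windowed profile minimum
  one <- trajectory_stack(list(stack$frames[[1]]))
  tr1 <- track_constriction(one, c(z_key - 3, z_key + 3), 31L)
  pf <- radius_profile(stack$frames[[1]], z_key - 3, z_key + 3, 31L)
  expect_equal(tr1$radius, min(pf$radius))
})
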