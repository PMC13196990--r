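test_that("biot_savart matches the infinite-wire closed form", {
  # 10 mm segmented wire, 1 nA, 10 um off-centre: mu0 I / (2 pi rho) = 20 pT
  cur <- wire_currents(10000, 2000, I_nA = 1)
  f <- biot_savart(cur, rbind(c(0, 10, 0)))
  bmag <- sqrt(f$values$Bx[1]^2 + f$values$By[1]^2 + f$values$Bz[1]^2)
  expect_equal(bmag, 20, tolerance = 0.01)
  # field is azimuthal: +x current, sensor at +y -> B along +z
  expect_gt(f$values$Bz[1], 0)
  expect_lt(abs(f$values$Bx[1]) + abs(f$values$By[1]), 1e-9 * bmag)

  # zero currents give zero field
  cur0 <- wire_currents(1000, 100, I_nA = 0)
  f0 <- biot_savart(cur0, rbind(c(0, 50, 0), c(100, -30, 40)))
  expect_true(all(f0$values$Bx == 0 & f0$values$By == 0 & f0$values$Bz == 0))

  # on-axis displacement along the segment direction -> parallel cross
  # product, zero field
  one <- wire_currents(10, 1, I_nA = 1)
  fax <- biot_savart(one, rbind(c(500, 0, 0)))
  expect_equal(max(abs(c(fax$values$Bx, fax$values$By, fax$values$Bz))), 0)

  # singular evaluation raises, no silent clamping
  expect_error(biot_savart(one, rbind(c(0.05, 0, 0))), "0.1 um")
})

test_that("line-source potential matches monopole and far-field limits", {
  ps <- point_sources(rbind(c(0, 0, 0)), 1)
  phi <- line_source_potential(ps, rbind(c(0, 0, 10)), sigma_e = 0.3)
  expect_equal(phi$values[1, 1], 1000 / (4 * pi * 0.3 * 10), tolerance = 1e-12)

  # a 10 um line source far away looks like a point source to 0.1%
  brk <- c(-5, 5)
  line <- neuromag:::new_compartment_currents(
    rbind(c(brk[1], 0, 0)), rbind(c(brk[2], 0, 0)), 1,
    I_a = matrix(0), I_m = matrix(1), dt = NA_real_, t = 0, check = FALSE)
  far <- rbind(c(0, 0, 400))
  expect_equal(line_source_potential(line, far, 0.3)$values[1, 1],
               line_source_potential(ps, far, 0.3)$values[1, 1],
               tolerance = 1e-3)

  # linear in currents
  ps2 <- point_sources(rbind(c(0, 0, 0)), 2)
  expect_equal(line_source_potential(ps2, rbind(c(3, 4, 5)), 0.3)$values[1, 1],
               2 * line_source_potential(ps, rbind(c(3, 4, 5)), 0.3)$values[1, 1])

  # point on the source line errors
  expect_error(line_source_potential(line, rbind(c(0, 0, 0.01)), 0.3),
               "0.1 um")
})

test_that("current dipole follows the two-point closed form", {
  src <- point_sources(rbind(c(0, 0, 0), c(1000, 0, 0)), c(-1, 1))
  p <- current_dipole(src)
  expect_equal(sqrt(sum(p^2)), 1) # 1 nA x 1 mm = 1 pA m
  # translation invariance under zero net current
  src2 <- point_sources(rbind(c(500, 200, -100), c(1500, 200, -100)), c(-1, 1))
  expect_equal(current_dipole(src2), p, ignore_attr = TRUE)
  # unbalanced source flags
  bad <- point_sources(rbind(c(0, 0, 0)), 1)
  expect_warning(pb <- current_dipole(bad), "origin-dependent")
  expect_true(attr(pb, "net_current_violated"))
})

test_that("superposition and solenoidality hold", {
  cur_a <- wire_currents(1000, 100, 1)
  cur_b <- point_sources(rbind(c(0, 200, 0), c(0, -200, 0)), c(1, -1))
  pts <- rbind(c(50, 80, 60), c(-200, 40, 30))
  both <- neuromag:::new_compartment_currents(
    rbind(cur_a$starts, cur_b$starts), rbind(cur_a$ends, cur_b$ends),
    c(cur_a$radii, cur_b$radii),
    rbind(cur_a$I_a, cur_b$I_a), rbind(cur_a$I_m, cur_b$I_m),
    NA_real_, 0, check = FALSE)
  fa <- biot_savart(cur_a, pts)$values
  fb <- biot_savart(cur_b, pts)$values
  fab <- biot_savart(both, pts)$values
  expect_equal(fab$Bz, fa$Bz + fb$Bz, tolerance = 1e-12)
  pa <- line_source_potential(cur_a, pts, 0.3)$values
  pb <- line_source_potential(cur_b, pts, 0.3)$values
  pab <- line_source_potential(both, pts, 0.3)$values
  expect_equal(pab, pa + pb, tolerance = 1e-12)

  # numerical div B on a 1 um stencil is tiny relative to |B|
  dv <- b_divergence(cur_a, c(40, 60, 35), h = 1)
  expect_lt(abs(dv$div[1]), 1e-3 * dv$b_scale)
})

test_that("scaling exponent fits recover synthetic power laws", {
  r <- exp(seq(log(10), log(1000), length.out = 30))
  fit <- fit_scaling_exponent(r, 7 / r^2.5, range(r))
  expect_equal(fit$exponent, 2.5, tolerance = 1e-12)
  # monopole potential
  ps <- point_sources(rbind(c(0, 0, 0)), 1)
  mags <- line_source_potential(ps, cbind(0, 0, r), 0.3)$values[, 1]
  expect_equal(fit_scaling_exponent(r, mags)$exponent, 1, tolerance = 1e-9)
  expect_error(fit_scaling_exponent(r[1:4], (7 / r^2)[1:4]), "5 points")
  expect_error(fit_scaling_exponent(r, r - 500), "positive")
  # window restriction is honoured
  mags2 <- c(1 / r[1:15]^2, 1 / r[16:30]^3 * r[15]^1) # broken power law
  f2 <- fit_scaling_exponent(r, mags2, c(r[1], r[15]))
  expect_equal(f2$exponent, 2, tolerance = 1e-6)
})

test_that("suprathreshold area counts pitch cells", {
  # single dominant sensor on a 5 um grid -> one 25 um^2 cell
  v <- matrix(0, 16, 4)
  v[6, 2] <- 10
  v[1, 1] <- 1 # below half the peak
  t5 <- grid_template(v, 4, 4, pitch = 5)
  expect_equal(suprathreshold_area(t5, 0.5), 25)
  # fraction 1 keeps only the argmax sensor(s)
  expect_equal(suprathreshold_area(t5, 1), 25)
  # all-equal template counts every sensor
  tall <- grid_template(matrix(3, 16, 4), 4, 4, pitch = 5)
  expect_equal(suprathreshold_area(tall, 0.5), 16 * 25)
  expect_error(suprathreshold_area(t5, 0), "fraction")
  # unknown pitch errors
  npx <- make_neuropixels_like(8)
  tn <- neuromag:::new_spike_template(matrix(1, 8, 2), npx, 0.03125, "phi")
  expect_error(suprathreshold_area(tn, 0.5), "pitch")
})

test_that("analytic cylinder exponents match the multipole orders", {
  res <- cylinder_scaling_exponents(n_r = 15)
  expect_equal(res$exponent[res$quantity == "B_magnitude"], 3,
               tolerance = 0.15 / 3)
  expect_equal(res$exponent[res$quantity == "phi_infinity_ref"], 3,
               tolerance = 0.15 / 3)
  expect_equal(res$exponent[res$quantity == "phi_gradient"], 4,
               tolerance = 0.2 / 4)
  # soma asymmetry flattens the decay: ball-stick exponents are smaller
  # than the cylinder's for both modalities
  m <- make_ball_stick(600, 2, 20, 10)
  cur <- propagate_ap(m, gaussian_ap(sigma = 100),
                      t_grid = seq(0, 0.6, length.out = 24), s_offset = 0)
  snap <- which.max(colSums(cur$I_a^2))
  r <- exp(seq(log(1000), log(10000), length.out = 12))
  ang <- 45 * pi / 180
  pts <- cbind(300 + r * cos(ang), r * sin(ang), 0)
  b <- biot_savart(cur, pts)$values
  bmag <- sqrt(b$Bx[, snap]^2 + b$By[, snap]^2 + b$Bz[, snap]^2)
  phi <- abs(line_source_potential(cur, pts, 0.3)$values[, snap])
  exp_b <- fit_scaling_exponent(r, bmag)$exponent
  exp_p <- fit_scaling_exponent(r, phi)$exponent
  cyl <- cylinder_scaling_exponents(sigma = 100, n_r = 12)
  expect_lt(exp_b, cyl$exponent[cyl$quantity == "B_magnitude"])
  expect_lt(exp_p, cyl$exponent[cyl$quantity == "phi_infinity_ref"])
})
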