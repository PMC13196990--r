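make_small_templates <- function() {
  sens <- make_sensor_grid(16, 16, 20)
  single_cell_templates(sens, modalities = c("phi", "Bx", "By", "Bz"),
                        morphology = make_ball_stick(200, 2, 20, 20),
                        t_grid = default_time_grid(48))
}

test_that("compute_template delegates per signal type", {
  tp <- make_small_templates()
  sens <- tp$phi$sensors
  expect_equal(dim(tp$phi$values), c(256, 48))
  # default time base gives 224 columns
  tp224 <- single_cell_templates(make_sensor_grid(3, 3, 50),
                                 modalities = "phi",
                                 morphology = make_ball_stick(100, 2, 20, 50))
  expect_equal(ncol(tp224$phi$values), 224)
  expect_equal(tp224$phi$dt, 0.03125)
  # zero currents -> zero template
  cur0 <- wire_currents(100, 10, 0)
  t0 <- compute_template(cur0, sens, "Bz")
  expect_true(all(t0$values == 0))
  # right-hand rule: Bz flips sign across the +x-aligned axon
  pos <- sens$positions
  i_up <- which(pos[, 1] == 10 & pos[, 2] == 30)
  i_dn <- which(pos[, 1] == 10 & pos[, 2] == -30)
  k <- which.max(abs(tp$Bz$values[i_up, ]))
  expect_lt(tp$Bz$values[i_up, k] * tp$Bz$values[i_dn, k], 0)
})

test_that("inverse-distance weights are a convex combination", {
  expect_equal(sum(idw_weights(c(3, 5, 11, 2, 7))), 1)
  expect_true(all(idw_weights(runif(5, 0.1, 10)) > 0))
  # exact match short-circuits
  expect_equal(idw_weights(c(2, 0, 5)), c(0, 1, 0))
  # closer neighbours weigh more
  w <- idw_weights(c(1, 2, 4))
  expect_true(all(diff(w) < 0))
})

test_that("rotate_template respects scalar and vector transformation rules", {
  tp <- make_small_templates()
  # spatially uniform scalar template is rotation invariant
  u <- grid_template(matrix(2.5, 256, 8), 16, 16, pitch = 20)
  for (th in c(30, 90, 215)) {
    expect_equal(rotate_template(u, th)$values, u$values, tolerance = 1e-9)
  }
  # uniform pure-Bx rotated by 90 deg becomes pure-By
  bx <- grid_template(matrix(1, 256, 8), 16, 16, 20, signal_type = "Bx")
  by0 <- grid_template(matrix(0, 256, 8), 16, 16, 20, signal_type = "By")
  rby <- rotate_template(by0, 90, partner = bx)
  expect_equal(rby$values, matrix(1, 256, 8), tolerance = 1e-9)
  rbx <- rotate_template(bx, 90, partner = by0)
  expect_equal(rbx$values, matrix(0, 256, 8), tolerance = 1e-9)
  expect_error(rotate_template(tp$Bx, 45), "partner")
  # theta = 0 is the identity
  expect_equal(rotate_template(tp$Bz, 0)$values, tp$Bz$values)
  # strict printed formula scales values by 1/K
  r1 <- rotate_template(tp$Bz, 37)
  r2 <- rotate_template(tp$Bz, 37, divide_by_k = TRUE)
  expect_equal(r2$values, r1$values / 5, tolerance = 1e-12)
})

test_that("translate_template shifts on the grid with zero fill", {
  tp <- make_small_templates()
  t0 <- tp$phi
  expect_equal(translate_template(t0, c(0, 0))$values, t0$values)
  # there and back: interior agrees, norm never grows
  fwd <- translate_template(t0, c(20, -40))
  back <- translate_template(fwd, c(-20, 40))
  interior <- which(abs(t0$sensors$positions[, 1]) < 110 &
                    abs(t0$sensors$positions[, 2]) < 110)
  expect_equal(back$values[interior, ], t0$values[interior, ])
  expect_lte(sum(fwd$values^2), sum(t0$values^2))
  expect_lte(sum(back$values^2), sum(fwd$values^2))
  # snapping warns on non-multiples
  expect_warning(translate_template(t0, c(7, 0)), "snapped")
})

test_that("spread_template is a rotation average with the stated structure", {
  tp <- make_small_templates()
  g <- spread_template(tp$Bz, theta_step = 45)
  expect_s3_class(g, "spread_template")
  # sweep commutes with global scaling
  t2 <- tp$Bz
  t2$values <- 3 * t2$values
  g2 <- spread_template(t2, theta_step = 45)
  expect_equal(g2$values, 3 * g$values, tolerance = 1e-12)
  # a radially symmetric scalar template is a fixed point of the sweep
  pos <- tp$phi$sensors$positions
  rad <- exp(-(pos[, 1]^2 + pos[, 2]^2) / (2 * 80^2))
  tr <- grid_template(matrix(rad, ncol = 4, nrow = 256), 16, 16, 20)
  gr <- spread_template(tr, theta_step = 30)
  core <- which(sqrt(pos[, 1]^2 + pos[, 2]^2) < 100) # corners leave the array
  expect_equal(gr$values[core, ], tr$values[core, ],
               tolerance = 0.01)
  # sweeping a rotated copy gives the sweep (group averaging), away from
  # the corners that rotation carries outside the array
  rot <- rotate_template(tp$Bz, 90)
  g90 <- spread_template(rot, theta_step = 45)
  core <- which(abs(pos[, 1]) < 100 & abs(pos[, 2]) < 100)
  expect_equal(g90$values[core, ], g$values[core, ],
               tolerance = 0.05 * max(abs(g$values)))
  expect_error(spread_template(tp$Bz, theta_step = 50), "divide")
})

test_that("similarity maps behave like cosines and effective radii shrink", {
  tp <- make_small_templates()
  disp <- list(dx = seq(-40, 40, by = 20), dy = seq(-40, 40, by = 20))
  # self-similarity without sweep is exactly 1 at zero displacement
  m_id <- similarity_map(tp$phi, tp$phi, disp, sweep = FALSE)
  expect_equal(m_id$values[3, 3], 1, tolerance = 1e-12)
  # anti-template gives -1
  neg <- tp$phi
  neg$values <- -neg$values
  m_neg <- similarity_map(tp$phi, neg, disp, sweep = FALSE)
  expect_equal(m_neg$values[3, 3], -1, tolerance = 1e-12)
  # Cauchy-Schwarz property over random template pairs
  set.seed(11)
  for (k in 1:100) {
    va <- matrix(rnorm(64), 16, 4)
    vb <- matrix(rnorm(64), 16, 4)
    ta <- grid_template(va, 4, 4, 25)
    tb <- grid_template(vb, 4, 4, 25)
    mm <- similarity_map(ta, tb, list(dx = c(-25, 0, 25), dy = c(0)),
                         sweep = FALSE)
    expect_true(all(mm$values >= -1 - 1e-9 & mm$values <= 1 + 1e-9))
  }
  # with sweep, bounds hold on the physical pair too
  ms <- similarity_map(tp$phi, tp$phi, disp, theta_step = 45)
  expect_true(all(ms$values >= -1 & ms$values <= 1))

  # effective radius: zero above-threshold points -> 0; one point with
  # dx = dy = 20 -> sqrt(400/pi); monotone non-increasing in gamma
  fake <- structure(list(dx = seq(-40, 40, 20), dy = seq(-40, 40, 20),
                         values = matrix(0, 5, 5), pitch = c(20, 20),
                         cell_ids = c(1, 1), signal_type = "phi"),
                    class = "similarity_map")
  expect_equal(effective_radius(fake, 0.25), 0)
  fake$values[2, 3] <- 0.9
  expect_equal(effective_radius(fake, 0.25), sqrt(400 / pi))
  gammas <- seq(-0.9, 0.9, by = 0.2)
  radii <- vapply(gammas, function(g) effective_radius(ms, g), numeric(1))
  expect_true(all(diff(radii) <= 1e-12))
  expect_error(effective_radius(ms, 1.5), "gamma")
})

test_that("templates survive the on-disk container round trip", {
  tp <- make_small_templates()
  path <- withr::local_tempdir()
  save_template(tp$Bz, path)
  t2 <- load_template(path)
  expect_equal(t2$values, tp$Bz$values, tolerance = 1e-6)
  expect_equal(t2$signal_type, "Bz")
  expect_equal(t2$sensors$positions, tp$Bz$sensors$positions,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(t2$sensors$nx, 16)
})
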