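test_that("make_ball_stick honours the canonical geometry", {
  m <- make_ball_stick(1000, 2, 20, 0.5)
  seg <- m$segments
  expect_equal(sum(seg$label == "axon"), 2000) # ceiling(1000 / 0.5)
  expect_equal(seg$radius[seg$label == "soma"], 10)
  expect_true(all(seg$radius[seg$label == "axon"] == 1))
  expect_equal(m$soma_position, c(0, 0, 0))
  # axon along +x
  expect_true(all(seg$y0 == 0 & seg$z0 == 0))
  expect_equal(max(seg$x1), 1000)

  expect_equal(sum(make_ball_stick(100, 2, 20, 100)$segments$label == "axon"), 1)
  expect_error(make_ball_stick(100, 2, 20, 0), "positive")
  expect_error(make_ball_stick(-1, 2, 20, 1), "positive")
  expect_error(make_ball_stick(100, 2, 20, 200), "segment_length")
})

test_that("branched cells reduce to ball-stick topology and are reproducible", {
  b0 <- make_branched_cell(500, 0, 100, seed = 3)
  expect_true(all(b0$segments$label %in% c("soma", "axon")))
  b1 <- make_branched_cell(500, 3, 100, seed = 7)
  b2 <- make_branched_cell(500, 3, 100, seed = 7)
  expect_identical(b1$segments, b2$segments)
  # leaves = segments that are nobody's parent
  leaves <- setdiff(seq_len(nrow(b1$segments)), b1$segments$parent)
  expect_length(leaves, 4)
  # at least one branch opposes the trunk (+x)
  dend <- b1$segments[b1$segments$label == "dendrite", ]
  ang <- atan2(dend$y1 - dend$y0, dend$x1 - dend$x0) * 180 / pi
  expect_true(any(abs(abs(ang) - 180) <= 20))
})

test_that("flatten_morphology rescales z into the band and is idempotent", {
  m <- make_branched_cell(400, 2, 150, seed = 1)
  # tilt the cell out of plane as a consistent function of position, so the
  # tree stays connected
  tilt <- function(x, y) 0.5 * x - 0.3 * y + 40
  m$segments$z0 <- tilt(m$segments$x0, m$segments$y0)
  m$segments$z1 <- tilt(m$segments$x1, m$segments$y1)
  f <- flatten_morphology(m, 5, 25)
  z <- c(f$segments$z0, f$segments$z1)
  expect_true(all(z >= 5 - 1e-9 & z <= 25 + 1e-9))
  expect_equal(range(z), c(5, 25))
  # x, y untouched
  expect_equal(f$segments$x0, m$segments$x0)
  expect_equal(f$segments$y1, m$segments$y1)
  # idempotent
  f2 <- flatten_morphology(f, 5, 25)
  expect_equal(f2$segments, f$segments, tolerance = 1e-12)
  # degenerate range maps to the midpoint
  p <- make_ball_stick(100, 2, 20, 10)
  p$segments$z0 <- 10
  p$segments$z1 <- 10
  p$soma_position[3] <- 10
  fp <- flatten_morphology(p, 5, 25)
  expect_true(all(abs(c(fp$segments$z0, fp$segments$z1) - 15) < 1e-12))
  expect_error(flatten_morphology(m, 25, 5), "z_min")
})

test_that("transform_morphology is rigid with the stated conventions", {
  m <- make_branched_cell(300, 2, 100, seed = 5)
  # identity cases
  expect_equal(transform_morphology(m, 0, c(0, 0))$segments, m$segments)
  m360 <- transform_morphology(m, 360, c(0, 0))
  expect_equal(max(abs(as.matrix(m360$segments[, 1:6]) -
                         as.matrix(m$segments[, 1:6]))), 0,
               tolerance = 1e-9)
  # +90 deg takes +x to +y (counterclockwise from +z)
  bs <- make_ball_stick(100, 2, 20, 50)
  r <- transform_morphology(bs, 90, c(0, 0))
  expect_equal(r$segments$x1[3], 0, tolerance = 1e-9)
  expect_equal(r$segments$y1[3], 100, tolerance = 1e-9)
  # pairwise distances preserved (property over random transforms)
  pts <- function(x) as.matrix(x$segments[, c("x1", "y1", "z1")])
  d0 <- dist(pts(m))
  set.seed(42)
  for (k in 1:5) {
    tr <- transform_morphology(m, runif(1, 0, 360), runif(2, -500, 500))
    expect_equal(as.numeric(dist(pts(tr))), as.numeric(d0),
                 tolerance = 1e-9)
  }
  # rotation is about the soma, so a translated cell rotates in place
  shifted <- transform_morphology(m, 0, c(100, 50))
  rot <- transform_morphology(shifted, 180, c(0, 0))
  expect_equal(rot$soma_position, shifted$soma_position)
})

test_that("SWC round trip is lossless and malformed files are rejected", {
  m <- make_branched_cell(300, 3, 80, seed = 9)
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(as.matrix(m2$segments[, 1:6]), as.matrix(m$segments[, 1:6]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(m2$segments$radius, m$segments$radius, tolerance = 1e-6)
  expect_identical(m2$segments$label, m$segments$label)
  expect_identical(m2$segments$parent, m$segments$parent)

  # 3-point toy: soma + 2 axon nodes -> 2 non-soma segments
  toy <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1",
               "2 2 50 0 0 1 1",
               "3 2 100 0 0 1 2"), toy)
  mt <- read_swc(toy)
  expect_equal(sum(mt$segments$label == "axon"), 2)
  expect_equal(nrow(mt$segments), 3)

  bad <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1",
               "2 2 50 0 0 1 3",
               "3 2 100 0 0 1 2"), bad)
  expect_error(read_swc(bad), "cyclic")

  tworoot <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1",
               "2 1 50 0 0 10 -1"), tworoot)
  expect_error(read_swc(tworoot), "[Mm]ultiple roots")

  short <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 2 50 0 0"), short)
  expect_error(read_swc(short), "line 2")
})

test_that("the shipped toy SWC fixture loads", {
  f <- system.file("extdata", "toy_cell.swc", package = "neuromag")
  expect_true(nzchar(f))
  m <- read_swc(f)
  expect_equal(nrow(m$segments), 6)
  expect_equal(sum(m$segments$label == "dendrite"), 2)
})

test_that("morphology invariants are enforced", {
  seg <- make_ball_stick(100, 2, 20, 50)$segments
  seg$radius[2] <- -1
  expect_error(new_morphology(seg), "radii")
  seg2 <- make_ball_stick(100, 2, 20, 50)$segments
  seg2$x0[3] <- 999 # break parent-child continuity
  expect_error(new_morphology(seg2), "coincide")
  seg3 <- make_ball_stick(100, 2, 20, 50)$segments
  seg3$label[1] <- "axon"
  expect_error(new_morphology(seg3), "soma")
})
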