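test_that("circle fit is exact on points sampled from one circle", {
  # unique circumcircle of three points
  f <- fit_circle(rbind(c(0, 1), c(1, 0), c(0, -1)))
  expect_equal(f$center, c(0, 0), tolerance = 1e-12)
  expect_equal(f$radius, 1, tolerance = 1e-12)
  expect_lt(f$rms_residual, 1e-9)

  # four points constructed on center (2,3), radius 5
  f <- fit_circle(rbind(c(7, 3), c(2, 8), c(-3, 3), c(2, -2)))
  expect_equal(f$center, c(2, 3), tolerance = 1e-12)
  expect_equal(f$radius, 5, tolerance = 1e-12)

  # exactness property on random circles and arc spans
  set.seed(101)
  for (i in 1:25) {
    ctr <- runif(2, -30, 30)
    r <- runif(1, 3, 20)
    th <- runif(1, 0, 2 * pi) + seq(0, runif(1, pi / 2, 2 * pi),
                                    length.out = sample(3:15, 1))
    pts <- cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
    f <- fit_circle(pts)
    expect_equal(f$center, ctr, tolerance = 1e-8)
    expect_equal(f$radius, r, tolerance = 1e-8)
    expect_lt(f$rms_residual, 1e-9)
  }
})

test_that("noisy circle fit recovers the center and matches the geometric oracle", {
  set.seed(1)
  th <- seq(0.3, 2 * pi - 0.3, length.out = 12)
  pts <- cbind(-20 + 12 * cos(th), 12 * sin(th)) +
    matrix(rnorm(24, 0, 0.2), 12, 2)
  f <- fit_circle(pts)
  expect_lt(sqrt(sum((f$center - c(-20, 0))^2)), 0.3)
  expect_lt(sqrt(sum((f$center - oracle_circle_center(pts))^2)), 0.01)
})

test_that("circle fit rejects degenerate input, naming the structure", {
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1)), label = "medial_plateau"),
               "medial_plateau.*3 points|3 points.*medial_plateau")
  expect_error(fit_circle(rbind(c(0, 0), c(1, 1), c(2, 2), c(3, 3)),
                          label = "medial_plateau"),
               "collinear")
})

test_that("total least-squares line fit matches examples and the eigen oracle", {
  expect_equal(axis_angle(fit_line(rbind(c(0, 0), c(1, 1)))), 45)
  expect_equal(axis_angle(fit_line(cbind(c(0, 2, 4, 6), 0))), 0)

  # near-vertical lines are handled (the reason for TLS over regression)
  expect_equal(axis_angle(fit_line(rbind(c(0, 0), c(0.001, 10)))),
               fold_angle(atan2(10, 0.001) * 180 / pi))

  set.seed(2)
  x <- seq(0, 9)
  pts <- cbind(x, 0.5 * x + rnorm(10, 0, 0.1))
  ang <- axis_angle(fit_line(pts))
  expect_lt(abs(ang - atan(0.5) * 180 / pi), 1)
  expect_equal(ang, oracle_line_angle(pts), tolerance = 1e-6)

  set.seed(22)
  for (i in 1:30) {
    pts <- matrix(rnorm(2 * sample(2:12, 1), sd = 5), ncol = 2)
    if (nrow(unique(pts)) < 2) next
    expect_equal(axis_angle(fit_line(pts)), oracle_line_angle(pts),
                 tolerance = 1e-6)
  }
  expect_error(fit_line(rbind(c(1, 1), c(1, 1))), "distinct")
})

test_that("bisector takes the near-vertical representative and bisects exactly", {
  deg2vec <- function(a) c(cos(a * pi / 180), sin(a * pi / 180))
  b <- bisector_direction(deg2vec(100), deg2vec(60))
  expect_equal(fold_angle(atan2(b[2], b[1]) * 180 / pi), 80)
  expect_equal(bisector_direction(deg2vec(95), deg2vec(85)), c(0, 1),
               tolerance = 1e-12)
  # identical axes return the common direction
  expect_equal(bisector_direction(deg2vec(37), deg2vec(37)), deg2vec(37),
               tolerance = 1e-12)

  # equal unsigned angles to both inputs, over random axis pairs
  set.seed(3)
  for (i in 1:50) {
    a <- runif(1, 0, 180); c2 <- runif(1, 0, 180)
    u <- deg2vec(a); v <- deg2vec(c2)
    b <- bisector_direction(u, v)
    angle_to <- function(w) {
      d <- abs(fold_angle(atan2(b[2], b[1]) * 180 / pi) -
                 fold_angle(atan2(w[2], w[1]) * 180 / pi))
      min(d %% 180, 180 - d %% 180)
    }
    expect_lt(abs(angle_to(u) - angle_to(v)), 1e-9)
  }
})

test_that("perpendicular is an involution on axes and shifts angles by 90", {
  p <- perpendicular(c(cos(80 * pi / 180), sin(80 * pi / 180)))
  expect_equal(fold_angle(atan2(p[2], p[1]) * 180 / pi), -10)
  expect_equal(perpendicular(c(0, 1)), c(1, 0))
  set.seed(4)
  for (i in 1:25) {
    d <- c(cos(a <- runif(1, 0, 2 * pi)), sin(a))
    pp <- perpendicular(perpendicular(d))
    expect_equal(abs(sum(pp * d)), 1, tolerance = 1e-12)  # same axis
    diff <- axis_angle(perpendicular(d)) - axis_angle(d)
    expect_equal(abs(diff), 90, tolerance = 1e-9)
  }
})

test_that("raw axis angles fold into (-90, 90]", {
  expect_equal(axis_angle(c(1, 0)), 0)
  expect_equal(axis_angle(c(1, 1)), 45)
  expect_equal(axis_angle(c(10, -3)), -16.69924423, tolerance = 1e-7)
  expect_equal(axis_angle(c(0, 1)), 90)
  expect_equal(axis_angle(c(0, -1)), 90)   # same undirected axis
  expect_equal(fold_angle(170), -10)
  expect_equal(fold_angle(-90), 90)
})

test_that("anatomical sign convention makes mirror-image limbs identical", {
  expect_equal(anatomical_sign(0, "left"), 0)
  expect_equal(anatomical_sign(0, "right"), 0)
  expect_equal(anatomical_sign(-16.699, "right"), -16.699)
  expect_equal(anatomical_sign(16.699, "left"), -16.699)
  expect_error(anatomical_sign(5, "bilateral"), "side")

  # reflecting a point set about a vertical line and swapping side leaves
  # the anatomical angle unchanged
  set.seed(5)
  for (i in 1:25) {
    pts <- matrix(rnorm(12, sd = 8), ncol = 2)
    x0 <- runif(1, -10, 10)
    a_right <- anatomical_sign(axis_angle(fit_line(pts)), "right")
    a_left <- anatomical_sign(axis_angle(fit_line(mirror_points(pts, x0))), "left")
    expect_equal(a_right, a_left, tolerance = 1e-9)
  }
})

test_that("rotating input points shifts every raw angle by the rotation", {
  set.seed(6)
  for (i in 1:20) {
    pts <- matrix(rnorm(16, sd = 6), ncol = 2)
    th <- runif(1, -170, 170)
    ctr <- runif(2, -5, 5)
    a0 <- axis_angle(fit_line(pts))
    a1 <- axis_angle(fit_line(rotate_points(pts, th, ctr)))
    expect_equal(fold_angle(a1 - a0 - th), 0, tolerance = 1e-8)
  }
})
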