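test_that("compute_scale follows the reference segment and rejects degeneracy", {
  p <- function(x, y) pixel_point(x, y)
  expect_equal(compute_scale(calibration_segment(p(0, 0), p(100, 0), 2))$pixels_per_cm, 50)
  expect_equal(compute_scale(calibration_segment(p(0, 0), p(30, 40), 2))$pixels_per_cm, 25)
  expect_error(compute_scale(calibration_segment(p(5, 5), p(5, 5), 2)),
               "degenerate calibration")
  expect_error(calibration_segment(p(0, 0), p(1, 0), known_length_cm = 0),
               "positive")
  expect_error(calibration_segment(p(0, 0), p(1, 0), known_length_cm = -2),
               "positive")
})

test_that("distance_cm matches brute force, is symmetric and metric", {
  scale <- compute_scale(calibration_segment(pixel_point(0, 0),
                                             pixel_point(50, 0), 1))
  expect_equal(distance_cm(pixel_point(0, 0), pixel_point(50, 0), scale), 1)
  expect_equal(distance_cm(pixel_point(3, 4), pixel_point(3, 4), scale), 0)
  set.seed(11)
  for (i in 1:100) {
    a <- runif(2, -500, 500); b <- runif(2, -500, 500); c <- runif(2, -500, 500)
    p <- pixel_point(a[1], a[2]); q <- pixel_point(b[1], b[2])
    r <- pixel_point(c[1], c[2])
    brute <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2) / 50
    d_pq <- distance_cm(p, q, scale)
    expect_equal(d_pq, brute, tolerance = 1e-12)
    expect_identical(d_pq, distance_cm(q, p, scale))
    expect_gte(d_pq, 0)
    # triangle inequality (allow fp slack)
    expect_lte(d_pq,
               distance_cm(p, r, scale) + distance_cm(r, q, scale) + 1e-12)
  }
})

test_that("distance_cm refuses mixed frames without a transform", {
  scale <- compute_scale(calibration_segment(pixel_point(0, 0),
                                             pixel_point(50, 0), 1))
  expect_error(distance_cm(pixel_point(0, 0), pixel_point(1, 1, "other"), scale),
               "frame mismatch")
})

test_that("level_of projects onto the midline axis and is rotation invariant", {
  ml <- midline(pixel_point(0, 0), pixel_point(0, 100))
  expect_equal(level_of(pixel_point(-30, 40), ml), 40)
  expect_equal(level_of(pixel_point(0, 0), ml), 0)
  expect_error(midline(pixel_point(5, 5), pixel_point(5, 5)), "degenerate")

  rot <- function(xy, deg) {
    th <- deg * pi / 180
    c(cos(th) * xy[1] - sin(th) * xy[2], sin(th) * xy[1] + cos(th) * xy[2])
  }
  set.seed(7)
  for (i in 1:25) {
    s <- runif(2, -50, 50); e <- runif(2, -50, 50); p <- runif(2, -50, 50)
    if (all(s == e)) next
    lvl0 <- level_of(pixel_point(p[1], p[2]),
                     midline(pixel_point(s[1], s[2]), pixel_point(e[1], e[2])))
    s2 <- rot(s, 30); e2 <- rot(e, 30); p2 <- rot(p, 30)
    lvl1 <- level_of(pixel_point(p2[1], p2[2]),
                     midline(pixel_point(s2[1], s2[2]), pixel_point(e2[1], e2[2])))
    expect_equal(lvl0, lvl1, tolerance = 1e-9)
  }
})

test_that("level_difference_cm: sign convention, magnitude, invariance", {
  ml <- midline(pixel_point(0, 0), pixel_point(0, 100))
  scale <- compute_scale(calibration_segment(pixel_point(0, 0),
                                             pixel_point(10, 0), 1))
  # mirror-symmetric pair
  sym <- level_difference_cm(pixel_point(-30, 40), pixel_point(30, 40), ml, scale)
  expect_equal(sym$signed_cm, 0)
  expect_equal(sym$magnitude_cm, 0)
  # levels 40 vs 46 px at 10 px/cm
  ld <- level_difference_cm(pixel_point(-30, 40), pixel_point(30, 46), ml, scale)
  expect_equal(ld$magnitude_cm, 0.6)
  expect_equal(ld$signed_cm, -0.6)  # right landmark more superior
  # rigid motion leaves the value alone
  mv <- function(xy) {
    th <- 77 * pi / 180
    c(cos(th) * xy[1] - sin(th) * xy[2] + 12.5,
      sin(th) * xy[1] + cos(th) * xy[2] - 31)
  }
  a <- mv(c(-30, 40)); b <- mv(c(30, 46)); s <- mv(c(0, 0)); e <- mv(c(0, 100))
  ca <- mv(c(0, 0)); cb <- mv(c(10, 0))
  ld2 <- level_difference_cm(
    pixel_point(a[1], a[2]), pixel_point(b[1], b[2]),
    midline(pixel_point(s[1], s[2]), pixel_point(e[1], e[2])),
    compute_scale(calibration_segment(pixel_point(ca[1], ca[2]),
                                      pixel_point(cb[1], cb[2]), 1)))
  expect_equal(ld2$magnitude_cm, 0.6, tolerance = 1e-9)
  # consistency: magnitude equals the distance between the projected points
  proj <- function(p) {
    lvl <- level_of(p, ml)
    pixel_point(lvl * 0, lvl)  # vertical midline: projection is (0, level)
  }
  expect_equal(ld$magnitude_cm,
               distance_cm(proj(pixel_point(-30, 40)),
                           proj(pixel_point(30, 46)), scale))
})

test_that("midline_distance_cm is the perpendicular point-line distance", {
  ml <- midline(pixel_point(0, 0), pixel_point(0, 100))
  scale <- compute_scale(calibration_segment(pixel_point(0, 0),
                                             pixel_point(10, 0), 1))
  expect_equal(midline_distance_cm(pixel_point(-30, 40), ml, scale), 3)
  expect_equal(midline_distance_cm(pixel_point(0, 77), ml, scale), 0)
  set.seed(13)
  for (i in 1:100) {
    s <- runif(2, -100, 100); e <- runif(2, -100, 100); p <- runif(2, -100, 100)
    ax <- e - s
    if (sum(ax^2) == 0) next
    brute <- abs((p[1] - s[1]) * ax[2] - (p[2] - s[2]) * ax[1]) /
      sqrt(sum(ax^2)) / 10
    got <- midline_distance_cm(
      pixel_point(p[1], p[2]),
      midline(pixel_point(s[1], s[2]), pixel_point(e[1], e[2])), scale)
    expect_equal(got, brute, tolerance = 1e-12)
  }
})

test_that("bind_photos recovers a forward-simulated similarity transform", {
  # identity when coordinates coincide
  ml1 <- midline(pixel_point(10, 20, "a"), pixel_point(10, 220, "a"))
  ml2 <- midline(pixel_point(10, 20, "b"), pixel_point(10, 220, "b"))
  tf <- bind_photos(ml1, ml2)
  expect_equal(tf$rotation_rad, 0)
  expect_equal(tf$scale_factor, 1)
  expect_equal(tf$translation_px, c(0, 0))

  # forward simulate: secondary = primary rotated 15 deg, scaled 1.3, shifted
  th <- 15 * pi / 180; sc <- 1.3; sh <- c(40, -25)
  fwd <- function(xy) sc * c(cos(th) * xy[1] - sin(th) * xy[2],
                             sin(th) * xy[1] + cos(th) * xy[2]) + sh
  prim <- list(sup = c(300, 100), inf = c(310, 600))
  sec_sup <- fwd(prim$sup); sec_inf <- fwd(prim$inf)
  tf2 <- bind_photos(
    midline(pixel_point(prim$sup[1], prim$sup[2], "pri"),
            pixel_point(prim$inf[1], prim$inf[2], "pri")),
    midline(pixel_point(sec_sup[1], sec_sup[2], "sec"),
            pixel_point(sec_inf[1], sec_inf[2], "sec")))
  set.seed(5)
  for (i in 1:20) {
    xy <- runif(2, 0, 800)
    mapped <- apply_transform(tf2, {
      f <- fwd(xy); pixel_point(f[1], f[2], "sec")
    })
    expect_equal(c(mapped$x, mapped$y), xy, tolerance = 1e-9)
  }
  # endpoints map exactly
  got <- apply_transform(tf2, pixel_point(sec_sup[1], sec_sup[2], "sec"))
  expect_equal(c(got$x, got$y), prim$sup, tolerance = 1e-9)

  expect_error(
    bind_photos(ml1, midline(pixel_point(1, 1, "b"), pixel_point(1, 1, "b"))),
    "degenerate")
})

test_that("bind_photos warns on calibration inconsistency beyond tolerance", {
  mk_scale <- function(ppc, id) {
    compute_scale(calibration_segment(pixel_point(0, 0, id),
                                      pixel_point(ppc * 2, 0, id), 2))
  }
  ml_p <- midline(pixel_point(0, 0, "p"), pixel_point(0, 200, "p"))
  ml_s <- midline(pixel_point(0, 0, "s"), pixel_point(0, 260, "s"))  # 1.3x
  # calibrations claim equal resolution -> 30% disagreement
  expect_warning(
    bind_photos(ml_p, ml_s, mk_scale(35, "p"), mk_scale(35, "s")),
    "calibration inconsistency")
  # consistent calibrations -> silent
  expect_silent(
    bind_photos(ml_p, ml_s, mk_scale(35, "p"), mk_scale(35 * 1.3, "s")))
})

test_that("apply_transform respects frames and round-trips with its inverse", {
  ml1 <- midline(pixel_point(5, 5, "a"), pixel_point(5, 300, "a"))
  ml2 <- midline(pixel_point(100, 50, "b"), pixel_point(160, 340, "b"))
  tf <- bind_photos(ml1, ml2)
  expect_error(apply_transform(tf, pixel_point(1, 1, "a")), "frame mismatch")
  inv <- invert_transform(tf)
  set.seed(3)
  for (i in 1:20) {
    xy <- runif(2, -100, 900)
    back <- apply_transform(inv, apply_transform(tf, pixel_point(xy[1], xy[2], "b")))
    expect_equal(c(back$x, back$y), xy, tolerance = 1e-10)
    expect_identical(back$photo_id, "b")
  }
  # pure translation
  tt <- bind_photos(midline(pixel_point(10, 0, "a"), pixel_point(10, 100, "a")),
                    midline(pixel_point(0, 0, "b"), pixel_point(0, 100, "b")))
  moved <- apply_transform(tt, pixel_point(0, 0, "b"))
  expect_equal(c(moved$x, moved$y), c(10, 0))
})
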