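# Tortuosity, centerlines, alpha-shape cross-sections, enclosure, spacing
# and plate zoning.

test_that("global tortuosity matches the analytic arcs", {
  straight <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 2, 0))
  expect_equal(global_tortuosity(straight), 1.0)
  expect_equal(global_tortuosity(circle_arc(pi / 2)), pi / (2 * sqrt(2)),
               tolerance = 1e-4)
  expect_equal(global_tortuosity(circle_arc(pi)), pi / 2, tolerance = 1e-4)
  # full circle: coincident endpoints are rejected as undefined
  expect_error(global_tortuosity(circle_arc(2 * pi)), "undefined")
})

test_that("tortuosity >= 1 on random polylines, = 1 only for straight ones", {
  set.seed(8)
  for (i in 1:25) {
    pts <- matrix(stats::rnorm(median(3:9) * 3 * 2), ncol = 3)
    t <- global_tortuosity(pts)
    expect_gte(t, 1 - 1e-9)
  }
  expect_equal(global_tortuosity(rbind(c(0, 0, 0), c(0.3, 0, 0), c(1.1, 0, 0))), 1)
})

test_that("local tortuosity windows are exact on straight and helical tracks", {
  straight <- mt_track("s", cbind(seq(0, 2, by = 0.05), 0, 0), plus_end = "first")
  lt <- local_tortuosity(straight)
  expect_equal(nrow(lt), 4L)
  expect_equal(lt$tortuosity, rep(1, 4), tolerance = 1e-9)
  # helix r = 0.3, pitch factor c = 0.1: closed-form window arc/chord ratio
  r <- 0.3; cc <- 0.1
  speed <- sqrt(r^2 + cc^2)
  tt <- seq(0, 6 * pi, by = 0.01)
  helix <- mt_track("h", cbind(r * cos(tt), r * sin(tt), cc * tt),
                    plus_end = "first")
  lt2 <- local_tortuosity(helix, segment_length = 0.5)
  dt <- 0.5 / speed
  chord <- sqrt((2 * r * sin(dt / 2))^2 + (cc * dt)^2)
  expect_true(all(abs(lt2$tortuosity - 0.5 / chord) < 0.01 * 0.5 / chord))
  # windows tile the track: n_windows * 0.5 <= spline length < (n+1) * 0.5
  sl <- spline_length(helix)
  expect_equal(nrow(lt2), floor(sl / 0.5 + 1e-9))
  # too-short track gives an empty result
  short <- mt_track("x", rbind(c(0, 0, 0), c(0.3, 0, 0)))
  expect_equal(nrow(local_tortuosity(short)), 0L)
})

make_bundle <- function(offsets, n = 9, len = 4, bend = 0) {
  # parallel (or bent) KMTs along -y from plate at y = 0
  trs <- lapply(seq_len(nrow(offsets)), function(i) {
    s <- seq(0, len, by = 0.1)
    x <- offsets[i, 1] + bend * (s / len)^2
    mt_track(sprintf("F%02d", i), cbind(x, -s, offsets[i, 2]),
             plus_end = "first", mt_class = "KMT", fiber_id = "KA")
  })
  spindle(trs, poles = list(pole(c(0, -4.5, 0), label = "P1"),
                            pole(c(0, 4.5, 0), label = "P2")),
          kinetochores = list(kinetochore("KA", vapply(trs, `[[`, "", "id"))))
}

test_that("the fiber centerline is the member path for degenerate bundles", {
  # identical parallel KMTs: centerline equals any member's path
  one <- make_bundle(matrix(c(0.1, 0.2), 1), len = 3)
  cl <- fiber_centerline(one, "KA")
  expect_equal(cl$points[1, ], c(0.1, 0, 0.2), tolerance = 1e-9)
  expect_equal(cl$points[nrow(cl$points), ], c(0.1, -3, 0.2), tolerance = 1e-9)
  # two parallel KMTs offset +-d: centerline midway
  two <- make_bundle(rbind(c(-0.1, 0), c(0.1, 0)), len = 3)
  cl2 <- fiber_centerline(two, "KA")
  expect_true(all(abs(cl2$points[, 1]) < 1e-9))
  # random bundles vs per-station component-wise median oracle
  set.seed(13)
  offs <- cbind(stats::rnorm(7, 0, 0.1), stats::rnorm(7, 0, 0.1))
  sp <- make_bundle(offs, len = 3)
  cl3 <- fiber_centerline(sp, "KA")
  for (fi in c(1, 5, length(cl3$fractions))) {
    fr <- cl3$fractions[fi]
    manual <- apply(vapply(sp$tracks, function(t) {
      pts <- t$points
      s <- c(0, cumsum(sqrt(rowSums((pts[-1, ] - pts[-nrow(pts), ])^2))))
      x <- fr * s[length(s)]
      i <- max(which(s <= x + 1e-12)); i <- min(i, length(s) - 1)
      w <- (x - s[i]) / (s[i + 1] - s[i])
      pts[i, ] * (1 - w) + pts[i + 1, ] * w
    }, numeric(3)), 1, median)
    expect_equal(cl3$points[fi, ], manual, tolerance = 1e-9)
  }
})

test_that("cross-section areas match closed forms and the convex-hull oracle", {
  # 4 KMTs at the corners of a 0.3 x 0.3 um square
  sq <- make_bundle(rbind(c(-0.15, -0.15), c(0.15, -0.15),
                          c(0.15, 0.15), c(-0.15, 0.15)), len = 3)
  cs <- cross_section_polygon_area(sq, "KA", 0.5)
  expect_equal(cs$polygon_area, 0.09, tolerance = 1e-6)
  # 6 KMTs on a regular hexagon of circumradius r
  r <- 0.2
  th <- seq(0, 2 * pi, length.out = 7)[-7]
  hx <- make_bundle(cbind(r * cos(th), r * sin(th)), len = 3)
  cs2 <- cross_section_polygon_area(hx, "KA", 0.5)
  expect_equal(cs2$polygon_area, 3 * sqrt(3) / 2 * r^2, tolerance = 1e-6)
  # fewer than 3 plane hits: area undefined
  two <- make_bundle(rbind(c(-0.1, 0), c(0.1, 0)), len = 3)
  expect_true(is.na(cross_section_polygon_area(two, "KA", 0.5)$polygon_area))
  # random convex configurations: alpha-shape area at large alpha equals the
  # convex-hull shoelace area
  set.seed(14)
  for (i in 1:25) {
    xy <- matrix(stats::rnorm(stats::rbinom(1, 20, 0.8) * 2, 0, 0.2), ncol = 2)
    expect_equal(alpha_shape_2d(xy, alpha = 50)$area, oracle_hull_area(xy),
                 tolerance = 1e-9)
  }
})

test_that("cross-section area is invariant under in-plane rotation", {
  set.seed(15)
  xy <- matrix(stats::rnorm(24, 0, 0.2), ncol = 2)
  a0 <- alpha_shape_2d(xy, alpha = 10)$area
  for (th in c(0.3, 1.2, 2.7)) {
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    expect_equal(alpha_shape_2d(xy %*% R, alpha = 10)$area, a0,
                 tolerance = 1e-9)
  }
})

test_that("the enclosure profile is 1 for rigid bundles and tracks an oracle on splayed ones", {
  rigid <- make_bundle(rbind(c(-0.1, -0.1), c(0.1, -0.1), c(0.1, 0.1),
                             c(-0.1, 0.1), c(0, 0)), len = 4)
  prof <- enclosed_fraction_profile(rigid, "KA")
  expect_true(all(prof$fraction == 1))
  expect_equal(prof$fraction[1], 1) # kinetochore station by construction
  # splaying bundle: KMTs diverge linearly; compare with direct
  # point-in-circle counting at each station
  splay <- make_bundle(rbind(c(-0.05, 0), c(0.05, 0), c(0, 0.05),
                             c(0, -0.05), c(0.02, 0.02)), len = 4, bend = 1.5)
  # give each KMT its own bend so the bundle spreads
  splay$tracks <- lapply(seq_along(splay$tracks), function(i) {
    t <- splay$tracks[[i]]
    s <- seq(0, 4, by = 0.1)
    t$points[, 1] <- t$points[1, 1] + (i - 3) * 0.4 * (s / 4)^2
    t
  })
  prof2 <- enclosed_fraction_profile(splay, "KA")
  R <- attr(prof2, "radius")
  cl <- fiber_centerline(splay, "KA")
  s <- c(0, cumsum(sqrt(rowSums((cl$points[-1, ] - cl$points[-nrow(cl$points), ])^2))))
  for (k in c(1, nrow(prof2))) {
    arc <- prof2$arc_position[k]
    i <- max(which(s <= arc + 1e-9)); i <- min(i, length(s) - 1)
    w <- if (s[i + 1] > s[i]) (arc - s[i]) / (s[i + 1] - s[i]) else 0
    ctr <- cl$points[i, ] * (1 - w) + cl$points[i + 1, ] * w
    # oracle: count KMTs whose y = ctr[2] crossing lies within R (the bundle
    # runs along -y, so the cutting plane is y = const)
    n_in <- 0
    for (t in splay$tracks) {
      pts <- t$points
      j <- which.min(abs(pts[, 2] - ctr[2]))
      if (sqrt(sum((pts[j, c(1, 3)] - ctr[c(1, 3)])^2)) <= R) n_in <- n_in + 1
    }
    expect_equal(prof2$n_enclosed[k], n_in)
  }
  expect_lt(prof2$fraction[nrow(prof2)], 1) # splayed at the far end
})

test_that("nearest-neighbour spacing matches hand geometry and a brute-force matrix", {
  # two KMTs 74 nm apart
  two <- make_bundle(rbind(c(0, 0), c(0.074, 0)), len = 3)
  sp2 <- kmt_neighbor_spacing(two, "KA")
  expect_equal(sp2$mean, 0.074, tolerance = 1e-9)
  # equilateral triangle of side s: every nearest neighbour is s away
  s <- 0.1
  tri <- make_bundle(rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2)), len = 3)
  expect_equal(kmt_neighbor_spacing(tri, "KA")$mean, s, tolerance = 1e-9)
  expect_equal(kmt_neighbor_spacing(tri, "KA")$sd, 0, tolerance = 1e-9)
  # random planar sets vs the full distance matrix
  set.seed(16)
  offs <- matrix(stats::rnorm(16, 0, 0.1), ncol = 2)
  spr <- make_bundle(offs, len = 3)
  got <- kmt_neighbor_spacing(spr, "KA")
  D <- as.matrix(stats::dist(offs)); diag(D) <- Inf
  expect_equal(sort(got$distances), sort(apply(D, 1, min)), tolerance = 1e-9)
  # single KMT: undefined
  one <- make_bundle(matrix(c(0, 0), 1), len = 3)
  expect_error(kmt_neighbor_spacing(one, "KA"), "fewer than 2")
})

test_that("minimum enclosing circle contains all points with minimal radius", {
  set.seed(17)
  for (i in 1:10) {
    xy <- matrix(stats::rnorm(stats::rbinom(1, 12, 0.9) * 2), ncol = 2)
    mec <- min_enclosing_circle(xy)
    d <- sqrt(rowSums(sweep(xy, 2, mec$center)^2))
    expect_true(all(d <= mec$radius + 1e-9))
    # at least two points on the boundary (or radius 0)
    expect_true(mec$radius == 0 || sum(abs(d - mec$radius) < 1e-7) >= 2)
  }
})

test_that("plate zoning fits the ellipse and assigns the three zones", {
  # kinetochores on a known ellipse (a = 2, b = 1.2 in x/z) plus centre points
  set.seed(18)
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  ring <- cbind(2 * cos(th), 1.2 * sin(th))
  mk <- function(id, x, z) {
    p <- c(x, 0.5, z)
    mt_track(id, rbind(p, p + c(0, -3, 0)), plus_end = "first",
             mt_class = "KMT", fiber_id = id)
  }
  trs <- c(lapply(seq_len(nrow(ring)), function(i)
    mk(sprintf("R%02d", i), ring[i, 1], ring[i, 2])),
    list(mk("C1", 0.01, 0.01)))
  kins <- lapply(trs, function(t) kinetochore(t$fiber_id, t$id))
  sp <- spindle(trs, poles = list(pole(c(0, -4.5, 0), label = "P1"),
                                  pole(c(0, 4.5, 0), label = "P2")),
                kinetochores = kins)
  z <- assign_zones(sp)
  fit <- attr(z, "ellipse")
  expect_equal(fit$a, 2, tolerance = 0.05)
  expect_equal(fit$b, 1.2, tolerance = 0.05)
  expect_identical(z$zone[z$kinetochore_id == "C1"], "central")
  expect_true(all(z$zone[z$kinetochore_id != "C1"] == "peripheral"))
  # noisy ellipse recovery within 5%
  noisy <- ring + matrix(stats::rnorm(length(ring), 0, 0.05), ncol = 2)
  fit2 <- fit_ellipse_direct(noisy)
  expect_equal(fit2$a, 2, tolerance = 0.05)
  expect_equal(fit2$b, 1.2, tolerance = 0.05)
  expect_error(assign_zones(spindle(trs[1:3],
                                    kinetochores = kins[1:3])), "at least 5")
})

test_that("tortuosity increases with length on generator bundles", {
  g <- generate_spindle(generator_config(seed = 19, n_pairs = 12, nonkmt_count = 0))
  kmts <- Filter(function(t) t$mt_class == "KMT", g$spindle$tracks)
  tor <- vapply(kmts, global_tortuosity, 0)
  len <- vapply(kmts, spline_length, 0)
  expect_gt(stats::cor(tor, len), 0) # sign check mirrors the reported positive correlation
})
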