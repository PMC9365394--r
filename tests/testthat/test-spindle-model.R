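# Core data model, spline lengths, Z-expansion, border filtering and I/O.

test_that("spline_length matches hand values and an independent oracle", {
  expect_equal(spline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 2.0)
  # unit semicircle at 1-degree sampling
  expect_equal(spline_length(circle_arc(pi)), pi, tolerance = 1e-3)
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(stats::rnorm(30), ncol = 3)
    manual <- 0
    for (j in 1:(nrow(pts) - 1)) manual <- manual + sqrt(sum((pts[j + 1, ] - pts[j, ])^2))
    expect_equal(spline_length(pts), manual, tolerance = 1e-12)
  }
})

test_that("spline_length is rigid-motion invariant", {
  set.seed(11)
  for (i in 1:10) {
    pts <- matrix(stats::rnorm(24), ncol = 3)
    rt <- random_rigid()
    expect_equal(spline_length(apply_rigid(pts, rt)), spline_length(pts),
                 tolerance = 1e-9)
  }
})

test_that("mt_track validates its invariants", {
  expect_error(mt_track("a", matrix(1:3, 1)), "at least 2")
  expect_error(mt_track("a", rbind(c(0, 0, 0), c(0, 0, 0))), "distinct")
  expect_error(mt_track("a", rbind(c(0, 0, NA), c(1, 0, 0))), "finite")
  t <- mt_track("a", rbind(c(0, 0, 0), c(1, 0, 0)), plus_end = "first")
  expect_equal(plus_end_point(t), c(0, 0, 0))
  expect_equal(minus_end_point(t), c(1, 0, 0))
})

test_that("apply_z_expansion scales z only and composes multiplicatively", {
  t <- mt_track("a", rbind(c(0, 0, 1), c(1, 2, 3)))
  sp <- spindle(list(t), poles = list(pole(c(0, 0, -1), label = "P1"),
                                      pole(c(0, 0, 2), label = "P2")))
  same <- apply_z_expansion(sp, 1.0)
  expect_equal(same$tracks[[1]]$points, t$points)
  ex <- apply_z_expansion(sp, 1.3)
  expect_equal(ex$tracks[[1]]$points[1, ], c(0, 0, 1.3))
  expect_equal(ex$tracks[[1]]$points[2, 1:2], c(1, 2))
  expect_equal(ex$poles[[2]]$mother_centriole, c(0, 0, 2.6))
  expect_equal(ex$z_factor, 1.3)
  # composition: (a then b) == (a*b)
  ab <- apply_z_expansion(apply_z_expansion(sp, 1.2), 1.5)
  once <- apply_z_expansion(sp, 1.8)
  expect_equal(ab$tracks[[1]]$points, once$tracks[[1]]$points, tolerance = 1e-12)
  expect_error(apply_z_expansion(sp, 0), "positive")
  expect_error(apply_z_expansion(sp, 0.8), ">= 1")
})

test_that("the Z-factor reproduces the nominal/measured thickness arithmetic", {
  # 300 nm x 22 sections = 6.6 um nominal; a stack measured at 6.6/1.3 um
  # must give back the applied factor of 1.3
  expect_equal(z_factor_from_thickness(300, 22, 6.6 / 1.3), 1.3)
})

test_that("neutral JSON round-trip preserves geometry and labels", {
  sp <- small_interaction_spindle(5, n_tracks = 12)
  sp$kinetochores[[1]]$sister_id <- NA_character_
  dir <- withr::local_tempdir()
  path <- file.path(dir, "sp.json")
  write_spatial_graph(sp, path)
  sp2 <- read_spatial_graph(path, dialect = "neutral_json")
  expect_equal(length(sp2$tracks), length(sp$tracks))
  for (i in seq_along(sp$tracks)) {
    expect_equal(sp2$tracks[[i]]$points, sp$tracks[[i]]$points,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(sp2$tracks[[i]]$mt_class, sp$tracks[[i]]$mt_class)
    expect_identical(sp2$tracks[[i]]$plus_end, sp$tracks[[i]]$plus_end)
  }
  expect_equal(sp2$poles[[1]]$mother_centriole, sp$poles[[1]]$mother_centriole)
  expect_identical(sp2$kinetochores[[1]]$kmt_ids, sp$kinetochores[[1]]$kmt_ids)
  # writing in nm and reading back normalises to um
  path_nm <- file.path(dir, "sp_nm.json")
  write_spatial_graph(sp, path_nm, unit = "nm")
  sp3 <- read_spatial_graph(path_nm)
  expect_equal(sp3$tracks[[1]]$points, sp$tracks[[1]]$points, tolerance = 1e-9)
})

test_that("the Amira ASCII dialect reader parses a minimal fixture", {
  fixture <- c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    "define VERTEX 6",
    "define EDGE 3",
    "define POINT 10",
    "",
    "Parameters { ContentType \"HxSpatialGraph\" }",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "",
    "@1",
    "0 0 0", "1 0 0", "0 1 0", "1 1 0", "0 2 0", "1 2 0",
    "",
    "@2",
    "0 1", "2 3", "4 5",
    "",
    "@3",
    "3", "4", "3",
    "",
    "@4",
    "0 0 0", "0.5 0 0", "1 0 0",
    "0 1 0", "0.3 1 0", "0.7 1 0", "1 1 0",
    "0 2 0", "0.5 2 0", "1 2 0")
  path <- withr::local_tempfile(fileext = ".am")
  writeLines(fixture, path)
  sp <- read_spatial_graph(path, dialect = "amira_ascii")
  expect_equal(length(sp$tracks), 3L)
  expect_equal(vapply(sp$tracks, function(t) nrow(t$points), 0L), c(3L, 4L, 3L))
  # independent line-count check on the raw file: the @4 block must hold
  # exactly as many coordinate rows as NumEdgePoints declares
  lines <- readLines(path)
  at4 <- which(trimws(lines) == "@4")
  coord_rows <- sum(grepl("^[0-9. -]+$", trimws(lines[(at4 + 1):length(lines)])) &
                      nzchar(trimws(lines[(at4 + 1):length(lines)])))
  expect_equal(coord_rows, 10L)
  expect_equal(sum(vapply(sp$tracks, function(t) nrow(t$points), 0L)), coord_rows)
  # nm-unit read scales into um
  sp_nm <- read_spatial_graph(path, dialect = "amira_ascii", unit = "nm")
  expect_equal(sp_nm$tracks[[1]]$points, sp$tracks[[1]]$points / 1000)
})

test_that("malformed Amira input fails with a parse error", {
  path <- withr::local_tempfile(fileext = ".am")
  writeLines(c("# AmiraMesh 3D ASCII 2.0", "define VERTEX 1"), path)
  expect_error(read_spatial_graph(path, dialect = "amira_ascii"), "parse error")
  writeLines(c("not amira"), path)
  expect_error(read_spatial_graph(path, dialect = "amira_ascii"), "line 1")
})

test_that("border filtering matches a brute-force endpoint check", {
  # hand-constructed: one endpoint 0.05 um from a face is discarded
  bb <- rbind(min = c(0, 0, 0), max = c(5, 5, 5))
  near <- mt_track("near", rbind(c(0.05, 2, 2), c(1, 2, 2)))
  far <- mt_track("far", rbind(c(2, 2, 2), c(3, 3, 3)))
  sp <- spindle(list(near, far), bounding_box = bb)
  res <- filter_border_tracks(sp, margin = 0.1)
  expect_identical(res$report$track_id, "near")
  expect_equal(length(res$spindle$tracks), 1L)
  # nothing removed when everything is clear of the faces
  res2 <- filter_border_tracks(spindle(list(far), bounding_box = bb), 0.1)
  expect_equal(nrow(res2$report), 0L)
  # random spindle: equality with a per-endpoint brute-force scan
  sp3 <- random_test_spindle(40, seed = 3)
  bb3 <- sp3$bounding_box
  res3 <- filter_border_tracks(sp3, margin = 0.25)
  expected <- vapply(sp3$tracks, function(t) {
    drop <- FALSE
    for (p in list(t$points[1, ], t$points[nrow(t$points), ])) {
      for (k in 1:3) {
        if (p[k] - bb3[1, k] < 0.25 || bb3[2, k] - p[k] < 0.25) drop <- TRUE
      }
    }
    drop
  }, NA)
  expect_setequal(res3$report$track_id,
                  vapply(sp3$tracks, `[[`, "", "id")[expected])
})

test_that("an empty spindle filters to an empty result with a warning", {
  sp <- spindle(list(), bounding_box = rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_warning(res <- filter_border_tracks(sp), "empty")
  expect_equal(nrow(res$report), 0L)
})
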