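# KMT classification, fiber assembly, sister pairing and staging metrics.

test_that("classification is the identity on pre-labelled tracks", {
  sp <- small_interaction_spindle(2, n_tracks = 9)
  before <- vapply(sp$tracks, `[[`, "", "mt_class")
  sp2 <- classify_kmts(sp)
  expect_identical(vapply(sp2$tracks, `[[`, "", "mt_class"), before)
  # unlabelled tracks without markers are rejected
  un <- spindle(list(mt_track("u", rbind(c(0, 0, 0), c(1, 0, 0)))))
  expect_error(classify_kmts(un), "markers")
})

test_that("marker-based classification attaches by plus-end proximity", {
  marker <- c(0, 0, 0)
  near <- mt_track("near", rbind(c(0.05, 0, 0), c(2, 0, 0)), plus_end = "first")
  far <- mt_track("far", rbind(c(1, 1, 1), c(3, 3, 3)), plus_end = "first")
  sp <- spindle(list(near, far),
                poles = list(pole(c(4, 0, 0), label = "P1"),
                             pole(c(-4, 0, 0), label = "P2")))
  sp2 <- classify_kmts(sp, markers = matrix(marker, 1), attach_radius = 0.1)
  cls <- vapply(sp2$tracks, `[[`, "", "mt_class")
  expect_identical(cls, c("KMT", "non-KMT"))
  expect_equal(length(sp2$kinetochores), 1L)
  expect_identical(sp2$kinetochores[[1]]$kmt_ids, "near")
})

test_that("marker-based classification recovers generator labels >= 99%", {
  g <- generate_spindle(generator_config(seed = 21, n_pairs = 10,
                                         nonkmt_count = 600))
  truth_cls <- vapply(g$spindle$tracks, `[[`, "", "mt_class")
  # strip the labels, keep the end annotations implicit
  stripped <- g$spindle
  stripped$tracks <- lapply(stripped$tracks, function(t) {
    t$mt_class <- "unclassified"; t$fiber_id <- NA_character_; t
  })
  stripped$kinetochores <- list()
  markers <- as.matrix(g$truth$kinetochores[, c("x", "y", "z")])
  rec <- classify_kmts(stripped, markers = markers, attach_radius = 0.25)
  got <- vapply(rec$tracks, `[[`, "", "mt_class")
  expect_gte(mean(got == truth_cls), 0.99)
})

test_that("pole_to_pole_distance is the mother-centriole separation", {
  sp <- spindle(list(mt_track("a", rbind(c(0, 0, 0), c(1, 0, 0)))),
                poles = list(pole(c(0, 0, 0) + c(0, 0, 1e-9), label = "P1"),
                             pole(c(9, 0, 0), label = "P2")))
  expect_equal(pole_to_pole_distance(sp), 9.0, tolerance = 1e-6)
  set.seed(5)
  for (i in 1:10) {
    a <- stats::rnorm(3); b <- stats::rnorm(3)
    spi <- spindle(list(mt_track("a", rbind(c(0, 0, 0), c(1, 0, 0)))),
                   poles = list(pole(a, label = "P1"), pole(b, label = "P2")))
    expect_equal(pole_to_pole_distance(spi), sqrt(sum((a - b)^2)))
  }
  expect_error(pole_to_pole_distance(spindle(list(mt_track("a", rbind(c(0, 0, 0), c(1, 0, 0)))))),
               "poles")
})

test_that("inter-kinetochore distances use component-wise median centres", {
  # sisters as point masses 1.1 um apart
  mk <- function(id, x, fiber) mt_track(id, rbind(c(x, 0, 0), c(x + 2 * (if (x < 0.5) -1 else 1), 0, 0)),
                                        plus_end = "first", mt_class = "KMT", fiber_id = fiber)
  tr <- list(mk("a1", 0, "KA"), mk("a2", 0, "KA"), mk("b1", 1.1, "KB"))
  sp <- spindle(tr, kinetochores = list(kinetochore("KA", c("a1", "a2"), "KB"),
                                        kinetochore("KB", "b1", "KA")))
  d <- interkinetochore_distances(sp)
  expect_equal(nrow(d), 1L)
  expect_equal(d$distance, 1.1)
  # scattered plus ends vs a hand-computed median
  set.seed(9)
  pa <- matrix(stats::rnorm(15, 0, 0.05), ncol = 3)
  pb <- matrix(stats::rnorm(15, 2, 0.05), ncol = 3)
  mk2 <- function(id, p, fiber, away) mt_track(id, rbind(p, p + away),
                                               plus_end = "first",
                                               mt_class = "KMT", fiber_id = fiber)
  tra <- lapply(1:5, function(i) mk2(paste0("a", i), pa[i, ], "KA", c(-3, 0, 0)))
  trb <- lapply(1:5, function(i) mk2(paste0("b", i), pb[i, ], "KB", c(3, 0, 0)))
  sp2 <- spindle(c(tra, trb),
                 kinetochores = list(kinetochore("KA", paste0("a", 1:5), "KB"),
                                     kinetochore("KB", paste0("b", 1:5), "KA")))
  d2 <- interkinetochore_distances(sp2)
  manual <- sqrt(sum((apply(pa, 2, median) - apply(pb, 2, median))^2))
  expect_equal(d2$distance, manual, tolerance = 1e-12)
})

test_that("mutual-nearest-neighbour sister pairing is symmetric", {
  g <- generate_spindle(generator_config(seed = 4, n_pairs = 8, nonkmt_count = 0))
  sp <- g$spindle
  # drop the generator pairing and recompute it
  sp$kinetochores <- lapply(sp$kinetochores, function(k) {
    k$sister_id <- NA_character_; k
  })
  sp <- pair_sisters(sp)
  ids <- vapply(sp$kinetochores, `[[`, "", "id")
  sis <- vapply(sp$kinetochores, `[[`, "", "sister_id")
  paired <- !is.na(sis)
  expect_true(any(paired))
  for (i in which(paired)) {
    j <- match(sis[i], ids)
    expect_identical(sis[j], ids[i])
  }
  # every pairing made agrees with the generator truth (ambiguous
  # kinetochores may stay unpaired, but must never be mis-paired)
  truth <- g$truth$kinetochores
  tsis <- truth$sister_id[match(ids, truth$id)]
  expect_true(all(sis[paired] == tsis[paired]))
  expect_gte(mean(paired), 0.5)
})

test_that("unpaired kinetochores are skipped with a warning", {
  mk <- function(id, x, fiber) mt_track(id, rbind(c(x, 0, 0), c(x, 1, 0)),
                                        plus_end = "first", mt_class = "KMT",
                                        fiber_id = fiber)
  sp <- spindle(list(mk("a", 0, "KA")),
                kinetochores = list(kinetochore("KA", "a")))
  expect_warning(d <- interkinetochore_distances(sp), "unpaired")
  expect_equal(nrow(d), 0L)
})

test_that("kmts_per_kinetochore summarises counts and ignores track order", {
  mk <- function(id, fiber) mt_track(id, rbind(stats::rnorm(3), stats::rnorm(3) + 5),
                                     mt_class = "KMT", fiber_id = fiber)
  set.seed(2)
  tr <- c(lapply(1:8, function(i) mk(paste0("a", i), "KA")),
          lapply(1:9, function(i) mk(paste0("b", i), "KB")),
          lapply(1:10, function(i) mk(paste0("c", i), "KC")))
  kins <- list(kinetochore("KA", paste0("a", 1:8)),
               kinetochore("KB", paste0("b", 1:9)),
               kinetochore("KC", paste0("c", 1:10)))
  sp <- spindle(tr, kinetochores = kins)
  k <- kmts_per_kinetochore(sp)
  expect_equal(k$mean, 9.0)
  expect_equal(unname(k$counts), c(8L, 9L, 10L))
  sp_shuf <- spindle(tr[sample(seq_along(tr))], kinetochores = kins)
  expect_equal(kmts_per_kinetochore(sp_shuf)$counts, k$counts)
})

test_that("KMT counts per kinetochore recover the generator's count law", {
  g <- generate_spindle(generator_config(seed = 31, n_pairs = 50,
                                         nonkmt_count = 0))
  k <- kmts_per_kinetochore(g$spindle)
  se <- 2.2 / sqrt(length(k$counts))
  expect_lt(abs(k$mean - 9), 2 * se + 0.25) # rounding the counts shifts the mean slightly
})

test_that("the staging report reproduces printed KMT fractions from counts", {
  # 797 KMTs of 4884 MTs -> 16.3%
  expect_equal(round(100 * 797 / 4884, 1), 16.3)
  g <- generate_spindle(generator_config(seed = 6, n_pairs = 5, nonkmt_count = 200))
  st <- staging_report(g$spindle)
  expect_equal(st$kmt_fraction, st$n_KMT / (st$n_KMT + st$n_nonKMT))
  expect_equal(st$n_kinetochores, 10L)
  expect_true(all(st$interkinetochore$distance >= 0))
})
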