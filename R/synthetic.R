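# Parametric synthetic spindle generator. Produces a labelled spindle whose
# statistical structure mirrors HeLa metaphase reconstructions - two poles
# ~9 um apart, ~100 kinetochores in sister pairs on an elliptical metaphase
# plate, k-fibers of ~9 KMTs with a broad length distribution, non-KMTs with
# exponential lengths and a minus-end density peaked ~1 um from the poles
# over a flat bulk - together with a ground-truth table for recovery tests.
#
# Geometry conventions: the pole-to-pole axis is y; the metaphase plate lies
# in the x/z plane at y = 0. KMT polylines run from the plus end (at the
# kinetochore) to the minus end (poleward), bent as a circular arc in a
# random plane so that the true tortuosity has the closed form
# (theta/2) / sin(theta/2).

#' Generator configuration
#'
#' Defaults state the emulated biology: 9-um pole separation, 50 sister
#' pairs (~100 kinetochores, matching per-spindle tomogram counts), KMT
#' counts from a truncated normal (mean 9, sd 2.2, min 1), broad
#' near-uniform KMT lengths between 0.2 um and 0.8 x pole distance, 5400 non-KMTs
#' with exponential lengths (mean 2 um) and 38% of their minus ends in a
#' Gaussian shell (mu 1.0 um, sigma 0.297 um, so that mu + 2 HWHM = 1.7 um)
#' around a pole, 74-nm KMT packing at the kinetochore, and arc curvature
#' increasing with length.
#'
#' @param seed integer RNG seed; fully determines the output.
#' @param pole_distance mother-centriole separation (um).
#' @param n_pairs number of sister-kinetochore pairs.
#' @param kmt_count_law list(mean, sd, min): truncated-normal KMT count per
#'   kinetochore.
#' @param kmt_length_law list(min, max_frac): uniform KMT length between
#'   `min` and `max_frac * pole_distance` (um).
#' @param nonkmt_count number of non-KMTs.
#' @param nonkmt_length_law list(mean, min, max): exponential non-KMT length
#'   (um), truncated.
#' @param minus_end_pole_fraction share of non-KMT minus ends in the
#'   pole-proximal Gaussian shell (the rest are uniform in the spindle body).
#' @param pole_peak_law list(mu, sigma): Gaussian radial law of shell
#'   minus-end distances to the mother centriole (um).
#' @param plate_ellipse list(a, b): metaphase-plate semi-axes in x/z (um).
#' @param interkinetochore_law list(mean, sd): sister separation along the
#'   spindle axis (um).
#' @param curvature_law list(rate, sd): per-KMT bend angle theta =
#'   kappa * length with kappa ~ truncated normal(rate, sd, min 0) (rad/um);
#'   set rate = sd = 0 for straight MTs.
#' @param kmt_spacing centre-to-centre KMT packing distance at the
#'   kinetochore (um).
#' @param point_jitter isotropic per-vertex jitter sd (um).
#' @param sample_step polyline sampling step (um).
#' @param chromosome_clearance minimum distance of non-KMT endpoints to any
#'   kinetochore centre (um); chromosome bodies exclude MT ends.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             pole_distance = 9.0,
                             n_pairs = 50L,
                             kmt_count_law = list(mean = 9, sd = 2.2, min = 1),
                             kmt_length_law = list(min = 0.2, max_frac = 0.8),
                             nonkmt_count = 5400L,
                             nonkmt_length_law = list(mean = 2.0, min = 0.1, max = 8),
                             minus_end_pole_fraction = 0.38,
                             pole_peak_law = list(mu = 1.0, sigma = 0.297),
                             plate_ellipse = list(a = 2.4, b = 1.8),
                             interkinetochore_law = list(mean = 1.13, sd = 0.24),
                             curvature_law = list(rate = 0.35, sd = 0.15),
                             kmt_spacing = 0.074,
                             point_jitter = 0.002,
                             sample_step = 0.1,
                             chromosome_clearance = 0.3) {
  cfg <- list(seed = as.integer(seed), pole_distance = pole_distance,
              n_pairs = as.integer(n_pairs), kmt_count_law = kmt_count_law,
              kmt_length_law = kmt_length_law,
              nonkmt_count = as.integer(nonkmt_count),
              nonkmt_length_law = nonkmt_length_law,
              minus_end_pole_fraction = minus_end_pole_fraction,
              pole_peak_law = pole_peak_law, plate_ellipse = plate_ellipse,
              interkinetochore_law = interkinetochore_law,
              curvature_law = curvature_law, kmt_spacing = kmt_spacing,
              point_jitter = point_jitter, sample_step = sample_step,
              chromosome_clearance = chromosome_clearance)
  stopifnot(cfg$pole_distance > 0, cfg$n_pairs >= 1,
            cfg$nonkmt_count >= 0, cfg$kmt_spacing > 0)
  if (max(cfg$plate_ellipse$a, cfg$plate_ellipse$b) >= cfg$pole_distance)
    stop("infeasible geometry: metaphase plate larger than the spindle")
  class(cfg) <- "generator_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, min = -Inf, max = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), min), max))
  out <- stats::rnorm(n, mean, sd)
  bad <- out < min | out > max
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out < min | out > max
  }
  out
}

# Hexagonal packing offsets (2D) around the origin: centre, then rings.
hex_offsets <- function(n, spacing) {
  pts <- matrix(0, 1, 2)
  ring <- 1L
  while (nrow(pts) < n) {
    k <- 6L * ring
    ang <- 2 * pi * (seq_len(k) - 1L) / k + pi / 6 * ring
    pts <- rbind(pts, spacing * ring * cbind(cos(ang), sin(ang)))
    ring <- ring + 1L
  }
  pts[seq_len(n), , drop = FALSE]
}

# Circular-arc polyline of arc length L and total bend theta whose *chord*
# runs from p0 along the unit vector `dir`; the arc bows sideways into the
# plane spanned by dir and the unit normal n0. Chord length is
# L * sin(theta/2) / (theta/2); tortuosity is the closed form
# (theta/2) / sin(theta/2).
arc_polyline <- function(p0, dir, n0, L, theta, step) {
  n_seg <- max(4L, ceiling(L / step))
  s <- seq(0, L, length.out = n_seg + 1L)
  if (theta < 1e-9) {
    return(p0[rep(1L, length(s)), , drop = FALSE] + outer(s, dir))
  }
  R <- L / theta
  phi0 <- theta / 2
  u <- (sin(phi0) - sin(phi0 - s / R)) * R        # along the chord
  v <- (cos(phi0 - s / R) - cos(phi0)) * R        # lateral bow
  sweep(outer(u, dir) + outer(v, n0), 2, p0, "+")
}

unit <- function(v) v / sqrt(sum(v^2))

random_unit_perp <- function(t0) {
  repeat {
    v <- stats::rnorm(3)
    v <- v - sum(v * t0) * t0
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Generate a synthetic spindle with ground truth
#'
#' @param config a [generator_config].
#' @return list with `spindle` (a labelled, sister-paired [spindle]) and
#'   `truth`: `kmt` (per-KMT table: fiber, closed-form length and
#'   tortuosity, minus-end pole distance), `kinetochores` (true centres,
#'   plate radius and zone), `nonkmt` (lengths, minus-end pole distances),
#'   `nominal_cutoff` (mu + 2 HWHM of the pole peak law) and summary truths
#'   used by the recovery tests.
#' @export
generate_spindle <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  pd <- config$pole_distance
  p1 <- c(0, -pd / 2, 0)
  p2 <- c(0, pd / 2, 0)
  poles <- list(pole(p1, daughter_centriole = p1 + c(0.3, 0.1, 0), label = "P1"),
                pole(p2, daughter_centriole = p2 + c(-0.3, -0.1, 0), label = "P2"))
  a <- config$plate_ellipse$a
  b <- config$plate_ellipse$b
  np <- config$n_pairs
  # sister pairs on the plate: uniform over the ellipse area
  rr <- sqrt(stats::runif(np))
  phi <- stats::runif(np, 0, 2 * pi)
  px <- rr * a * cos(phi)
  pz <- rr * b * sin(phi)
  sep <- rtrunc_norm(np, config$interkinetochore_law$mean,
                     config$interkinetochore_law$sd, min = 0.5, max = 2)
  tracks <- list()
  kins <- list()
  kmt_truth <- list()
  kin_truth <- list()
  kid <- 0L
  tid <- 0L
  kin_centers <- matrix(0, 0, 3)
  for (i in seq_len(np)) {
    for (side in c(-1, 1)) {
      kid <- kid + 1L
      kin_id <- sprintf("K%03d", kid)
      center <- c(px[i], side * sep[i] / 2, pz[i])
      kin_centers <- rbind(kin_centers, center)
      mypole <- if (side < 0) p1 else p2
      fiber_axis <- unit(mypole - center)
      n_kmt <- max(1L, round(rtrunc_norm(1, config$kmt_count_law$mean,
                                         config$kmt_count_law$sd,
                                         min = config$kmt_count_law$min)))
      offs <- hex_offsets(n_kmt, config$kmt_spacing)
      # in-plate basis perpendicular to the fiber axis
      e1 <- random_unit_perp(fiber_axis)
      e2 <- unit(c(fiber_axis[2] * e1[3] - fiber_axis[3] * e1[2],
                   fiber_axis[3] * e1[1] - fiber_axis[1] * e1[3],
                   fiber_axis[1] * e1[2] - fiber_axis[2] * e1[1]))
      lmin <- config$kmt_length_law$min
      lmax <- config$kmt_length_law$max_frac * pd
      kmt_ids <- character(n_kmt)
      for (m in seq_len(n_kmt)) {
        tid <- tid + 1L
        id <- sprintf("KMT%05d", tid)
        kmt_ids[m] <- id
        plus_pos <- center + offs[m, 1] * e1 + offs[m, 2] * e2 +
          stats::rnorm(3, 0, 0.005)
        L <- stats::runif(1, lmin, lmax)
        kappa <- rtrunc_norm(1, config$curvature_law$rate,
                             config$curvature_law$sd, min = 0)
        theta <- kappa * L
        t0 <- unit(fiber_axis + stats::rnorm(3, 0, 0.03))
        n0 <- random_unit_perp(t0)
        pts <- arc_polyline(matrix(plus_pos, 1), t0, n0, L, theta,
                            config$sample_step)
        if (config$point_jitter > 0)
          pts <- pts + matrix(stats::rnorm(length(pts), 0, config$point_jitter),
                              nrow(pts))
        tracks[[tid]] <- mt_track(id, pts, plus_end = "first",
                                  mt_class = "KMT", fiber_id = kin_id)
        minus_pos <- pts[nrow(pts), ]
        dmin <- min(dist_pp(minus_pos, p1), dist_pp(minus_pos, p2))
        kmt_truth[[tid]] <- data.frame(
          id = id, fiber_id = kin_id, length = L,
          tortuosity = if (theta < 1e-9) 1 else (theta / 2) / sin(theta / 2),
          theta = theta, minus_pole_distance = dmin)
      }
      rel_r <- sqrt((px[i] / a)^2 + (pz[i] / b)^2)
      kin_truth[[kid]] <- data.frame(
        id = kin_id, x = center[1], y = center[2], z = center[3],
        sister_id = sprintf("K%03d", if (side < 0) kid + 1L else kid - 1L),
        n_kmts = n_kmt, relative_radius = rel_r,
        zone = if (rel_r < 0.5) "central" else if (rel_r < 0.75)
          "intermediate" else "peripheral")
      kins[[kid]] <- kinetochore(kin_id, kmt_ids = kmt_ids,
                                 sister_id = kin_truth[[kid]]$sister_id)
    }
  }
  # non-KMTs ----------------------------------------------------------------
  body_ax <- c(a + 0.6, pd / 2 + 1.0, b + 0.6) # spindle body semi-axes
  clear2 <- config$chromosome_clearance^2
  clear_ok <- function(p) {
    if (nrow(kin_centers) == 0L) return(TRUE)
    all(rowSums((kin_centers - matrix(p, nrow(kin_centers), 3, byrow = TRUE))^2) > clear2)
  }
  in_body <- function(p) sum((p / body_ax)^2) <= 1
  nk <- config$nonkmt_count
  nonkmt_truth <- list()
  for (j in seq_len(nk)) {
    tid <- tid + 1L
    id <- sprintf("MT%05d", tid)
    at_pole <- stats::runif(1) < config$minus_end_pole_fraction
    for (try in 1:200) {
      if (at_pole) {
        mypole <- if (stats::runif(1) < 0.5) p1 else p2
        r <- rtrunc_norm(1, config$pole_peak_law$mu, config$pole_peak_law$sigma,
                         min = 0.05)
        dirv <- unit(stats::rnorm(3))
        minus_pos <- mypole + r * dirv
      } else {
        minus_pos <- (2 * stats::runif(3) - 1) * body_ax
        if (!in_body(minus_pos)) next
        mypole <- if (dist_pp(minus_pos, p1) < dist_pp(minus_pos, p2)) p1 else p2
      }
      if (!clear_ok(minus_pos)) next
      # growth direction: away from the owning pole, toward the midzone
      growth <- unit(unit(c(0, -sign(mypole[2]), 0)) + 0.6 * stats::rnorm(3))
      L <- stats::rexp(1, 1 / config$nonkmt_length_law$mean)
      if (L < config$nonkmt_length_law$min || L > config$nonkmt_length_law$max) next
      kappa <- rtrunc_norm(1, 0.15, 0.1, min = 0)
      theta <- kappa * L
      n0 <- random_unit_perp(growth)
      pts <- arc_polyline(matrix(minus_pos, 1), growth, n0, L, theta,
                          config$sample_step)
      plus_pos <- pts[nrow(pts), ]
      if (!clear_ok(plus_pos)) next
      if (config$point_jitter > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), 0, config$point_jitter),
                            nrow(pts))
      tracks[[tid]] <- mt_track(id, pts, plus_end = "last",
                                mt_class = "non-KMT")
      dmin <- min(dist_pp(minus_pos, p1), dist_pp(minus_pos, p2))
      nonkmt_truth[[j]] <- data.frame(id = id, length = L,
                                      minus_pole_distance = dmin,
                                      shell = at_pole)
      break
    }
    if (length(tracks) < tid) tid <- tid - 1L # all tries failed; skip quietly
  }
  pts_all <- do.call(rbind, lapply(tracks, `[[`, "points"))
  bb <- rbind(apply(pts_all, 2, min) - 0.25, apply(pts_all, 2, max) + 0.25)
  dimnames(bb) <- list(c("min", "max"), c("x", "y", "z"))
  sp <- spindle(tracks, poles = poles, kinetochores = kins, bounding_box = bb,
                z_factor = 1,
                provenance = sprintf("synthetic seed=%d", config$seed))
  kmt_tab <- do.call(rbind, kmt_truth)
  non_tab <- if (length(nonkmt_truth)) do.call(rbind, nonkmt_truth) else
    data.frame(id = character(), length = double(),
               minus_pole_distance = double(), shell = logical())
  kin_tab <- do.call(rbind, kin_truth)
  hwhm <- config$pole_peak_law$sigma * sqrt(2 * log(2))
  cutoff <- config$pole_peak_law$mu + 2 * hwhm
  truth <- list(
    kmt = kmt_tab, kinetochores = kin_tab, nonkmt = non_tab,
    nominal_cutoff = cutoff,
    mean_kmts_per_kinetochore = mean(kin_tab$n_kmts),
    mean_kmt_length = mean(kmt_tab$length),
    mean_kmt_tortuosity = mean(kmt_tab$tortuosity),
    pole_association_fraction = mean(kmt_tab$minus_pole_distance <= cutoff),
    config = config)
  list(spindle = sp, truth = truth)
}

#' Plant known MT-MT interactions
#'
#' Re-routes selected non-KMTs so that a known association exists, for
#' closed-loop detector tests. Two plant types:
#' * `"lattice"`: the source track is replaced by an offset copy of a span
#'   of the target, running at exactly `distance` for `length` micrometres.
#' * `"end"`: the source track is translated so its minus end sits exactly
#'   `distance` from the target's minus end.
#'
#' @param spindle a [spindle].
#' @param plants data frame with columns `type` ("lattice" or "end"),
#'   `source_id`, `target_id`, `distance` (um), and for lattice plants
#'   `length` (um) and `at_arc` (span start on the target, um).
#' @return list with `spindle` (modified) and `planted` (the input table).
#' @export
plant_interactions <- function(spindle, plants) {
  ids <- vapply(spindle$tracks, `[[`, "", "id")
  for (r in seq_len(nrow(plants))) {
    p <- plants[r, ]
    si <- match(p$source_id, ids)
    ti <- match(p$target_id, ids)
    if (is.na(si) || is.na(ti)) stop("unknown track id in plant ", r)
    target <- spindle$tracks[[ti]]
    if (p$type == "lattice") {
      tp <- target$points
      s <- cum_arclength(tp)
      total <- s[length(s)]
      a0 <- min(p$at_arc, max(total - p$length, 0))
      stations <- seq(a0, min(a0 + p$length, total), by = 0.01)
      if (length(stations) < 2L)
        stop("target track too short for the requested plant span")
      base <- interp_at_arclength(tp, s, stations)
      tg <- unit(base[nrow(base), ] - base[1L, ])
      off <- random_unit_perp(tg)
      newpts <- base + matrix(off * p$distance, nrow(base), 3, byrow = TRUE)
      spindle$tracks[[si]]$points <- newpts
      spindle$tracks[[si]]$plus_end <- "last"
    } else if (p$type == "end") {
      tgt_end <- minus_end_point(target)
      src <- spindle$tracks[[si]]
      src_end <- minus_end_point(src)
      dirv <- unit(stats::rnorm(3))
      shift <- (tgt_end + dirv * p$distance) - src_end
      spindle$tracks[[si]]$points <-
        src$points + matrix(shift, nrow(src$points), 3, byrow = TRUE)
    } else stop("unknown plant type: ", p$type)
  }
  spindle$bounding_box <- tracks_bbox(spindle$tracks)
  spindle$bounding_box <- spindle$bounding_box +
    matrix(c(-0.25, 0.25), 2, 3) # keep endpoints clear of the border filter
  list(spindle = spindle, planted = plants)
}
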