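# K-fiber morphology: tortuosity (global and in 500-nm windows), fiber
# centerlines, alpha-shape cross-section areas, KMT enclosure profiles,
# nearest-neighbour KMT spacing, and metaphase-plate zoning.

#' Global tortuosity of a track
#'
#' Spline length divided by the 3D distance between the two ends. Straight
#' tracks give 1; a quarter-circle arc gives pi/(2*sqrt(2)) ~ 1.11 and a
#' half circle pi/2 ~ 1.57.
#'
#' @param track an [mt_track] or n x 3 matrix.
#' @return tortuosity >= 1.
#' @export
global_tortuosity <- function(track) {
  pts <- if (inherits(track, "mt_track")) track$points else as.matrix(track)
  chord <- dist_pp(pts[1L, ], pts[nrow(pts), ])
  if (chord < 1e-12)
    stop("coincident endpoints: global tortuosity undefined")
  spline_length(pts) / chord
}

# Points of a track ordered from the plus end (kinetochore side first).
points_from_plus <- function(track) {
  if (track$plus_end == "last") track$points[rev(seq_len(nrow(track$points))), , drop = FALSE]
  else track$points
}

#' Local tortuosity in 500-nm windows
#'
#' The track is cut into consecutive non-overlapping arc-length windows of
#' `segment_length`, anchored at the plus (kinetochore) end; the trailing
#' residual shorter than a full window is discarded. Each window reports its
#' arc/chord ratio and the window midpoint.
#'
#' @param track an [mt_track].
#' @param segment_length window length in micrometres (default 0.5).
#' @param spindle optional [spindle]; when given (and the track is a KMT
#'   with a kinetochore) the window midpoint is also mapped to the
#'   pole-to-kinetochore axis.
#' @return data frame: `window`, `arc_start`, `arc_mid_fraction`,
#'   `tortuosity`, `axis_position` (NA without spindle context). Tracks
#'   shorter than one window give zero rows.
#' @export
local_tortuosity <- function(track, segment_length = 0.5, spindle = NULL) {
  pts <- points_from_plus(track)
  s <- cum_arclength(pts)
  total <- s[length(s)]
  n_win <- floor(total / segment_length + 1e-9)
  empty <- data.frame(window = integer(), arc_start = double(),
                      arc_mid_fraction = double(), tortuosity = double(),
                      axis_position = double())
  if (n_win < 1L) return(empty)
  out <- empty
  for (w in seq_len(n_win)) {
    a <- (w - 1L) * segment_length
    b <- w * segment_length
    inner <- which(s > a & s < b)
    wa <- interp_at_arclength(pts, s, a)
    wb <- interp_at_arclength(pts, s, b)
    wpts <- rbind(wa, pts[inner, , drop = FALSE], wb)
    chord <- dist_pp(wpts[1L, ], wpts[nrow(wpts), ])
    tor <- if (chord < 1e-12) NA_real_ else spline_length(wpts) / chord
    mid <- interp_at_arclength(pts, s, (a + b) / 2)
    axis_pos <- NA_real_
    if (!is.null(spindle) && track$mt_class == "KMT" && !is.na(track$fiber_id))
      axis_pos <- tryCatch(
        relative_axis_position(spindle, track, point = as.numeric(mid)),
        error = function(e) NA_real_)
    out <- rbind(out, data.frame(window = w, arc_start = a,
                                 arc_mid_fraction = (a + b) / 2 / total,
                                 tortuosity = tor, axis_position = axis_pos))
  }
  out
}

fiber_tracks <- function(spindle, fiber_id) {
  trs <- Filter(function(t) t$mt_class == "KMT" && !is.na(t$fiber_id) &&
                  t$fiber_id == fiber_id, spindle$tracks)
  if (length(trs) == 0L) stop("no KMTs in fiber ", fiber_id)
  trs
}

#' Median centerline of a k-fiber
#'
#' Each KMT is resampled at a common set of normalized arc fractions
#' (kinetochore end = 0); the centerline point at a fraction is the
#' component-wise median over the fiber's KMTs. The number of stations is
#' set so that stations are about `step` apart along the longest KMT.
#'
#' @param spindle a classified [spindle].
#' @param fiber_id kinetochore/fiber identifier.
#' @param step nominal station spacing (um), default 0.5.
#' @return list with `points` (m x 3 centerline polyline), `fractions`
#'   (normalized arc positions, 0 = kinetochore) and `n_kmts`.
#' @export
fiber_centerline <- function(spindle, fiber_id, step = 0.5) {
  trs <- fiber_tracks(spindle, fiber_id)
  lens <- vapply(trs, spline_length, 0)
  m <- max(2L, ceiling(max(lens) / step) + 1L)
  fr <- seq(0, 1, length.out = m)
  stations <- lapply(trs, function(t) {
    pts <- points_from_plus(t)
    s <- cum_arclength(pts)
    interp_at_arclength(pts, s, fr * s[length(s)])
  })
  ctr <- sapply(seq_len(m), function(i) {
    apply(do.call(rbind, lapply(stations, function(S) S[i, ])), 2, stats::median)
  })
  list(points = t(ctr), fractions = fr, n_kmts = length(trs))
}

# Intersections of the fiber's KMTs with the plane through `origin` with
# normal `tangent`; returns in-plane 2D coordinates (one hit per KMT, the
# crossing nearest the origin) plus the KMT ids that hit.
fiber_plane_hits <- function(trs, origin, tangent) {
  tangent <- tangent / sqrt(sum(tangent^2))
  # in-plane orthonormal basis
  ref <- if (abs(tangent[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * tangent) * tangent
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(tangent[2] * e1[3] - tangent[3] * e1[2],
          tangent[3] * e1[1] - tangent[1] * e1[3],
          tangent[1] * e1[2] - tangent[2] * e1[1])
  hits <- matrix(0, 0, 2)
  ids <- character()
  touch_tol <- 0.02 # um: terminal vertices this close to the plane count as hits
  for (t in trs) {
    pts <- t$points
    sd <- as.numeric((pts - matrix(origin, nrow(pts), 3, byrow = TRUE)) %*% tangent)
    cross <- which(sd[-length(sd)] * sd[-1L] <= 0 &
                   abs(sd[-length(sd)] - sd[-1L]) > 1e-15)
    cand <- if (length(cross)) t(vapply(cross, function(i) {
      w <- sd[i] / (sd[i] - sd[i + 1L])
      pts[i, ] * (1 - w) + pts[i + 1L, ] * w
    }, numeric(3))) else matrix(0, 0, 3)
    # terminal vertices grazing the plane (e.g. plus ends at the kinetochore
    # station) are valid hits even without a sign change
    for (i in c(1L, nrow(pts))) {
      if (abs(sd[i]) <= touch_tol)
        cand <- rbind(cand, pts[i, ] - sd[i] * tangent)
    }
    if (nrow(cand) == 0L) next
    d2 <- rowSums((cand - matrix(origin, nrow(cand), 3, byrow = TRUE))^2)
    p <- cand[which.min(d2), ]
    hits <- rbind(hits, c(sum((p - origin) * e1), sum((p - origin) * e2)))
    ids <- c(ids, t$id)
  }
  list(hits = hits, ids = ids, basis = rbind(e1, e2), tangent = tangent)
}

centerline_tangent <- function(cl, i) {
  m <- nrow(cl$points)
  i0 <- max(1L, i - 1L)
  i1 <- min(m, i + 1L)
  tg <- cl$points[i1, ] - cl$points[i0, ]
  nrm <- sqrt(sum(tg^2))
  if (nrm < 1e-12) tg <- c(0, 1, 0) else tg <- tg / nrm
  tg
}

#' Cross-section of a k-fiber at a station
#'
#' The cutting plane passes through the centerline point at the requested
#' normalized arc position and is perpendicular to the centerline tangent.
#' KMT intersection points with the plane form a 2D point set whose
#' alpha-shape boundary gives the polygonal cross-section; its planar area
#' equals the 1-um prism-extrusion volume divided by the prism height.
#'
#' @param spindle a classified [spindle].
#' @param fiber_id fiber identifier.
#' @param station normalized arc position along the fiber centerline
#'   (0 = kinetochore, 1 = pole-proximal end).
#' @param alpha alpha-shape disc radius in micrometres (default 10; at
#'   fiber scale this is effectively a convex hull).
#' @param centerline optional precomputed [fiber_centerline].
#' @return object of class `cross_section`: `fiber_id`, `station`,
#'   `origin`, `tangent`, `kmt_hits` (k x 2, in-plane), `hit_ids`,
#'   `polygon_area` (NA with fewer than 3 hits), `n_kmts`.
#' @export
cross_section_polygon_area <- function(spindle, fiber_id, station, alpha = 10,
                                       centerline = NULL) {
  stopifnot(station >= 0, station <= 1)
  cl <- centerline %||% fiber_centerline(spindle, fiber_id)
  trs <- fiber_tracks(spindle, fiber_id)
  s <- cum_arclength(cl$points)
  origin <- as.numeric(interp_at_arclength(cl$points, s, station * s[length(s)]))
  i <- which.min(abs(cl$fractions - station))
  tg <- centerline_tangent(cl, i)
  ph <- fiber_plane_hits(trs, origin, tg)
  area <- if (nrow(ph$hits) >= 3L) alpha_shape_2d(ph$hits, alpha)$area else NA_real_
  structure(list(fiber_id = fiber_id, station = station, origin = origin,
                 tangent = tg, kmt_hits = ph$hits, hit_ids = ph$ids,
                 polygon_area = area, n_kmts = length(trs)),
            class = "cross_section")
}

#' KMT enclosure profile of a k-fiber
#'
#' At the kinetochore station the minimum circle enclosing all KMT hits
#' defines a radius, which is doubled to allow for fiber flexing. At each
#' station along the centerline the fraction of the fiber's KMTs whose
#' plane hit lies within that radius of the centerline point is reported
#' (KMTs that no longer cross the plane count as not enclosed).
#'
#' @param spindle a classified [spindle].
#' @param fiber_id fiber identifier.
#' @param step station spacing along the centerline arc (um), default 0.5.
#' @param radius_floor radius used for single-KMT fibers (um), default 0.05.
#' @return data frame: `station` (normalized), `arc_position` (um),
#'   `n_enclosed`, `fraction`, plus attribute `radius`.
#' @export
enclosed_fraction_profile <- function(spindle, fiber_id, step = 0.5,
                                      radius_floor = 0.05) {
  cl <- fiber_centerline(spindle, fiber_id, step = step)
  trs <- fiber_tracks(spindle, fiber_id)
  n <- length(trs)
  s <- cum_arclength(cl$points)
  total <- s[length(s)]
  # kinetochore-station radius
  ph0 <- fiber_plane_hits(trs, cl$points[1L, ], centerline_tangent(cl, 1L))
  hits0 <- ph0$hits
  if (nrow(hits0) < 1L) {
    ends <- do.call(rbind, lapply(trs, plus_end_point))
    hits0 <- cbind(0, 0)[rep(1, nrow(ends)), , drop = FALSE]
  }
  R <- if (n == 1L || nrow(hits0) < 2L) radius_floor
       else 2 * min_enclosing_circle(hits0)$radius
  R <- max(R, radius_floor)
  arcs <- seq(0, total, by = step)
  rows <- lapply(arcs, function(a) {
    origin <- as.numeric(interp_at_arclength(cl$points, s, a))
    i <- which.min(abs(s - a))
    ph <- fiber_plane_hits(trs, origin, centerline_tangent(cl, i))
    inside <- if (nrow(ph$hits)) sum(sqrt(rowSums(ph$hits^2)) <= R) else 0L
    data.frame(station = if (total > 0) a / total else 0, arc_position = a,
               n_enclosed = inside, fraction = inside / n)
  })
  out <- do.call(rbind, rows)
  attr(out, "radius") <- R
  out
}

#' Nearest-neighbour KMT spacing in a cross-section
#'
#' Centre-to-centre distances between KMT plane hits at a station; for each
#' KMT its `k`-th nearest in-fiber neighbour is taken, and the fiber mean
#' and SD are reported. At the kinetochore of HeLa k-fibers this spacing is
#' about 74 nm.
#'
#' @param spindle a classified [spindle].
#' @param fiber_id fiber identifier.
#' @param station normalized centerline position, default 0 (kinetochore).
#' @param k neighbour rank, default 1.
#' @return list: `distances` (per KMT, um), `mean`, `sd`, `n`.
#' @export
kmt_neighbor_spacing <- function(spindle, fiber_id, station = 0, k = 1L) {
  cs <- cross_section_polygon_area(spindle, fiber_id, station, alpha = 1e6)
  hits <- cs$kmt_hits
  if (nrow(hits) < 2L) stop("fewer than 2 KMTs cross the station plane")
  if (k > nrow(hits) - 1L) stop("k exceeds the number of neighbours")
  D <- as.matrix(stats::dist(hits))
  diag(D) <- Inf
  dk <- apply(D, 1, function(r) sort(r)[k])
  list(distances = dk, mean = mean(dk),
       sd = if (length(dk) > 1L) stats::sd(dk) else NA_real_, n = length(dk))
}

#' Zone assignment of kinetochores on the metaphase plate
#'
#' Kinetochore centres are projected on a 2D plane (X/Z by default, i.e.
#' orthogonal to a y spindle axis; `plane = "auto"` picks the plane
#' orthogonal to the pole-to-pole axis), an ellipse is fitted by direct
#' least squares, and each kinetochore receives its relative elliptical
#' radius r = sqrt((u/a)^2 + (v/b)^2) in the ellipse frame. Zones: central
#' r < 0.5, intermediate 0.5 <= r < 0.75, peripheral r >= 0.75.
#'
#' @param spindle a [spindle] with >= 5 kinetochores.
#' @param plane `"xz"`, `"xy"`, `"yz"` or `"auto"`.
#' @return data frame: `kinetochore_id`, `relative_radius`, `zone`; the
#'   fitted ellipse is attached as attribute `ellipse`.
#' @export
assign_zones <- function(spindle, plane = c("xz", "xy", "yz", "auto")) {
  plane <- match.arg(plane)
  kins <- spindle$kinetochores
  if (length(kins) < 5L) stop("need at least 5 kinetochores for the ellipse fit")
  centers <- t(vapply(kins, function(k) {
    c0 <- kinetochore_center(spindle, k)
    if (is.null(c0)) rep(NA_real_, 3) else c0
  }, numeric(3)))
  keep <- stats::complete.cases(centers)
  if (plane == "auto") {
    if (is.null(spindle$poles)) stop("auto plane needs poles")
    ax <- abs(spindle$poles[[2]]$mother_centriole -
              spindle$poles[[1]]$mother_centriole)
    plane <- c("yz", "xz", "xy")[which.max(ax)]
  }
  cols <- switch(plane, xz = c(1, 3), xy = c(1, 2), yz = c(2, 3))
  xy <- centers[keep, cols, drop = FALSE]
  fit <- fit_ellipse_direct(xy)
  rot <- matrix(c(cos(fit$angle), sin(fit$angle),
                  -sin(fit$angle), cos(fit$angle)), 2, 2)
  uv <- (xy - matrix(fit$center, nrow(xy), 2, byrow = TRUE)) %*% rot
  r <- sqrt((uv[, 1] / fit$a)^2 + (uv[, 2] / fit$b)^2)
  zone <- ifelse(r < 0.5, "central", ifelse(r < 0.75, "intermediate", "peripheral"))
  out <- data.frame(
    kinetochore_id = vapply(kins, `[[`, "", "id")[keep],
    relative_radius = r, zone = zone, stringsAsFactors = FALSE)
  attr(out, "ellipse") <- fit
  out
}
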