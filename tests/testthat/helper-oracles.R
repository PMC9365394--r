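# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (scalar loops, no shared code with R/) so that the
# package implementation can be checked against them.

# scalar point-to-segment distance, written independently of the package
oracle_point_segment <- function(p, a, b) {
  d <- b - a
  len2 <- sum(d^2)
  if (len2 == 0) return(sqrt(sum((p - a)^2)))
  t <- sum((p - a) * d) / len2
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * d))^2))
}

oracle_point_polyline <- function(p, pts) {
  best <- Inf
  for (i in seq_len(nrow(pts) - 1L))
    best <- min(best, oracle_point_segment(p, pts[i, ], pts[i + 1L, ]))
  best
}

# brute-force end-to-lattice detector: every minus end of `end_class`
# against every other track's polyline
oracle_end_lattice <- function(sp, end_class, threshold_um) {
  hits <- list()
  for (t in sp$tracks) {
    if (t$mt_class != end_class) next
    e <- minus_end_point(t)
    for (u in sp$tracks) {
      if (u$id == t$id) next
      if (oracle_point_polyline(e, u$points) <= threshold_um)
        hits[[length(hits) + 1L]] <- c(t$id, u$id)
    }
  }
  if (length(hits) == 0L) return(character())
  sort(vapply(hits, paste, "", collapse = "->"))
}

# brute-force per-step lattice pairing run decomposition
oracle_lattice_runs <- function(sp, threshold_um, step = 0.02) {
  out <- list()
  for (t in sp$tracks) {
    # naive arc-length resampling
    pts <- t$points
    seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seglen))
    stations <- seq(0, s[length(s)], by = step)
    P <- t(vapply(stations, function(x) {
      i <- max(which(s <= x + 1e-12))
      if (i >= length(s)) return(pts[nrow(pts), ])
      w <- (x - s[i]) / (s[i + 1] - s[i])
      pts[i, ] * (1 - w) + pts[i + 1, ] * w
    }, numeric(3)))
    for (u in sp$tracks) {
      if (u$id == t$id) next
      contact <- vapply(seq_len(nrow(P)), function(i)
        oracle_point_polyline(P[i, ], u$points) <= threshold_um, NA)
      # run decomposition
      i <- 1L
      while (i <= length(contact)) {
        if (contact[i]) {
          j <- i
          while (j < length(contact) && contact[j + 1L]) j <- j + 1L
          if (j > i)
            out[[length(out) + 1L]] <- data.frame(
              source_id = t$id, target_id = u$id,
              contact_length = step * (j - i), n_steps = j - i + 1L)
          i <- j + 1L
        } else i <- i + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(source_id = character(), target_id = character(),
                      contact_length = double(), n_steps = integer()))
  d <- do.call(rbind, out)
  d[order(d$source_id, d$target_id, d$contact_length), ]
}

# does segment a-b intersect the axis-aligned cube [lo, hi]? independent
# parametric clipping
oracle_seg_cube <- function(a, b, lo, hi) {
  t0 <- 0; t1 <- 1
  d <- b - a
  for (k in 1:3) {
    if (abs(d[k]) < 1e-15) {
      if (a[k] < lo[k] || a[k] > hi[k]) return(FALSE)
    } else {
      tt <- sort(c((lo[k] - a[k]) / d[k], (hi[k] - a[k]) / d[k]))
      t0 <- max(t0, tt[1]); t1 <- min(t1, tt[2])
    }
  }
  t0 <= t1
}

oracle_voxel_count <- function(sp, center, side) {
  lo <- center - side / 2; hi <- center + side / 2
  n <- 0L
  for (t in sp$tracks) {
    pts <- t$points
    hit <- FALSE
    for (i in seq_len(nrow(pts) - 1L))
      if (oracle_seg_cube(pts[i, ], pts[i + 1L, ], lo, hi)) { hit <- TRUE; break }
    if (hit) n <- n + 1L
  }
  n
}

# shoelace area of the convex hull, the oracle route for alpha-shape areas
oracle_hull_area <- function(xy) {
  h <- grDevices::chull(xy)
  hp <- xy[h, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) return(0)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + hp[i, 1] * hp[j, 2] - hp[j, 1] * hp[i, 2]
  }
  abs(s) / 2
}

# random rigid transform (rotation + translation)
random_rigid <- function() {
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  list(R = Rx %*% Ry %*% Rz, t = stats::rnorm(3, 0, 3))
}

apply_rigid <- function(pts, rt) sweep(pts %*% t(rt$R), 2, -rt$t, "-")

transform_spindle <- function(sp, rt) {
  sp$tracks <- lapply(sp$tracks, function(t) { t$points <- apply_rigid(t$points, rt); t })
  sp$poles <- lapply(sp$poles, function(p) {
    p$mother_centriole <- as.numeric(apply_rigid(matrix(p$mother_centriole, 1), rt))
    if (!is.null(p$daughter_centriole))
      p$daughter_centriole <- as.numeric(apply_rigid(matrix(p$daughter_centriole, 1), rt))
    p
  })
  sp$bounding_box <- NULL
  sp$bounding_box <- kfibergraph:::tracks_bbox(sp$tracks)
  sp
}

# small random unlabelled spindle for IO / filtering tests
random_test_spindle <- function(n_tracks = 20, seed = 99) {
  set.seed(seed)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    start <- stats::rnorm(3, 0, 2)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    npt <- sample(3:12, 1)
    pts <- t(sapply(0:(npt - 1), function(k) start + dir * 0.2 * k +
                      stats::rnorm(3, 0, 0.01)))
    mt_track(sprintf("T%03d", i), pts)
  })
  spindle(tracks, poles = list(pole(c(0, -4, 0), label = "P1"),
                               pole(c(0, 4, 0), label = "P2")))
}

# arc sampled at fine angular resolution (unit radius)
circle_arc <- function(theta_total, n = NULL) {
  if (is.null(n)) n <- max(10, round(theta_total / (pi / 180)))
  th <- seq(0, theta_total, length.out = n + 1)
  cbind(cos(th), sin(th), 0)
}

small_interaction_spindle <- function(seed, n_tracks = 60) {
  set.seed(seed)
  tracks <- lapply(seq_len(n_tracks), function(i) {
    start <- stats::runif(3, 0, 2)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    L <- stats::runif(1, 0.3, 1.5)
    npt <- max(3, round(L / 0.1))
    pts <- t(sapply(seq(0, L, length.out = npt), function(s) start + dir * s))
    # mild kink so polylines are not all straight
    pts <- pts + cbind(0, 0.02 * sin(seq(0, pi, length.out = npt)), 0)
    mt_track(sprintf("S%03d", i), pts,
             mt_class = if (i %% 3 == 0) "KMT" else "non-KMT",
             fiber_id = if (i %% 3 == 0) "K001" else NA_character_)
  })
  kin <- list(kinetochore("K001",
                          kmt_ids = vapply(Filter(function(t) t$mt_class == "KMT",
                                                  tracks), `[[`, "", "id")))
  spindle(tracks, poles = list(pole(c(-1, -1, -1), label = "P1"),
                               pole(c(3, 3, 3), label = "P2")),
          kinetochores = kin)
}
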