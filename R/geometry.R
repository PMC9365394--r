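# Low-level 3D/2D geometry kernels shared by all analysis modules.
# Coordinates are micrometres throughout; points are rows of n x 3 (or n x 2)
# numeric matrices.

#' Euclidean distance between two points
#' @param a,b numeric vectors of equal length.
#' @return scalar distance.
#' @keywords internal
#' @noRd
dist_pp <- function(a, b) sqrt(sum((a - b)^2))

#' Cumulative arc length along a polyline
#'
#' @param pts n x d numeric matrix of ordered polyline points.
#' @return numeric vector of length n; `[1]` is 0, `[n]` is the total
#'   spline length.
#' @keywords internal
cum_arclength <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(rep(0, n))
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  c(0, cumsum(seg))
}

#' Resample a polyline at fixed arc-length steps
#'
#' Linear interpolation along the chordal arc-length parametrisation. The
#' first point is always kept; the last resampled point is the final station
#' at or before the total length (the terminal vertex is appended when
#' `keep_end = TRUE`).
#'
#' @param pts n x 3 matrix.
#' @param step arc-length step in micrometres.
#' @param keep_end append the exact terminal vertex if it is not already a
#'   station.
#' @return m x 3 matrix of resampled points.
#' @keywords internal
polyline_resample <- function(pts, step, keep_end = FALSE) {
  s <- cum_arclength(pts)
  total <- s[length(s)]
  st <- seq(0, total, by = step)
  if (keep_end && total - st[length(st)] > 1e-12) st <- c(st, total)
  interp_at_arclength(pts, s, st)
}

# Interpolate polyline positions at given arc-length stations.
interp_at_arclength <- function(pts, s, stations) {
  idx <- findInterval(stations, s, rightmost.closed = TRUE)
  idx[idx >= length(s)] <- length(s) - 1L
  idx[idx < 1L] <- 1L
  t0 <- s[idx]
  t1 <- s[idx + 1L]
  w <- ifelse(t1 > t0, (stations - t0) / (t1 - t0), 0)
  w <- pmin(pmax(w, 0), 1) # clamp: no extrapolation beyond the polyline

  pts[idx, , drop = FALSE] * (1 - w) + pts[idx + 1L, , drop = FALSE] * w
}

#' Minimum distances from many points to one polyline
#'
#' Exact point-to-segment minimisation over every segment of the polyline,
#' vectorised over both points and segments.
#'
#' @param P m x 3 matrix of query points.
#' @param pts n x 3 polyline.
#' @return numeric vector of m minimum distances.
#' @keywords internal
dists_points_polyline <- function(P, pts) {
  n <- nrow(pts)
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (n == 1L) {
    return(sqrt(rowSums((P - matrix(pts[1L, ], nrow(P), 3, byrow = TRUE))^2)))
  }
  A <- pts[-n, , drop = FALSE]
  B <- pts[-1L, , drop = FALSE]
  D <- B - A
  len2 <- rowSums(D^2)
  len2[len2 == 0] <- 1 # degenerate segments behave as points (t = 0)
  m <- nrow(P)
  best <- rep(Inf, m)
  # loop over coordinates to form m x S matrices without 3D arrays
  PA1 <- outer(P[, 1], A[, 1], "-")
  PA2 <- outer(P[, 2], A[, 2], "-")
  PA3 <- outer(P[, 3], A[, 3], "-")
  tt <- (sweep(PA1, 2, D[, 1], "*") +
         sweep(PA2, 2, D[, 2], "*") +
         sweep(PA3, 2, D[, 3], "*"))
  tt <- sweep(tt, 2, len2, "/")
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  dx <- PA1 - sweep(tt, 2, D[, 1], "*")
  dy <- PA2 - sweep(tt, 2, D[, 2], "*")
  dz <- PA3 - sweep(tt, 2, D[, 3], "*")
  d2 <- dx * dx + dy * dy + dz * dz
  best <- sqrt(apply(d2, 1L, min))
  best
}

#' Does a 3D segment intersect an axis-aligned box?
#'
#' Slab clipping of the segment parameter interval against each axis.
#'
#' @param a,b segment endpoints (length-3 vectors).
#' @param lo,hi box corners (length-3 vectors), `lo <= hi`.
#' @return logical scalar.
#' @keywords internal
segment_intersects_box <- function(a, b, lo, hi) {
  d <- b - a
  t0 <- 0
  t1 <- 1
  for (k in 1:3) {
    if (abs(d[k]) < 1e-15) {
      if (a[k] < lo[k] || a[k] > hi[k]) return(FALSE)
    } else {
      u <- (lo[k] - a[k]) / d[k]
      v <- (hi[k] - a[k]) / d[k]
      if (u > v) { tmp <- u; u <- v; v <- tmp }
      t0 <- max(t0, u)
      t1 <- min(t1, v)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

#' Polygon area by the shoelace formula
#' @param xy k x 2 matrix of polygon vertices in traversal order.
#' @return non-negative area.
#' @keywords internal
shoelace_area <- function(xy) {
  n <- nrow(xy)
  if (n < 3L) return(0)
  x <- xy[, 1]; y <- xy[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Two-dimensional alpha shape of a point set
#'
#' Classical circumcircle formulation: a pair of points at distance `<= 2
#' alpha` spans a boundary edge when at least one of the two discs of radius
#' `alpha` through the pair contains no other point of the set in its
#' interior. For `alpha` large relative to the point spread, the boundary is
#' the convex hull. Boundary edges are chained into closed loops and the
#' enclosed area is the sum of loop areas (shoelace).
#'
#' @param xy n x 2 numeric matrix.
#' @param alpha disc radius, same units as the coordinates (micrometres for
#'   fiber cross-sections). Default 10.
#' @return list with `area` (um^2 when inputs are um), `edges` (k x 2 matrix
#'   of point indices) and `loops` (list of index cycles). Fewer than 3
#'   distinct points give area 0 and no edges.
#' @export
#' @examples
#' sq <- rbind(c(0, 0), c(0.3, 0), c(0.3, 0.3), c(0, 0.3))
#' alpha_shape_2d(sq, alpha = 10)$area # 0.09
alpha_shape_2d <- function(xy, alpha = 10) {
  stopifnot(is.numeric(alpha), alpha > 0)
  xy <- unique(round(as.matrix(xy), 12))
  n <- nrow(xy)
  if (n < 3L) return(list(area = 0, edges = matrix(0L, 0, 2), loops = list()))
  eps <- 1e-12 * max(1, alpha)
  edges <- matrix(0L, 0, 2)
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- xy[i, ]; q <- xy[j, ]
      d <- dist_pp(p, q)
      if (d > 2 * alpha + eps || d < eps) next
      mid <- (p + q) / 2
      h2 <- alpha^2 - (d / 2)^2
      h <- sqrt(max(h2, 0))
      nv <- c(-(q[2] - p[2]), q[1] - p[1]) / d
      others <- xy[-c(i, j), , drop = FALSE]
      for (sgn in c(1, -1)) {
        ctr <- mid + sgn * h * nv
        if (nrow(others) == 0L ||
            all(sqrt((others[, 1] - ctr[1])^2 +
                     (others[, 2] - ctr[2])^2) >= alpha - eps)) {
          edges <- rbind(edges, c(i, j))
          break
        }
      }
    }
  }
  loops <- chain_edge_loops(edges)
  area <- 0
  for (lp in loops) area <- area + shoelace_area(xy[lp, , drop = FALSE])
  list(area = area, edges = edges, loops = loops)
}

# Chain undirected edges into closed vertex loops (greedy walk). Open chains
# (degenerate alpha) are dropped: they bound no area.
chain_edge_loops <- function(edges) {
  if (nrow(edges) == 0L) return(list())
  used <- rep(FALSE, nrow(edges))
  verts <- sort(unique(as.vector(edges)))
  adj <- lapply(verts, function(v) which(edges[, 1] == v | edges[, 2] == v))
  names(adj) <- as.character(verts)
  loops <- list()
  for (e0 in seq_len(nrow(edges))) {
    if (used[e0]) next
    start <- edges[e0, 1]
    cur <- edges[e0, 2]
    used[e0] <- TRUE
    loop <- c(start, cur)
    repeat {
      nxt_edges <- adj[[as.character(cur)]]
      nxt_edges <- nxt_edges[!used[nxt_edges]]
      if (length(nxt_edges) == 0L) break
      e <- nxt_edges[1L]
      used[e] <- TRUE
      cur <- if (edges[e, 1] == cur) edges[e, 2] else edges[e, 1]
      if (cur == start) {
        loops[[length(loops) + 1L]] <- loop
        break
      }
      loop <- c(loop, cur)
    }
  }
  loops
}

#' Smallest enclosing circle of 2D points
#'
#' Welzl's move-to-front recursion; exact for the scales used here (tens of
#' KMT hit points per cross-section).
#'
#' @param xy n x 2 matrix.
#' @return list with `center` (length-2) and `radius`.
#' @export
min_enclosing_circle <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 1)
  circ2 <- function(p, q) list(center = (p + q) / 2, radius = dist_pp(p, q) / 2)
  circ3 <- function(p, q, r) {
    ax <- p[1]; ay <- p[2]; bx <- q[1]; by <- q[2]; cx <- r[1]; cy <- r[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) {
      # collinear: take the widest two-point circle
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      return(cands[[which.max(vapply(cands, `[[`, 0, "radius"))]])
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    list(center = c(ux, uy), radius = dist_pp(c(ux, uy), p))
  }
  inside <- function(c, p) dist_pp(c$center, p) <= c$radius + 1e-9
  trivial <- function(R) {
    if (length(R) == 0L) return(list(center = c(0, 0), radius = 0))
    if (length(R) == 1L) return(list(center = R[[1]], radius = 0))
    if (length(R) == 2L) return(circ2(R[[1]], R[[2]]))
    circ3(R[[1]], R[[2]], R[[3]])
  }
  welzl <- function(P, R) {
    if (length(P) == 0L || length(R) == 3L) return(trivial(R))
    p <- P[[1]]
    d <- welzl(P[-1L], R)
    if (inside(d, p)) return(d)
    welzl(P[-1L], c(R, list(p)))
  }
  pts <- lapply(seq_len(nrow(xy)), function(i) xy[i, ])
  welzl(pts, list())
}

#' Direct least-squares ellipse fit
#'
#' Numerically stable Halir-Flusser variant of the Fitzgibbon direct conic
#' fit constrained to ellipses.
#'
#' @param xy n x 2 matrix (n >= 5, not collinear).
#' @return list with `center` (x, y), `a`, `b` (semi-axes, `a >= b`),
#'   `angle` (radians, major-axis orientation) and `conic` (A B C D E F).
#' @export
fit_ellipse_direct <- function(xy) {
  xy <- as.matrix(xy)
  stopifnot(nrow(xy) >= 5)
  x <- xy[, 1] - mean(xy[, 1])
  y <- xy[, 2] - mean(xy[, 2])
  sc <- max(stats::sd(x), stats::sd(y))
  if (!is.finite(sc) || sc < 1e-12) stop("degenerate point configuration for ellipse fit")
  x <- x / sc; y <- y / sc
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate point configuration for ellipse fit"))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (length(k) == 0L) stop("no elliptical solution (collinear or hyperbolic data)")
  a1 <- Re(ev$vectors[, k[1]])
  coef <- c(a1, Tm %*% a1) # conic (A B C D E F) in the centred/scaled frame
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  x0 <- (2 * C * D - B * E) / den
  y0 <- (2 * A * E - B * D) / den
  common <- 2 * (A * E^2 + C * D^2 - B * D * E + den * Fc)
  root <- sqrt((A - C)^2 + B^2)
  a_ax <- -sqrt(common * (A + C + root)) / den
  b_ax <- -sqrt(common * (A + C - root)) / den
  ang <- atan2(-B, C - A) / 2
  if (b_ax > a_ax) { tmp <- a_ax; a_ax <- b_ax; b_ax <- tmp; ang <- ang + pi / 2 }
  list(center = c(x0 * sc + mean(xy[, 1]), y0 * sc + mean(xy[, 2])),
       a = a_ax * sc, b = b_ax * sc,
       angle = ang, conic = coef)
}
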