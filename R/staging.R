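# KMT classification, k-fiber assembly and metaphase staging metrics.

#' Classify tracks into KMTs and non-KMTs
#'
#' KMTs are microtubules whose putative plus end makes end-on contact with a
#' kinetochore. When the input already carries labels
#' (`markers = NULL`) the classification is the identity. Otherwise each
#' track whose plus end lies within `attach_radius` of a kinetochore marker
#' is labelled KMT and assigned to the fiber of the nearest marker; all other
#' tracks become non-KMTs.
#'
#' For unclassified tracks without an end annotation the putative plus end
#' is taken as the endpoint *farther* from the nearest mother centriole
#' (the minus end of any spindle MT points poleward).
#'
#' @param spindle a [spindle].
#' @param markers optional k x 3 matrix of kinetochore marker positions
#'   (micrometres), one row per kinetochore.
#' @param attach_radius maximum plus-end-to-marker distance for attachment
#'   (micrometres). Default 0.1.
#' @return the [spindle] with `mt_class`/`fiber_id` set on every track and
#'   `kinetochores` rebuilt from the marker assignment (marker i becomes
#'   kinetochore `"K<i>"`) when markers are given.
#' @export
classify_kmts <- function(spindle, markers = NULL, attach_radius = 0.1) {
  cls <- vapply(spindle$tracks, `[[`, "", "mt_class")
  if (is.null(markers)) {
    if (any(cls == "unclassified"))
      stop("no kinetochore markers given and tracks are not pre-labelled")
    return(spindle)
  }
  markers <- as.matrix(markers)
  stopifnot(ncol(markers) == 3L)
  if (!is.null(spindle$poles)) {
    mothers <- rbind(spindle$poles[[1]]$mother_centriole,
                     spindle$poles[[2]]$mother_centriole)
  } else mothers <- NULL
  assign <- character(length(spindle$tracks))
  for (i in seq_along(spindle$tracks)) {
    t <- spindle$tracks[[i]]
    ends <- rbind(t$points[1L, ], t$points[nrow(t$points), ])
    if (t$mt_class == "unclassified" && !is.null(mothers)) {
      dpole <- apply(ends, 1, function(e) min(sqrt(rowSums((mothers - matrix(e, nrow(mothers), 3, byrow = TRUE))^2))))
      t$plus_end <- if (which.max(dpole) == 2L) "last" else "first"
    }
    pe <- if (t$plus_end == "last") ends[2L, ] else ends[1L, ]
    d <- sqrt(rowSums((markers - matrix(pe, nrow(markers), 3, byrow = TRUE))^2))
    j <- which.min(d)
    if (d[j] <= attach_radius) {
      t$mt_class <- "KMT"
      t$fiber_id <- sprintf("K%03d", j)
    } else {
      t$mt_class <- "non-KMT"
      t$fiber_id <- NA_character_
    }
    assign[i] <- t$fiber_id
    spindle$tracks[[i]] <- t
  }
  ids <- vapply(spindle$tracks, `[[`, "", "id")
  spindle$kinetochores <- lapply(seq_len(nrow(markers)), function(j) {
    kinetochore(sprintf("K%03d", j),
                kmt_ids = ids[!is.na(assign) & assign == sprintf("K%03d", j)])
  })
  spindle$kinetochores <- Filter(function(k) length(k$kmt_ids) > 0,
                                 spindle$kinetochores)
  spindle
}

#' Pole-to-pole distance
#'
#' 3D distance between the two mother-centriole centres; the staging
#' read-out for spindle size.
#'
#' @param spindle a [spindle] with both poles.
#' @return length in micrometres.
#' @export
pole_to_pole_distance <- function(spindle) {
  if (is.null(spindle$poles) || length(spindle$poles) != 2L)
    stop("both poles are required")
  dist_pp(spindle$poles[[1]]$mother_centriole,
          spindle$poles[[2]]$mother_centriole)
}

#' Pair sister kinetochores by mutual nearest neighbours
#'
#' Fills in missing `sister_id` fields. Kinetochore centres (median KMT
#' plus-end positions) are matched by mutual nearest neighbour; ties are
#' broken by smallest distance, then lowest id.
#'
#' @param spindle a [spindle] with assembled kinetochores.
#' @return the spindle with symmetric sister pairing.
#' @export
pair_sisters <- function(spindle) {
  kins <- spindle$kinetochores
  n <- length(kins)
  if (n < 2L) return(spindle)
  centers <- t(vapply(kins, function(k) {
    c0 <- kinetochore_center(spindle, k)
    if (is.null(c0)) rep(NA_real_, 3) else c0
  }, numeric(3)))
  ids <- vapply(kins, `[[`, "", "id")
  # sisters face opposite poles, so they sit on opposite sides of the plate:
  # restrict candidates to the other side of the spindle-axis median
  if (!is.null(spindle$poles)) {
    ax <- spindle$poles[[2]]$mother_centriole -
      spindle$poles[[1]]$mother_centriole
  } else {
    ax <- stats::prcomp(centers[stats::complete.cases(centers), , drop = FALSE])$rotation[, 1]
  }
  proj <- as.numeric(centers %*% ax)
  side <- proj > stats::median(proj)
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  D[outer(side, side, "==")] <- Inf
  nn <- apply(D, 1, which.min)
  for (i in seq_len(n)) {
    if (!is.na(kins[[i]]$sister_id)) next
    j <- nn[i]
    if (!is.finite(D[i, j])) next
    if (nn[j] == i && is.na(kins[[j]]$sister_id)) {
      kins[[i]]$sister_id <- ids[j]
      kins[[j]]$sister_id <- ids[i]
    }
  }
  spindle$kinetochores <- kins
  spindle
}

#' Inter-kinetochore distances
#'
#' For each sister pair, the 3D distance between the two kinetochore centres
#' (component-wise median KMT plus-end positions). Unpaired kinetochores are
#' skipped with a warning.
#'
#' @param spindle a [spindle] with sister pairing set (see [pair_sisters]).
#' @return data frame with columns `kin_a`, `kin_b`, `distance` (one row per
#'   unordered pair).
#' @export
interkinetochore_distances <- function(spindle) {
  kins <- spindle$kinetochores
  ids <- vapply(kins, `[[`, "", "id")
  sis <- vapply(kins, `[[`, "", "sister_id")
  unpaired <- is.na(sis) | !(sis %in% ids)
  if (any(unpaired))
    warning(sum(unpaired), " unpaired kinetochore(s) skipped")
  seen <- character()
  out <- list()
  for (i in seq_along(kins)) {
    if (unpaired[i]) next
    a <- ids[i]; b <- sis[i]
    key <- paste(sort(c(a, b)), collapse = "|")
    if (key %in% seen) next
    seen <- c(seen, key)
    ca <- kinetochore_center(spindle, a)
    cb <- kinetochore_center(spindle, b)
    if (is.null(ca) || is.null(cb)) next
    out[[length(out) + 1L]] <- data.frame(kin_a = a, kin_b = b,
                                          distance = dist_pp(ca, cb))
  }
  if (length(out) == 0L)
    return(data.frame(kin_a = character(), kin_b = character(),
                      distance = double()))
  do.call(rbind, out)
}

#' KMTs per kinetochore
#'
#' @param spindle a [spindle] with assembled kinetochores.
#' @return list with `counts` (named integer vector per kinetochore),
#'   `mean`, `sd` and `histogram` (a `table` of counts).
#' @export
kmts_per_kinetochore <- function(spindle) {
  counts <- vapply(spindle$kinetochores, function(k) length(k$kmt_ids), 0L)
  names(counts) <- vapply(spindle$kinetochores, `[[`, "", "id")
  list(counts = counts,
       mean = if (length(counts)) mean(counts) else NA_real_,
       sd = if (length(counts) > 1L) stats::sd(counts) else NA_real_,
       histogram = table(counts))
}

#' Staging report for one spindle
#'
#' Mirrors the per-spindle staging columns: pole-to-pole distance,
#' inter-kinetochore distances (mean +- SD), class counts and KMT fraction.
#'
#' @param spindle a classified, sister-paired [spindle].
#' @return object of class `staging_report` (a list).
#' @export
staging_report <- function(spindle) {
  cc <- track_counts(spindle)
  ik <- suppressWarnings(interkinetochore_distances(spindle))
  rep <- list(
    pole_to_pole_distance = if (!is.null(spindle$poles))
      pole_to_pole_distance(spindle) else NA_real_,
    interkinetochore = ik,
    interkinetochore_mean = if (nrow(ik)) mean(ik$distance) else NA_real_,
    interkinetochore_sd = if (nrow(ik) > 1L) stats::sd(ik$distance) else NA_real_,
    n_kinetochores = length(spindle$kinetochores),
    n_kfibers = sum(vapply(spindle$kinetochores,
                           function(k) length(k$kmt_ids) > 0, NA)),
    n_KMT = unname(cc["KMT"]),
    n_nonKMT = unname(cc["non-KMT"]),
    kmt_fraction = unname(cc["KMT"] / (cc["KMT"] + cc["non-KMT"])))
  class(rep) <- "staging_report"
  rep
}

#' @export
print.staging_report <- function(x, ...) {
  cat(sprintf(
    "<staging: pole-pole %.2f um, %d kinetochores, %d KMT / %d non-KMT (%.1f%%), interkin %.2f +- %.2f um>\n",
    x$pole_to_pole_distance, x$n_kinetochores, x$n_KMT, x$n_nonKMT,
    100 * x$kmt_fraction, x$interkinetochore_mean, x$interkinetochore_sd))
  invisible(x)
}
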