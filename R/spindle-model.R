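# Core data model: microtubule tracks, poles, kinetochores and the Spindle
# container. All coordinates are micrometres in a right-handed frame; the
# spindle (pole-to-pole) axis of generated data runs along y.

#' Construct a microtubule track
#'
#' A track is an ordered 3D polyline with a designated plus end at one of the
#' two terminal vertices. The other terminal vertex is the minus end.
#'
#' @param id track identifier (coerced to character).
#' @param points n x 3 numeric matrix (n >= 2) of ordered polyline vertices
#'   in micrometres; consecutive vertices must be distinct.
#' @param plus_end `"first"` or `"last"`: which terminal vertex is the plus
#'   end. KMT plus ends sit at the kinetochore; for non-KMTs the minus end is
#'   the end nearest the mother centriole.
#' @param mt_class one of `"KMT"`, `"non-KMT"`, `"unclassified"`.
#' @param fiber_id kinetochore/fiber identifier for KMTs, `NA` otherwise.
#' @return an object of class `mt_track`.
#' @export
mt_track <- function(id, points, plus_end = c("last", "first"),
                     mt_class = c("unclassified", "KMT", "non-KMT"),
                     fiber_id = NA_character_) {
  plus_end <- match.arg(plus_end)
  mt_class <- match.arg(mt_class)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (ncol(points) != 3L) stop("track points must be an n x 3 matrix")
  if (nrow(points) < 2L) stop("a track needs at least 2 points")
  if (!all(is.finite(points))) stop("track coordinates must be finite")
  seg <- rowSums((points[-1L, , drop = FALSE] -
                  points[-nrow(points), , drop = FALSE])^2)
  if (any(seg == 0)) stop("consecutive track points must be distinct")
  structure(
    list(id = as.character(id), points = points, plus_end = plus_end,
         mt_class = mt_class, fiber_id = as.character(fiber_id)),
    class = "mt_track")
}

#' @export
print.mt_track <- function(x, ...) {
  cat(sprintf("<mt_track %s: %d pts, %.3f um, %s%s>\n", x$id, nrow(x$points),
              spline_length(x), x$mt_class,
              if (!is.na(x$fiber_id)) paste0(", fiber ", x$fiber_id) else ""))
  invisible(x)
}

#' Plus- and minus-end coordinates of a track
#' @param track an [mt_track].
#' @return length-3 numeric vector (micrometres).
#' @export
plus_end_point <- function(track) {
  if (track$plus_end == "last") track$points[nrow(track$points), ] else track$points[1L, ]
}

#' @rdname plus_end_point
#' @export
minus_end_point <- function(track) {
  if (track$plus_end == "last") track$points[1L, ] else track$points[nrow(track$points), ]
}

#' Construct a spindle pole
#'
#' @param mother_centriole length-3 numeric; the reference point for all
#'   pole-distance measurements.
#' @param daughter_centriole optional length-3 numeric.
#' @param label `"P1"` or `"P2"`.
#' @return object of class `pole`.
#' @export
pole <- function(mother_centriole, daughter_centriole = NULL,
                 label = c("P1", "P2")) {
  label <- match.arg(label)
  stopifnot(length(mother_centriole) == 3L, all(is.finite(mother_centriole)))
  structure(list(mother_centriole = as.numeric(mother_centriole),
                 daughter_centriole = if (is.null(daughter_centriole)) NULL
                                      else as.numeric(daughter_centriole),
                 label = label),
            class = "pole")
}

#' Construct a kinetochore record
#'
#' The kinetochore centre is not stored: it is always recomputed as the
#' component-wise median of the plus-end positions of the attached KMTs,
#' which keeps it deterministic under track edits.
#'
#' @param id kinetochore identifier.
#' @param kmt_ids character vector of attached KMT track ids.
#' @param sister_id id of the paired sister kinetochore (or `NA`).
#' @return object of class `kinetochore`.
#' @export
kinetochore <- function(id, kmt_ids = character(), sister_id = NA_character_) {
  structure(list(id = as.character(id), kmt_ids = as.character(kmt_ids),
                 sister_id = as.character(sister_id)),
            class = "kinetochore")
}

#' Assemble a spindle
#'
#' @param tracks list of [mt_track] objects (unique ids).
#' @param poles list of two [pole] objects labelled P1 and P2 (or `NULL` for
#'   pole-free fixtures).
#' @param kinetochores list of [kinetochore] objects.
#' @param bounding_box 2 x 3 matrix (rows: min, max) or `NULL` to use the
#'   axis-aligned extent of all track points.
#' @param z_factor Z-expansion factor already applied to the coordinates
#'   (1 means unexpanded).
#' @param provenance free-text origin note.
#' @return object of class `spindle`.
#' @export
spindle <- function(tracks, poles = NULL, kinetochores = list(),
                    bounding_box = NULL, z_factor = 1, provenance = "") {
  stopifnot(is.list(tracks))
  ids <- vapply(tracks, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("track ids must be unique")
  if (!is.null(poles)) {
    stopifnot(length(poles) == 2L)
    if (isTRUE(all.equal(poles[[1]]$mother_centriole,
                         poles[[2]]$mother_centriole)))
      stop("the two poles must have distinct mother-centriole positions")
  }
  if (is.null(bounding_box)) bounding_box <- tracks_bbox(tracks)
  s <- structure(
    list(tracks = tracks, poles = poles, kinetochores = kinetochores,
         bounding_box = bounding_box, z_factor = as.numeric(z_factor),
         provenance = provenance),
    class = "spindle")
  validate_spindle(s)
  s
}

tracks_bbox <- function(tracks) {
  if (length(tracks) == 0L) return(matrix(0, 2, 3, dimnames = list(c("min", "max"), c("x", "y", "z"))))
  pts <- do.call(rbind, lapply(tracks, `[[`, "points"))
  bb <- rbind(apply(pts, 2, min), apply(pts, 2, max))
  dimnames(bb) <- list(c("min", "max"), c("x", "y", "z"))
  bb
}

validate_spindle <- function(s) {
  cls <- vapply(s$tracks, `[[`, "", "mt_class")
  fib <- vapply(s$tracks, `[[`, "", "fiber_id")
  kin_ids <- vapply(s$kinetochores, `[[`, "", "id")
  bad <- cls == "KMT" & !is.na(fib) & !(fib %in% kin_ids) & length(kin_ids) > 0
  if (any(bad))
    stop("KMT fiber_id refers to an unknown kinetochore: ",
         paste(unique(fib[bad]), collapse = ", "))
  stopifnot(sum(cls == "KMT") + sum(cls == "non-KMT") +
            sum(cls == "unclassified") == length(s$tracks))
  invisible(s)
}

#' @export
print.spindle <- function(x, ...) {
  cls <- vapply(x$tracks, `[[`, "", "mt_class")
  cat(sprintf(
    "<spindle: %d tracks (%d KMT, %d non-KMT, %d unclassified), %d kinetochores, z-factor %.2f>\n",
    length(x$tracks), sum(cls == "KMT"), sum(cls == "non-KMT"),
    sum(cls == "unclassified"), length(x$kinetochores), x$z_factor))
  invisible(x)
}

#' Per-class track counts
#' @param spindle a [spindle].
#' @return named integer vector (KMT, non-KMT, unclassified, total).
#' @export
track_counts <- function(spindle) {
  cls <- vapply(spindle$tracks, `[[`, "", "mt_class")
  c(KMT = sum(cls == "KMT"), `non-KMT` = sum(cls == "non-KMT"),
    unclassified = sum(cls == "unclassified"), total = length(spindle$tracks))
}

#' Get tracks of one class
#' @param spindle a [spindle].
#' @param mt_class class label to select.
#' @return list of [mt_track].
#' @export
tracks_of_class <- function(spindle, mt_class) {
  Filter(function(t) t$mt_class == mt_class, spindle$tracks)
}

#' Kinetochore centre
#'
#' Component-wise median of the plus-end positions of the attached KMTs.
#'
#' @param spindle a [spindle].
#' @param kin a [kinetochore] or kinetochore id.
#' @return length-3 numeric, or `NULL` when no KMTs are attached.
#' @export
kinetochore_center <- function(spindle, kin) {
  if (is.character(kin)) {
    kin <- Find(function(k) k$id == kin, spindle$kinetochores)
    if (is.null(kin)) stop("unknown kinetochore id")
  }
  if (length(kin$kmt_ids) == 0L) return(NULL)
  tr <- spindle$tracks[vapply(spindle$tracks, `[[`, "", "id") %in% kin$kmt_ids]
  ends <- do.call(rbind, lapply(tr, plus_end_point))
  apply(ends, 2, stats::median)
}

#' Spline length of a track
#'
#' Sum of consecutive point-to-point Euclidean distances along the polyline.
#'
#' @param track an [mt_track] or an n x 3 matrix.
#' @return length in micrometres.
#' @export
#' @examples
#' spline_length(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))) # 2
spline_length <- function(track) {
  pts <- if (inherits(track, "mt_track")) track$points else as.matrix(track)
  if (nrow(pts) < 2L) stop("spline_length needs at least 2 points")
  s <- cum_arclength(pts)
  s[length(s)]
}

#' Expand a spindle in Z
#'
#' Plastic sections collapse in the electron beam; the stack is corrected by
#' multiplying every z coordinate by a Z-factor about z = 0 of the stack
#' frame. x and y are unchanged. The factor is the nominal stack thickness
#' (microtome setting x number of sections) divided by the measured
#' thickness, e.g. 1.3 to 1.42 for HeLa metaphase stacks.
#'
#' @param spindle a [spindle].
#' @param z_factor multiplicative factor, must be >= 1.
#' @return the expanded [spindle]; `z_factor` records the cumulative factor.
#' @export
apply_z_expansion <- function(spindle, z_factor) {
  if (!is.numeric(z_factor) || length(z_factor) != 1L || z_factor <= 0)
    stop("z_factor must be a positive scalar")
  if (z_factor < 1) stop("z_factor must be >= 1 (sections only collapse)")
  spindle$tracks <- lapply(spindle$tracks, function(t) {
    t$points[, 3] <- t$points[, 3] * z_factor
    t
  })
  scale_z <- function(p) { p[3] <- p[3] * z_factor; p }
  if (!is.null(spindle$poles)) {
    spindle$poles <- lapply(spindle$poles, function(p) {
      p$mother_centriole <- scale_z(p$mother_centriole)
      if (!is.null(p$daughter_centriole))
        p$daughter_centriole <- scale_z(p$daughter_centriole)
      p
    })
  }
  spindle$bounding_box[, 3] <- spindle$bounding_box[, 3] * z_factor
  spindle$z_factor <- spindle$z_factor * z_factor
  spindle
}

#' Compute a Z-factor from the microtome setting
#'
#' @param section_thickness_nm nominal microtome feed per section (nm),
#'   typically 300.
#' @param n_sections number of serial sections in the stack.
#' @param measured_thickness_um measured total stack thickness (micrometres).
#' @return nominal/measured thickness ratio.
#' @export
#' @examples
#' z_factor_from_thickness(300, 22, 6.6 / 1.3) # 1.3
z_factor_from_thickness <- function(section_thickness_nm, n_sections,
                                    measured_thickness_um) {
  stopifnot(section_thickness_nm > 0, n_sections > 0,
            measured_thickness_um > 0)
  (section_thickness_nm / 1000 * n_sections) / measured_thickness_um
}

#' Discard tracks ending at the tomogram border
#'
#' Tracks with at least one endpoint within `margin` of any bounding-box face
#' most likely leave the reconstructed volume and are removed before
#' analysis.
#'
#' @param spindle a [spindle] with a bounding box.
#' @param margin distance to a face below which an endpoint counts as
#'   "at the border" (micrometres); default 0.1 (100 nm).
#' @return list with `spindle` (filtered) and `report` (data frame of
#'   removed ids plus the removed fraction as attribute `fraction`).
#' @export
filter_border_tracks <- function(spindle, margin = 0.1) {
  bb <- spindle$bounding_box
  if (is.null(bb)) stop("bounding_box must be set")
  if (length(spindle$tracks) == 0L) {
    warning("empty spindle: nothing to filter")
    rep <- data.frame(track_id = character())
    attr(rep, "fraction") <- 0
    return(list(spindle = spindle, report = rep))
  }
  near_border <- function(p) {
    any(p - bb[1, ] < margin) || any(bb[2, ] - p < margin)
  }
  drop <- vapply(spindle$tracks, function(t) {
    near_border(t$points[1L, ]) || near_border(t$points[nrow(t$points), ])
  }, NA)
  removed <- vapply(spindle$tracks[drop], `[[`, "", "id")
  spindle$tracks <- spindle$tracks[!drop]
  kept_ids <- vapply(spindle$tracks, `[[`, "", "id")
  spindle$kinetochores <- lapply(spindle$kinetochores, function(k) {
    k$kmt_ids <- intersect(k$kmt_ids, kept_ids)
    k
  })
  rep <- data.frame(track_id = removed, stringsAsFactors = FALSE)
  attr(rep, "fraction") <- length(removed) / length(drop)
  list(spindle = spindle, report = rep)
}
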