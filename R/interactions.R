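# Distance-thresholded MT-MT association detection: minus ends vs lattices,
# lattice-lattice segment pairing with contact lengths, local-density
# normalisation and axis mapping.
#
# Distances are exact point-to-polyline minima (not point-to-resampled-point):
# at a 25-nm threshold the sub-step accuracy matters. A per-track bounding-box
# prefilter (expanded by the threshold) prunes the all-pairs scan; results are
# identical to the brute-force scan by construction and by oracle test.

INTERACTION_THRESHOLDS_NM <- c(25, 30, 35, 45, 50, 75, 100)

check_threshold <- function(threshold_nm) {
  if (!threshold_nm %in% INTERACTION_THRESHOLDS_NM)
    stop("threshold must be one of ",
         paste(INTERACTION_THRESHOLDS_NM, collapse = ", "), " nm")
  threshold_nm / 1000
}

track_bbox <- function(t) {
  rbind(apply(t$points, 2, min), apply(t$points, 2, max))
}

bbox_overlap <- function(b1, b2, pad) {
  all(b1[1, ] - pad <= b2[2, ]) && all(b2[1, ] - pad <= b1[2, ])
}

point_in_bbox <- function(p, b, pad) {
  all(p >= b[1, ] - pad) && all(p <= b[2, ] + pad)
}

#' Local MT density around a point
#'
#' Number of distinct tracks whose polyline intersects the cubic voxel of
#' `voxel_volume` centred at `point`, divided by the voxel volume. The
#' default 0.001 um^3 voxel has a 0.1 um side.
#'
#' @param spindle a [spindle].
#' @param point length-3 numeric (um).
#' @param voxel_volume voxel volume in um^3, default 0.001.
#' @return list (`density_voxel`): `center`, `volume`, `side`, `mt_count`,
#'   `density` (um^-3).
#' @export
local_density <- function(spindle, point, voxel_volume = 0.001) {
  side <- voxel_volume^(1 / 3)
  lo <- point - side / 2
  hi <- point + side / 2
  count <- 0L
  for (t in spindle$tracks) {
    bb <- track_bbox(t)
    if (!bbox_overlap(bb, rbind(lo, hi), 0)) next
    pts <- t$points
    n <- nrow(pts)
    hit <- FALSE
    for (i in seq_len(n - 1L)) {
      if (segment_intersects_box(pts[i, ], pts[i + 1L, ], lo, hi)) {
        hit <- TRUE; break
      }
    }
    if (hit) count <- count + 1L
  }
  structure(list(center = point, volume = voxel_volume, side = side,
                 mt_count = count, density = count / voxel_volume),
            class = "density_voxel")
}

#' Minus-end-to-lattice associations
#'
#' For every minus end of `end_class`, all tracks of `lattice_class` (other
#' than the end's own track) whose polyline passes within the threshold of
#' the end. Each record carries the local MT density in the 0.001-um^3
#' voxel around the end and the end's relative axis position.
#'
#' @param spindle a classified [spindle].
#' @param end_class class of the tracks whose minus ends are tested
#'   (`"KMT"` or `"non-KMT"`).
#' @param lattice_class class of candidate partner lattices (`"KMT"`,
#'   `"non-KMT"` or `"any"`).
#' @param threshold_nm association distance in nm; one of 25, 30, 35, 45,
#'   50, 75, 100.
#' @param exclude_same_fiber also exclude lattices of the end's own fiber.
#' @param with_density compute the local-density voxel per qualifying end
#'   (TRUE by default; disable for speed in oracle tests).
#' @return data frame of `interaction_record`s: `source_id`, `target_id`,
#'   `mode`, `threshold_nm`, `distance`, `axis_position`, `local_density`.
#' @export
end_lattice_associations <- function(spindle, end_class = "KMT",
                                     lattice_class = "any",
                                     threshold_nm = 35,
                                     exclude_same_fiber = FALSE,
                                     with_density = TRUE) {
  thr <- check_threshold(threshold_nm)
  ends_tracks <- tracks_of_class(spindle, end_class)
  lat_tracks <- if (lattice_class == "any") spindle$tracks
                else tracks_of_class(spindle, lattice_class)
  lat_bb <- lapply(lat_tracks, track_bbox)
  rows <- list()
  for (t in ends_tracks) {
    e <- minus_end_point(t)
    dens <- NA_real_
    axis_pos <- if (!is.null(spindle$poles))
      tryCatch(relative_axis_position(spindle, t, point = e),
               error = function(er) NA_real_) else NA_real_
    for (j in seq_along(lat_tracks)) {
      lt <- lat_tracks[[j]]
      if (lt$id == t$id) next
      if (exclude_same_fiber && !is.na(t$fiber_id) && !is.na(lt$fiber_id) &&
          lt$fiber_id == t$fiber_id) next
      if (!point_in_bbox(e, lat_bb[[j]], thr)) next
      d <- dists_points_polyline(matrix(e, 1L), lt$points)
      if (d <= thr) {
        if (is.na(dens) && with_density)
          dens <- local_density(spindle, e)$density
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = t$id, target_id = lt$id, mode = "end_to_lattice",
          threshold_nm = threshold_nm, distance = d,
          axis_position = axis_pos, local_density = dens)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(source_id = character(), target_id = character(),
                      mode = character(), threshold_nm = double(),
                      distance = double(), axis_position = double(),
                      local_density = double()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lattice-lattice pairing with contact lengths
#'
#' Every track is resampled at `step` (20 nm) arc intervals; at each step
#' point the distance to each candidate partner polyline is taken. Maximal
#' runs of consecutive in-contact steps per (source, partner) become one
#' record with `contact_length = step * (run size - 1)`; runs below the
#' 20-nm minimum length (a single step point) are discarded. A step can
#' contribute to runs with several partners simultaneously.
#'
#' @param spindle a [spindle].
#' @param threshold_nm association distance in nm (25, 30, 35, 45, 50, 75
#'   or 100).
#' @param step resampling step (um), default 0.02.
#' @param source_class restrict source tracks to one class (`"any"` default).
#' @return data frame: `source_id`, `target_id`, `mode`, `threshold_nm`,
#'   `contact_length`, `n_steps`, `arc_start`, `axis_position` (relative
#'   pole-to-pole position of the run midpoint; NA without poles).
#' @export
lattice_pairing <- function(spindle, threshold_nm = 35, step = 0.02,
                            source_class = "any") {
  thr <- check_threshold(threshold_nm)
  tracks <- spindle$tracks
  src <- if (source_class == "any") tracks else tracks_of_class(spindle, source_class)
  bb <- lapply(tracks, track_bbox)
  names(bb) <- vapply(tracks, `[[`, "", "id")
  resampled <- lapply(src, function(t) polyline_resample(t$points, step, keep_end = FALSE))
  axis <- NULL
  if (!is.null(spindle$poles)) {
    p1 <- spindle$poles[[1]]$mother_centriole
    p2 <- spindle$poles[[2]]$mother_centriole
    axis <- list(origin = p1, dir = p2 - p1, L2 = sum((p2 - p1)^2))
  }
  rows <- list()
  for (i in seq_along(src)) {
    A <- src[[i]]
    P <- resampled[[i]]
    abox <- rbind(apply(P, 2, min), apply(P, 2, max))
    for (j in seq_along(tracks)) {
      B <- tracks[[j]]
      if (B$id == A$id) next
      if (!bbox_overlap(abox, bb[[j]], thr)) next
      d <- dists_points_polyline(P, B$points)
      contact <- d <= thr
      if (!any(contact)) next
      r <- rle(contact)
      ends_idx <- cumsum(r$lengths)
      starts_idx <- ends_idx - r$lengths + 1L
      for (k in which(r$values & r$lengths >= 2L)) {
        i0 <- starts_idx[k]; i1 <- ends_idx[k]
        midpt <- P[floor((i0 + i1) / 2), ]
        ap <- if (is.null(axis)) NA_real_
              else sum((midpt - axis$origin) * axis$dir) / axis$L2
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = A$id, target_id = B$id, mode = "lattice_to_lattice",
          threshold_nm = threshold_nm,
          contact_length = step * (i1 - i0),
          n_steps = i1 - i0 + 1L,
          arc_start = step * (i0 - 1L),
          axis_position = ap)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(source_id = character(), target_id = character(),
                      mode = character(), threshold_nm = double(),
                      contact_length = double(), n_steps = integer(),
                      arc_start = double(), axis_position = double()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Axis-binned, density-normalised interaction profiles
#'
#' Records are binned by relative axis position (bin width 0.05, the
#' moving-average period used for presentation). End-mode counts are
#' normalised by each record's local MT density; lattice-mode counts are
#' divided by the number of distinct tracks present in the bin. The
#' fraction of records falling inside the MT-centrosome interaction band
#' is reported.
#'
#' @param records a record data frame from [end_lattice_associations] or
#'   [lattice_pairing].
#' @param spindle the [spindle] the records came from (needed for
#'   lattice-mode track presence).
#' @param bin axis bin width, default 0.05.
#' @param area_band relative-axis band counted as "at the pole", default
#'   `c(-0.2, 0.2)`.
#' @param step resampling step used for lattice-mode presence counting.
#' @return list: `profile` (data frame bin_mid, count, normalized),
#'   `pole_fraction` (share of records inside `area_band`), `n_records`.
#' @export
interaction_profiles <- function(records, spindle, bin = 0.05,
                                 area_band = c(-0.2, 0.2), step = 0.02) {
  if (nrow(records) == 0L)
    return(list(profile = data.frame(bin_mid = double(), count = integer(),
                                     normalized = double()),
                pole_fraction = NA_real_, n_records = 0L))
  ap <- records$axis_position
  ok <- is.finite(ap)
  lo <- floor(min(ap[ok]) / bin) * bin
  hi <- ceiling(max(ap[ok]) / bin) * bin
  if (hi <= lo) hi <- lo + bin
  breaks <- seq(lo, hi, by = bin)
  idx <- findInterval(ap[ok], breaks, rightmost.closed = TRUE)
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  count <- tabulate(idx, nbins = length(mids))
  if (all(records$mode == "end_to_lattice") && "local_density" %in% names(records)) {
    w <- ifelse(is.finite(records$local_density[ok]) & records$local_density[ok] > 0,
                1 / records$local_density[ok], 0)
    normalized <- vapply(seq_along(mids), function(b) sum(w[idx == b]), 0)
  } else {
    # lattice mode: divide by number of distinct tracks present in the bin
    presence <- integer(length(mids))
    if (!is.null(spindle$poles)) {
      p1 <- spindle$poles[[1]]$mother_centriole
      p2 <- spindle$poles[[2]]$mother_centriole
      dirv <- p2 - p1
      L2 <- sum(dirv^2)
      for (t in spindle$tracks) {
        P <- polyline_resample(t$points, step, keep_end = TRUE)
        pos <- as.numeric((P - matrix(p1, nrow(P), 3, byrow = TRUE)) %*% dirv) / L2
        bidx <- unique(findInterval(pos, breaks, rightmost.closed = TRUE))
        bidx <- bidx[bidx >= 1L & bidx <= length(mids)]
        presence[bidx] <- presence[bidx] + 1L
      }
    }
    normalized <- ifelse(presence > 0, count / presence, NA_real_)
  }
  frac <- mean(ap[ok] >= area_band[1] & ap[ok] <= area_band[2])
  list(profile = data.frame(bin_mid = mids, count = count,
                            normalized = normalized),
       pole_fraction = frac, n_records = nrow(records))
}

#' Per-track interaction summary
#'
#' @param records output of [lattice_pairing] (possibly several thresholds
#'   row-bound together).
#' @return data frame: `source_id`, `threshold_nm`, `n_partners` (distinct
#'   partner tracks), `mean_contact_length`.
#' @export
per_mt_interaction_summary <- function(records) {
  if (nrow(records) == 0L)
    return(data.frame(source_id = character(), threshold_nm = double(),
                      n_partners = integer(), mean_contact_length = double()))
  sp <- split(records, list(records$source_id, records$threshold_nm), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(r) data.frame(
    source_id = r$source_id[1], threshold_nm = r$threshold_nm[1],
    n_partners = length(unique(r$target_id)),
    mean_contact_length = mean(r$contact_length))))
  rownames(out) <- NULL
  out[order(out$source_id, out$threshold_nm), ]
}
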