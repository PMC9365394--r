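# Orchestration and reporting: the full per-spindle analysis, pooled
# aggregation across spindles, endpoint-Z QC and report emission.

#' Published per-spindle summary tables
#'
#' Loads the bundled per-spindle summary values of the three HeLa metaphase
#' reconstructions (counts, staging distances, per-object means) used to
#' validate the pooled-aggregation conventions.
#'
#' @return data frame, one row per spindle.
#' @export
hela_spindle_tables <- function() {
  path <- system.file("extdata", "hela_metaphase_tables.csv",
                      package = "kfibergraph", mustWork = TRUE)
  utils::read.csv(path)
}

#' Weighted or unweighted pooled mean
#' @param x per-spindle values.
#' @param w optional weights (e.g. per-spindle object counts).
#' @return scalar.
#' @export
pooled_mean <- function(x, w = NULL) {
  if (is.null(w)) mean(x) else sum(x * w) / sum(w)
}

#' Pool per-spindle summary values
#'
#' Aggregation conventions: spindle-level quantities (MT counts, pole
#' distance, pole-association percentages, curved-KMT percentage) pool as
#' unweighted means across spindles; per-object quantities (KMT length,
#' KMTs per kinetochore, spacing, tortuosity, inter-kinetochore distance)
#' pool as n-weighted means using the per-spindle object counts. The KMT
#' fraction pools as total KMTs over total MTs.
#'
#' @param tab data frame in the layout of [hela_spindle_tables] (any number
#'   of spindles).
#' @return named list of pooled statistics.
#' @export
pooled_spindle_stats <- function(tab) {
  list(
    mean_mt_count = pooled_mean(tab$n_mts),
    mean_pole_distance = pooled_mean(tab$pole_distance_um),
    mean_kmt_count = pooled_mean(tab$n_kmts),
    kmt_fraction = sum(tab$n_kmts) / sum(tab$n_mts),
    kmts_per_kinetochore = pooled_mean(tab$kmts_per_kinetochore,
                                       tab$n_kinetochores),
    mean_kmt_length = pooled_mean(tab$kmt_length_um, tab$n_kmts),
    pct_pole_association = pooled_mean(tab$pct_kmts_pole_assoc),
    mean_tortuosity = pooled_mean(tab$global_tortuosity, tab$n_kmts),
    kmt_spacing_nm = pooled_mean(tab$kmt_spacing_nm, tab$n_kinetochores),
    pct_curved = pooled_mean(tab$pct_curved_kmts),
    interkinetochore = pooled_mean(tab$interkin_mean_um, tab$interkin_n))
}

#' Run the full single-spindle analysis
#'
#' Stages: optional Z-expansion, border filtering, classification (identity
#' when labels are present), sister pairing, staging metrics, pole model
#' (fitted from the non-KMT minus ends, or fixed), pole-association and
#' length statistics, per-KMT global tortuosity, per-fiber kinetochore
#' cross-section (polygon area and nearest-neighbour spacing) and plate
#' zoning. Interaction detection is not part of the default run (it scales
#' with the square of the track count); call [end_lattice_associations] /
#' [lattice_pairing] explicitly.
#'
#' @param spindle a [spindle] (labelled, or supply `markers`).
#' @param z_factor optional Z-expansion to apply first.
#' @param border_margin tomogram border margin for [filter_border_tracks]
#'   (um); `NULL` skips filtering.
#' @param markers optional kinetochore markers for [classify_kmts].
#' @param attach_radius marker attachment radius (um).
#' @param fit_pole fit the pole model from non-KMT minus ends (default);
#'   otherwise use `cutoff`.
#' @param cutoff fixed interaction-area cutoff (um) when `fit_pole = FALSE`
#'   or fitting fails.
#' @param zones compute metaphase-plate zones (needs >= 5 kinetochores).
#' @param fiber_morphology compute per-fiber kinetochore-station spacing
#'   and polygon area.
#' @param out_dir optional directory; per-stage CSVs and a summary JSON are
#'   written there.
#' @return object of class `spindle_report`: all stage outputs plus a flat
#'   `summary` list.
#' @export
run_pipeline <- function(spindle, z_factor = NULL, border_margin = 0.1,
                         markers = NULL, attach_radius = 0.1,
                         fit_pole = TRUE, cutoff = 1.7, zones = TRUE,
                         fiber_morphology = TRUE, out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(z_factor) && z_factor != 1)
    spindle <- stage("z_expansion", apply_z_expansion(spindle, z_factor))
  border_report <- NULL
  if (!is.null(border_margin)) {
    fb <- stage("border_filter", filter_border_tracks(spindle, border_margin))
    spindle <- fb$spindle
    border_report <- fb$report
  }
  spindle <- stage("classification",
                   classify_kmts(spindle, markers = markers,
                                 attach_radius = attach_radius))
  spindle <- stage("sister_pairing", pair_sisters(spindle))
  staging <- stage("staging", staging_report(spindle))
  nonkmt_rec <- stage("pole_distances",
                      end_distances_to_pole(spindle, "nonKMT_minus"))
  pm <- NULL
  if (fit_pole && nrow(nonkmt_rec) >= 100L)
    pm <- tryCatch(fit_pole_model(nonkmt_rec$distance_to_pole),
                   error = function(e) NULL)
  if (is.null(pm)) pm <- pole_model_fixed(cutoff)
  assoc <- stage("pole_association", pole_association_stats(spindle, pm))
  lengths <- stage("length_classes", classify_kmt_lengths(spindle, pm))
  kmts <- tracks_of_class(spindle, "KMT")
  tort <- stage("tortuosity", vapply(kmts, global_tortuosity, 0))
  names(tort) <- vapply(kmts, `[[`, "", "id")
  zone_tab <- NULL
  if (zones && length(spindle$kinetochores) >= 5L)
    zone_tab <- stage("zones", assign_zones(spindle))
  fiber_tab <- NULL
  if (fiber_morphology && length(spindle$kinetochores) > 0L) {
    fiber_tab <- stage("fiber_morphology", {
      rows <- lapply(spindle$kinetochores, function(k) {
        if (length(k$kmt_ids) == 0L) return(NULL)
        area <- tryCatch(
          cross_section_polygon_area(spindle, k$id, 0)$polygon_area,
          error = function(e) NA_real_)
        spac <- tryCatch(kmt_neighbor_spacing(spindle, k$id, 0)$mean,
                         error = function(e) NA_real_)
        data.frame(fiber_id = k$id, n_kmts = length(k$kmt_ids),
                   kinetochore_area = area, kmt_spacing = spac)
      })
      do.call(rbind, rows)
    })
  }
  kpk <- kmts_per_kinetochore(spindle)
  summary <- list(
    n_tracks = length(spindle$tracks),
    n_KMT = staging$n_KMT, n_nonKMT = staging$n_nonKMT,
    kmt_fraction = staging$kmt_fraction,
    pole_to_pole_distance = staging$pole_to_pole_distance,
    interkinetochore_mean = staging$interkinetochore_mean,
    n_kinetochores = staging$n_kinetochores,
    kmts_per_kinetochore_mean = kpk$mean,
    kmts_per_kinetochore_sd = kpk$sd,
    mean_kmt_length = if (nrow(lengths)) mean(lengths$length) else NA_real_,
    pct_short_kmts = if (nrow(lengths)) 100 * mean(lengths$class == "short") else NA_real_,
    pct_long_kmts = if (nrow(lengths)) 100 * mean(lengths$class == "long") else NA_real_,
    pole_cutoff = pm$cutoff,
    kmt_pole_association = assoc$kmt_fraction,
    nonkmt_pole_association = assoc$nonkmt_fraction,
    mean_tortuosity = if (length(tort)) mean(tort) else NA_real_,
    pct_curved = if (length(tort)) 100 * mean(tort > 1.1) else NA_real_,
    mean_kinetochore_area = if (!is.null(fiber_tab))
      mean(fiber_tab$kinetochore_area, na.rm = TRUE) else NA_real_,
    mean_kmt_spacing = if (!is.null(fiber_tab))
      mean(fiber_tab$kmt_spacing, na.rm = TRUE) else NA_real_,
    border_removed_fraction = if (!is.null(border_report))
      attr(border_report, "fraction") else NA_real_)
  rep <- structure(
    list(spindle = spindle, staging = staging, pole_model = pm,
         association = assoc, lengths = lengths, tortuosity = tort,
         zones = zone_tab, fibers = fiber_tab, border = border_report,
         summary = summary),
    class = "spindle_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.spindle_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<spindle_report: %d MTs (%.1f%% KMT), pole-pole %.2f um,\n",
           "  %.1f KMTs/kinetochore, KMT length %.2f um, tortuosity %.3f,\n",
           "  pole association %.1f%% (cutoff %.2f um)>\n"),
    s$n_tracks, 100 * s$kmt_fraction, s$pole_to_pole_distance,
    s$kmts_per_kinetochore_mean, s$mean_kmt_length, s$mean_tortuosity,
    100 * s$kmt_pole_association, s$pole_cutoff))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s <- report$summary
  jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  utils::write.csv(report$lengths, file.path(out_dir, "kmt_lengths.csv"),
                   row.names = FALSE)
  utils::write.csv(
    data.frame(track_id = names(report$tortuosity),
               tortuosity = unname(report$tortuosity)),
    file.path(out_dir, "tortuosity.csv"), row.names = FALSE)
  if (!is.null(report$zones))
    utils::write.csv(report$zones, file.path(out_dir, "zones.csv"),
                     row.names = FALSE)
  if (!is.null(report$fibers))
    utils::write.csv(report$fibers, file.path(out_dir, "fibers.csv"),
                     row.names = FALSE)
  ik <- report$staging$interkinetochore
  utils::write.csv(ik, file.path(out_dir, "interkinetochore.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' Endpoint-density QC along Z
#'
#' Serial-section stitching artefacts show up as excess MT endpoints at
#' section boundaries. Endpoints are binned along z; bins containing a
#' declared section boundary are compared with the bulk mean, and the QC
#' flag is raised when any boundary bin exceeds `factor` times the bulk.
#'
#' @param spindle a [spindle].
#' @param section_boundaries z values of section interfaces (um).
#' @param bin z bin width (um), default 0.1.
#' @param factor flag threshold as a multiple of the bulk bin mean.
#' @return list: `profile` (data frame z_mid, count, is_boundary), `flag`,
#'   `bulk_mean`.
#' @export
endpoint_z_qc <- function(spindle, section_boundaries, bin = 0.1, factor = 2) {
  if (length(spindle$tracks) == 0L)
    return(list(profile = data.frame(z_mid = double(), count = integer(),
                                     is_boundary = logical()),
                flag = FALSE, bulk_mean = NA_real_))
  z <- unlist(lapply(spindle$tracks, function(t)
    c(t$points[1L, 3], t$points[nrow(t$points), 3])))
  lo <- floor(min(z, section_boundaries) / bin) * bin
  hi <- ceiling(max(z, section_boundaries) / bin) * bin
  breaks <- seq(lo, hi + bin, by = bin)
  idx <- findInterval(z, breaks, rightmost.closed = TRUE)
  mids <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  count <- tabulate(idx, nbins = length(mids))
  bidx <- findInterval(section_boundaries, breaks, rightmost.closed = TRUE)
  is_boundary <- seq_along(mids) %in% bidx
  bulk <- count[!is_boundary & count > 0]
  bulk_mean <- if (length(bulk)) mean(bulk) else 0
  flag <- bulk_mean > 0 && any(count[is_boundary] > factor * bulk_mean)
  list(profile = data.frame(z_mid = mids, count = count,
                            is_boundary = is_boundary),
       flag = flag, bulk_mean = bulk_mean)
}
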