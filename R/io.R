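# File I/O: neutral JSON + CSV interchange (schema version "1") and a reader
# for the Amira-style ASCII spatial-graph dialect that filament tracings are
# deposited in.
#
# Neutral interchange, schema "1":
#   <name>.json  - metadata: schema_version, unit, z_factor, provenance,
#                  poles, kinetochores, per-track table (id, mt_class,
#                  fiber_id, plus_end), bounding_box, points_file
#   <name>.csv   - per-point table: track_id, point_index, x, y, z
# Coordinates are stored in the declared unit and normalised to micrometres
# on read.

NEUTRAL_SCHEMA_VERSION <- "1"

unit_to_um <- function(unit) {
  switch(unit,
         um = 1, "µm" = 1, micron = 1, microns = 1,
         nm = 1e-3,
         stop("unsupported coordinate unit: ", unit))
}

#' Read a spindle spatial graph
#'
#' @param path file path. For the neutral dialect this is the JSON metadata
#'   file (the per-point CSV is located via its `points_file` field,
#'   relative to the JSON). For the Amira dialect it is the ASCII
#'   spatial-graph file.
#' @param dialect `"neutral_json"` or `"amira_ascii"`.
#' @param unit coordinate unit override (`"um"` or `"nm"`). For the neutral
#'   dialect the file header declares the unit and the override is ignored;
#'   the Amira dialect has no reliable unit declaration, so `unit` applies
#'   (default `"um"`).
#' @return a [spindle], coordinates in micrometres.
#' @export
read_spatial_graph <- function(path, dialect = c("neutral_json", "amira_ascii"),
                               unit = "um") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         neutral_json = read_neutral_json(path),
         amira_ascii = read_amira_ascii(path, unit = unit))
}

#' Write a spindle in the neutral interchange format
#'
#' @param spindle a [spindle].
#' @param path output JSON path; the per-point CSV is written next to it
#'   with the same stem.
#' @param unit unit to store coordinates in (`"um"` or `"nm"`).
#' @return `path`, invisibly.
#' @export
write_spatial_graph <- function(spindle, path, unit = "um") {
  f <- unit_to_um(unit)
  csv_name <- paste0(sub("\\.json$", "", basename(path)), ".csv")
  csv_path <- file.path(dirname(path), csv_name)
  pts <- do.call(rbind, lapply(spindle$tracks, function(t) {
    data.frame(track_id = t$id,
               point_index = seq_len(nrow(t$points)) - 1L,
               x = t$points[, 1] / f, y = t$points[, 2] / f,
               z = t$points[, 3] / f)
  }))
  if (is.null(pts)) pts <- data.frame(track_id = character(),
                                      point_index = integer(),
                                      x = double(), y = double(), z = double())
  utils::write.csv(pts, csv_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    schema_version = NEUTRAL_SCHEMA_VERSION,
    unit = unit,
    z_factor = spindle$z_factor,
    provenance = spindle$provenance,
    points_file = csv_name,
    bounding_box = list(min = spindle$bounding_box[1, ] / c(f, f, f),
                        max = spindle$bounding_box[2, ] / c(f, f, f)),
    poles = if (is.null(spindle$poles)) NULL else lapply(spindle$poles, function(p) {
      list(label = p$label, mother_centriole = p$mother_centriole / f,
           daughter_centriole = if (is.null(p$daughter_centriole)) NULL
                                else p$daughter_centriole / f)
    }),
    kinetochores = lapply(spindle$kinetochores, function(k) {
      list(id = k$id, sister_id = k$sister_id, kmt_ids = as.list(k$kmt_ids))
    }),
    tracks = lapply(spindle$tracks, function(t) {
      list(id = t$id, mt_class = t$mt_class, fiber_id = t$fiber_id,
           plus_end = t$plus_end)
    })
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

read_neutral_json <- function(path) {
  meta <- tryCatch(jsonlite::read_json(path),
                   error = function(e) stop("malformed JSON in ", path, ": ",
                                            conditionMessage(e)))
  if (!identical(meta$schema_version, NEUTRAL_SCHEMA_VERSION))
    stop("unsupported neutral schema version: ", meta$schema_version)
  f <- unit_to_um(meta$unit %||% "um")
  csv_path <- file.path(dirname(path), meta$points_file)
  if (!file.exists(csv_path)) stop("points file not found: ", csv_path)
  pts <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  need <- c("track_id", "point_index", "x", "y", "z")
  if (!all(need %in% names(pts)))
    stop("points CSV must have columns: ", paste(need, collapse = ", "))
  if (anyNA(pts[c("x", "y", "z")])) stop("missing coordinates in ", csv_path)
  pts$track_id <- as.character(pts$track_id)
  by_track <- split(pts[order(pts$point_index), ], pts$track_id[order(pts$point_index)])
  track_meta <- meta$tracks %||% list()
  tm_ids <- vapply(track_meta, function(t) as.character(t$id), "")
  tracks <- lapply(names(by_track), function(id) {
    tp <- by_track[[id]]
    m <- if (id %in% tm_ids) track_meta[[match(id, tm_ids)]] else list()
    mt_track(id, cbind(tp$x, tp$y, tp$z) * f,
             plus_end = m$plus_end %||% "last",
             mt_class = m$mt_class %||% "unclassified",
             fiber_id = if (is.null(m$fiber_id) || is.na(m$fiber_id))
               NA_character_ else as.character(m$fiber_id))
  })
  # preserve the metadata track order where available
  if (length(tm_ids) && all(vapply(tracks, `[[`, "", "id") %in% tm_ids)) {
    ord <- match(tm_ids, vapply(tracks, `[[`, "", "id"))
    tracks <- tracks[ord[!is.na(ord)]]
  }
  poles <- NULL
  if (!is.null(meta$poles) && length(meta$poles) == 2L) {
    poles <- lapply(meta$poles, function(p) {
      pole(unlist(p$mother_centriole) * f,
           daughter_centriole = if (is.null(p$daughter_centriole)) NULL
                                else unlist(p$daughter_centriole) * f,
           label = p$label)
    })
  }
  kins <- lapply(meta$kinetochores %||% list(), function(k) {
    kinetochore(k$id, kmt_ids = unlist(k$kmt_ids) %||% character(),
                sister_id = if (is.null(k$sister_id)) NA_character_
                            else as.character(k$sister_id))
  })
  bb <- NULL
  if (!is.null(meta$bounding_box)) {
    bb <- rbind(unlist(meta$bounding_box$min), unlist(meta$bounding_box$max)) * f
    dimnames(bb) <- list(c("min", "max"), c("x", "y", "z"))
  }
  spindle(tracks, poles = poles, kinetochores = kins, bounding_box = bb,
          z_factor = meta$z_factor %||% 1,
          provenance = meta$provenance %||% paste0("read from ", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- Amira-style ASCII spatial graph ----------------------------------------
#
# Supported subset: "define VERTEX/EDGE/POINT n" counts, section declarations
# of the form  EDGE { int[2] EdgeConnectivity } @N  and the corresponding
# numeric @N data blocks. Tracks are edges; each edge's point run (lengths
# from NumEdgePoints) becomes one polyline. Unknown sections are skipped with
# a warning. Vertex indices in EdgeConnectivity are 0-based.

read_amira_ascii <- function(path, unit = "um") {
  f <- unit_to_um(unit)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("AmiraMesh.*ASCII", lines[1]))
    stop("parse error at line 1: not an AmiraMesh ASCII file")
  counts <- c(VERTEX = NA_integer_, EDGE = NA_integer_, POINT = NA_integer_)
  decl <- list() # maps "@N" -> list(entity, field, width)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^define\\s+(\\w+)\\s+(\\d+)", ln))[[1]]
    if (length(m) == 3L) {
      counts[m[2]] <- as.integer(m[3])
      next
    }
    m <- regmatches(ln, regexec(
      "^(\\w+)\\s*\\{\\s*(\\w+)(\\[(\\d+)\\])?\\s+(\\w+)\\s*\\}\\s*(@\\d+)", ln))[[1]]
    if (length(m) == 7L) {
      # m: full match, entity, base type, "[w]", w, field name, "@N"
      decl[[m[7]]] <- list(entity = m[2],
                           width = if (m[5] == "") 1L else as.integer(m[5]),
                           field = m[6], line = i)
    }
  }
  if (any(is.na(counts)))
    stop("parse error: missing 'define VERTEX/EDGE/POINT' counts")
  # locate data blocks
  at_lines <- grep("^@\\d+\\s*$", trimws(lines))
  blocks <- list()
  for (k in seq_along(at_lines)) {
    tag <- trimws(lines[at_lines[k]])
    from <- at_lines[k] + 1L
    to <- if (k < length(at_lines)) at_lines[k + 1L] - 1L else length(lines)
    body <- lines[from:to]
    body <- body[nzchar(trimws(body))]
    blocks[[tag]] <- body
  }
  get_block <- function(field, entity, width, n) {
    tag <- NULL
    for (nm in names(decl))
      if (decl[[nm]]$field == field && decl[[nm]]$entity == entity) tag <- nm
    if (is.null(tag)) stop("parse error: no section declares ", entity, " ", field)
    body <- blocks[[tag]]
    if (is.null(body)) stop("parse error: data block ", tag, " (", field, ") missing")
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
    if (anyNA(vals))
      stop("parse error in block ", tag, " near line ",
           decl[[tag]]$line, ": non-numeric value")
    if (length(vals) != n * width)
      stop("parse error in block ", tag, ": expected ", n * width,
           " values, got ", length(vals))
    matrix(vals, ncol = width, byrow = TRUE)
  }
  known <- c("VertexCoordinates", "EdgeConnectivity", "NumEdgePoints",
             "EdgePointCoordinates")
  unknown <- vapply(decl, function(d) !(d$field %in% known), NA)
  if (any(unknown))
    warning("skipping unknown spatial-graph sections: ",
            paste(vapply(decl[unknown], `[[`, "", "field"), collapse = ", "))
  conn <- get_block("EdgeConnectivity", "EDGE", 2L, counts["EDGE"])
  npts <- get_block("NumEdgePoints", "EDGE", 1L, counts["EDGE"])[, 1]
  pts <- get_block("EdgePointCoordinates", "POINT", 3L, counts["POINT"])
  if (sum(npts) != counts["POINT"])
    stop("parse error: NumEdgePoints sums to ", sum(npts),
         " but POINT count is ", counts["POINT"])
  offs <- cumsum(c(0, npts))
  tracks <- lapply(seq_len(counts["EDGE"]), function(e) {
    p <- pts[(offs[e] + 1L):offs[e + 1L], , drop = FALSE] * f
    # collapse exactly repeated consecutive vertices (stitching artefacts)
    if (nrow(p) > 1L) {
      keep <- c(TRUE, rowSums((p[-1L, , drop = FALSE] -
                               p[-nrow(p), , drop = FALSE])^2) > 0)
      p <- p[keep, , drop = FALSE]
    }
    mt_track(sprintf("E%04d", e - 1L), p)
  })
  spindle(tracks, provenance = paste0("amira_ascii:", basename(path)))
}
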