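# split one track's rows at frame gaps; returns list of row-index vectors
.splitRuns <- function(frames) {
  brk <- c(0L, which(diff(frames) != 1L), length(frames))
  lapply(seq_len(length(brk) - 1L), function(i)
    (brk[i] + 1L):brk[i + 1L])
}

.buildTracks <- function(df, dt, minLen, maxLen, splitGaps, hasScale,
                         axes) {
  out <- list()
  for (id in unique(df$id)) {
    sub <- df[df$id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (anyDuplicated(sub$frame))
      stopf("duplicate (track_id, frame) pair in track '%s'", id)
    pieces <- if (splitGaps) .splitRuns(sub$frame) else
      list(seq_len(nrow(sub)))
    npiece <- sum(vapply(pieces, length, integer(1)) >= max(minLen, 2L))
    seg <- 0L
    for (rows in pieces) {
      if (length(rows) < max(minLen, 2L)) next
      seg <- seg + 1L
      rows <- rows[seq_len(min(length(rows), maxLen))]
      pm <- as.matrix(sub[rows, axes, drop = FALSE])
      dimnames(pm) <- list(NULL, sub("_um$", "", axes))
      out[[length(out) + 1L]] <- Track(
        pm, dt = dt, frames = sub$frame[rows],
        trackId = if (npiece > 1L) paste0(id, ".", seg) else as.character(id),
        peakErrorScale = if (hasScale) sub$scale[rows] else NULL)
    }
  }
  TrackSet(out)
}

#' Read tracks from a CSV table
#'
#' Expects one row per localization with track id, frame index and per-axis
#' coordinates in micrometres. Tracks are grouped, sorted by frame, split at
#' frame gaps (the likelihood has no missing-observation term, so bridging a
#' gap would misstate the displacement time), filtered to a minimum length,
#' and truncated to at most `maxLen` positions (long tracks carry diminishing
#' information per position and slow the recursion).
#'
#' @param path CSV file path.
#' @param dt frame interval (s).
#' @param columns named character vector mapping roles to column names;
#'   roles: `id`, `frame`, `x`, optionally `y`, `z`, `scale` (per-peak
#'   localization-error scale).
#' @param minLen minimum positions per track (default 3).
#' @param maxLen maximum positions used per track (default 50).
#' @param splitGaps split tracks at frame gaps (default TRUE).
#' @return A [TrackSet-class].
#' @export
readTrackCSV <- function(path, dt,
                         columns = c(id = "track_id", frame = "frame",
                                     x = "x_um", y = "y_um", z = "z_um",
                                     scale = "sigma_scale"),
                         minLen = 3L, maxLen = 50L, splitGaps = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- read.csv(path, check.names = FALSE)
  need <- c("id", "frame", "x")
  for (role in need)
    if (!columns[[role]] %in% names(raw))
      stopf("missing required column '%s'", columns[[role]])
  axes <- c("x", "y", "z")
  axes <- axes[axes %in% names(columns) & columns[axes] %in% names(raw)]
  df <- data.frame(id = as.character(raw[[columns[["id"]]]]),
                   frame = raw[[columns[["frame"]]]])
  if (any(!is.finite(df$frame)))
    stopf("non-numeric frame index at row %s",
          paste(head(which(!is.finite(df$frame))), collapse = ","))
  df$frame <- as.integer(df$frame)
  for (a in axes) {
    v <- suppressWarnings(as.numeric(raw[[columns[[a]]]]))
    if (any(!is.finite(v)))
      stopf("non-numeric coordinate '%s' at row %d", columns[[a]],
            which(!is.finite(v))[1L])
    df[[paste0(a, "_um")]] <- v
  }
  hasScale <- "scale" %in% names(columns) &&
    columns[["scale"]] %in% names(raw)
  if (hasScale) df$scale <- as.numeric(raw[[columns[["scale"]]]])
  .buildTracks(df, dt, minLen, maxLen, splitGaps, hasScale,
               paste0(axes, "_um"))
}

#' Write tracks to CSV
#'
#' One row per localization: `track_id`, `frame`, per-axis `*_um` columns and
#' `sigma_scale` when any track carries per-peak error scales. The
#' writer/reader pair round-trips coordinates losslessly at full double
#' precision.
#'
#' @param tracks a [TrackSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrackCSV <- function(tracks, path) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  anyScale <- any(vapply(tracks, function(t) length(t@peakErrorScale) > 0,
                         logical(1)))
  rows <- lapply(as.list(tracks), function(tr) {
    pos <- positions(tr)
    colnames(pos) <- paste0(colnames(pos), "_um")
    df <- data.frame(track_id = trackId(tr), frame = tr@frames, pos,
                     row.names = NULL)
    if (anyScale)
      df$sigma_scale <- if (length(tr@peakErrorScale)) tr@peakErrorScale
                        else 1
    df
  })
  df <- do.call(rbind, rows)
  # full precision so the round trip is lossless
  old <- options(digits = 17); on.exit(options(old))
  write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from a TrackMate-style XML export
#'
#' Parses the `AllSpots` / `AllTracks` subset of TrackMate model XML: spot
#' positions (`POSITION_X/Y[/Z]`, `FRAME`) and the edges that assign spots to
#' tracks. Positions are taken as physical units when the file declares a
#' spatial calibration; otherwise `pixelSize` (um/px) must be given. The gap
#' and length rules of [readTrackCSV()] apply, so a gap-closed link in the
#' source becomes a split track here.
#'
#' @param path XML file path.
#' @param dt frame interval (s).
#' @param pixelSize um per pixel, required when the file stores pixel
#'   coordinates without calibration.
#' @param minLen,maxLen,splitGaps see [readTrackCSV()].
#' @return A [TrackSet-class].
#' @export
readTrackMateXML <- function(path, dt, pixelSize = NULL, minLen = 3L,
                             maxLen = 50L, splitGaps = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stopf("malformed XML: %s",
                                            conditionMessage(e)))
  spots <- xml2::xml_find_all(doc, ".//AllSpots//Spot")
  if (!length(spots)) stopf("no spots found; not a TrackMate model file?")
  att <- function(nodes, name) xml2::xml_attr(nodes, name)
  sid <- att(spots, "ID")
  sx <- as.numeric(att(spots, "POSITION_X"))
  sy <- as.numeric(att(spots, "POSITION_Y"))
  sz <- suppressWarnings(as.numeric(att(spots, "POSITION_Z")))
  sframe <- as.integer(att(spots, "FRAME"))
  cal <- xml2::xml_find_first(doc, ".//ImageData")
  calScale <- if (!inherits(cal, "xml_missing"))
    suppressWarnings(as.numeric(xml2::xml_attr(cal, "pixelwidth"))) else NA
  scale <- 1
  if (is.na(calScale)) {
    if (is.null(pixelSize))
      stopf("no spatial calibration in file; supply pixelSize (um/px)")
    scale <- pixelSize
  }
  trackNodes <- xml2::xml_find_all(doc, ".//AllTracks/Track")
  if (!length(trackNodes)) stopf("no tracks found")
  recs <- list()
  for (tn in trackNodes) {
    tid <- xml2::xml_attr(tn, "TRACK_ID")
    edges <- xml2::xml_find_all(tn, ".//Edge")
    ids <- unique(c(xml2::xml_attr(edges, "SPOT_SOURCE_ID"),
                    xml2::xml_attr(edges, "SPOT_TARGET_ID")))
    sel <- match(ids, sid)
    sel <- sel[!is.na(sel)]
    if (length(sel) < 2L) next
    rec <- data.frame(id = paste0("tm", tid), frame = sframe[sel],
                      x_um = sx[sel] * scale, y_um = sy[sel] * scale)
    if (!all(is.na(sz[sel])) && any(sz[sel] != 0))
      rec$z_um <- sz[sel] * scale
    recs[[length(recs) + 1L]] <- rec
  }
  df <- do.call(rbind, recs)
  axes <- intersect(c("x_um", "y_um", "z_um"), names(df))
  .buildTracks(df, dt, minLen, maxLen, splitGaps, hasScale = FALSE, axes)
}

#' Tracks as a flat table
#'
#' @param tracks a [TrackSet-class].
#' @return data.frame with `track_id`, `frame` and `*_um` coordinates.
#' @export
trackTable <- function(tracks) {
  if (!is(tracks, "TrackSet")) tracks <- TrackSet(tracks)
  do.call(rbind, lapply(as.list(tracks), function(tr) {
    pos <- positions(tr)
    colnames(pos) <- paste0(colnames(pos), "_um")
    data.frame(track_id = trackId(tr), frame = tr@frames, pos,
               row.names = NULL)
  }))
}
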