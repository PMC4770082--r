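# Aspiration-depth extraction from bright-field video: pipette geometry
# detection, cross-correlation template tracking of the embryo's leading
# edge, and conversion of pixel positions into an aspiration trace.

#' Detect the pipette geometry in one video frame
#'
#' The pipette enters horizontally from a frame border as two dark,
#' roughly horizontal wall bars terminating at the opening. Detection:
#' Gaussian smoothing, Otsu binarisation into dark/bright, identification
#' of the rows whose dark run starts at the entry border and is at least
#' `min_run` px long (the wall rows — the embryo never touches the entry
#' border), then refinement of the opening column as the termination of
#' those runs, cross-checked on a Canny edge map of the wall band.
#'
#' @param frame numeric matrix in [0, 1].
#' @param entry_side `"auto"` (default), `"left"` or `"right"`.
#' @param min_run minimum wall length in px (default 20).
#' @param sigma smoothing s.d. in px.
#' @return A `pipette_geometry` list: `opening_column`, `wall_rows`
#'   (outer lumen-boundary rows, 0-based), `lumen_center_row`,
#'   `inner_radius`, `entry_side`.
#' @export
detect_pipette <- function(frame, entry_side = c("auto", "left", "right"),
                           min_run = 20, sigma = 2) {
  entry_side <- match.arg(entry_side)
  sm <- EBImage::gblur(frame, sigma = sigma)
  thr <- EBImage::otsu(pmin(pmax(sm, 0), 1), range = c(0, 1))
  dark <- sm < thr
  h <- nrow(dark); w <- ncol(dark)

  run_from <- function(side) {
    m <- if (side == "left") dark else dark[, w:1]
    # length of the contiguous dark run starting at column 1, per row
    apply(m, 1, function(r) {
      z <- which(!r)
      if (length(z) == 0) w else z[1] - 1L
    })
  }
  pick <- function(side) {
    runs <- run_from(side)
    rows <- which(runs >= min_run & runs < 0.95 * w)
    list(side = side, runs = runs, rows = rows)
  }
  cand <- if (entry_side == "auto") {
    cl <- pick("left"); cr <- pick("right")
    if (length(cl$rows) >= length(cr$rows)) cl else cr
  } else pick(entry_side)

  rows <- cand$rows
  if (length(rows) < 4)
    stop("detect_pipette: no wall pair found (stage: wall-row scan)")
  # split wall rows into the two bands across the lumen gap
  gaps <- which(diff(rows) > 1)
  if (length(gaps) < 1)
    stop("detect_pipette: walls found but no lumen gap between them (stage: band split)")
  split_at <- gaps[which.max(diff(rows)[gaps])]
  top <- rows[seq_len(split_at)]
  bot <- rows[(split_at + 1):length(rows)]
  if (length(top) < 2 || length(bot) < 2)
    stop("detect_pipette: could not resolve two wall bands (stage: band split)")

  wall_rows <- c(max(top), min(bot)) # lumen-facing wall rows (1-based)
  inner_radius <- (wall_rows[2] - wall_rows[1]) / 2
  # opening column = termination corner of the wall edge lines: per wall
  # row, follow the Canny edge run from the entry border (gaps <= 2 px)
  # and record where it ends; the dark-run length is not used because the
  # embryo body can sit flush against the wall ends and extend the run
  edges <- canny_edges(frame, sigma = sigma)
  edge_end <- function(r) {
    e <- which(if (cand$side == "left") edges[r, ] else rev(edges[r, ]))
    if (length(e) == 0 || e[1] > max(5, 0.2 * w)) return(NA_real_)
    stop_i <- which(diff(e) > 2)
    if (length(stop_i)) e[stop_i[1]] else e[length(e)]
  }
  # the edge lines live on the wall boundary rows, not in the bar
  # interiors: keep band rows carrying a substantial horizontal edge run
  band0 <- unique(pmin(pmax(c(outer(c(top, bot), -2:2, "+")), 1), h))
  band <- band0[rowSums(edges[band0, , drop = FALSE]) >= max(10, 0.15 * w)]
  if (!length(band))
    stop("detect_pipette: wall edge lines not found (stage: corner refinement)")
  edge_runs <- vapply(band, edge_end, numeric(1))
  if (all(is.na(edge_runs)))
    stop("detect_pipette: wall edge lines not found (stage: corner refinement)")
  oc <- stats::median(edge_runs, na.rm = TRUE)
  opening_column <- if (cand$side == "left") oc - 1 else (w - 1) - (oc - 1)

  structure(list(opening_column = as.numeric(opening_column),
                 wall_rows = wall_rows - 1, # 0-based
                 lumen_center_row = mean(wall_rows) - 1,
                 inner_radius = inner_radius,
                 entry_side = cand$side),
            class = "pipette_geometry")
}

# normalized cross-correlation of template against same-size patch
ncc <- function(patch, template) {
  p <- patch - mean(patch); t <- template - mean(template)
  den <- sqrt(sum(p^2) * sum(t^2))
  if (den < 1e-12) return(0)
  sum(p * t) / den
}

#' Track the embryo's leading edge across an image sequence
#'
#' A template centred on the leading edge in frame 1 (restricted to the
#' pipette lumen rows) is matched in every frame by normalised
#' cross-correlation over a 1-D search along the pipette axis; the peak
#' is refined to subpixel precision by parabolic interpolation of the
#' correlation around its maximum. Frames whose peak correlation falls
#' below `quality_threshold` are flagged and their positions linearly
#' interpolated from neighbouring good frames (up to 3 consecutive).
#'
#' @param seq `image_sequence` (list of frames) from [render_video()] or
#'   [read_stack()].
#' @param geom [detect_pipette()] result (detected from frame 1 when
#'   `NULL`).
#' @param template_halfwidth half-width of the template along the axis,
#'   px (default 8).
#' @param quality_threshold minimum acceptable peak correlation
#'   (default 0.6).
#' @return A `track_result` data.frame: `frame`, `position_px` (signed
#'   axis position of the edge, increasing into the pipette, subpixel),
#'   `quality`, `flagged`.
#' @export
track_edge <- function(seq, geom = NULL, template_halfwidth = 8,
                       quality_threshold = 0.6) {
  if (length(seq) < 2) stop("track_edge: need >= 2 frames")
  if (is.null(geom)) geom <- detect_pipette(seq[[1]])
  h <- nrow(seq[[1]]); w <- ncol(seq[[1]])
  sgn <- if (geom$entry_side == "left") -1 else 1 # axis direction into pipette
  lum <- (round(geom$wall_rows[1]) + 2):(round(geom$wall_rows[2])) # 1-based rows
  oc <- round(geom$opening_column) + 1 # 1-based

  # locate the leading edge in frame 1: strongest axial intensity step
  # inside the lumen between the opening and the far end
  axis_cols <- if (geom$entry_side == "left") 1:oc else oc:w
  prof <- colMeans(seq[[1]][lum, axis_cols, drop = FALSE])
  dstep <- abs(diff(prof))
  e0 <- axis_cols[which.max(dstep)]
  # keep the template clear of the static opening structure: a patch
  # overlapping the pipette mouth anchors the correlation to scenery
  # that does not move with the embryo and biases the track
  hw <- min(template_halfwidth, max(3, abs(e0 - oc) - 2))
  t_cols <- max(1, e0 - hw):min(w, e0 + hw)
  template <- seq[[1]][lum, t_cols, drop = FALSE]

  search <- if (geom$entry_side == "left") (hw + 1):(oc + hw) else (oc - hw):(w - hw)
  n <- length(seq)
  pos <- numeric(n); qual <- numeric(n)
  for (f in seq_len(n)) {
    frame <- seq[[f]]
    shifts <- search - e0
    cc <- vapply(shifts, function(s) {
      cols <- t_cols + s
      if (cols[1] < 1 || cols[length(cols)] > w) return(-2)
      ncc(frame[lum, cols, drop = FALSE], template)
    }, numeric(1))
    i <- which.max(cc)
    qual[f] <- cc[i]
    # subpixel refinement: NCC against linearly interpolated fractional
    # shifts around the integer peak, then a parabola on the fine grid
    # (plain 3-point interpolation of the integer-spaced NCC suffers
    # pixel locking at the 0.1 px level)
    delta <- 0
    if (i > 1 && i < length(cc) && cc[i - 1] > -2 && cc[i + 1] > -2) {
      fine <- seq(-1, 1, by = 0.2)
      ccf <- vapply(fine, function(s) {
        s_int <- floor(s); fr <- s - s_int
        cols <- t_cols + shifts[i] + s_int
        if (cols[1] < 1 || cols[length(cols)] + 1 > w) return(-2)
        patch <- (1 - fr) * frame[lum, cols, drop = FALSE] +
          fr * frame[lum, cols + 1, drop = FALSE]
        ncc(patch, template)
      }, numeric(1))
      j <- which.max(ccf)
      delta <- fine[j]
      if (j > 1 && j < length(fine) && ccf[j - 1] > -2 && ccf[j + 1] > -2) {
        den <- ccf[j - 1] - 2 * ccf[j] + ccf[j + 1]
        if (abs(den) > 1e-12)
          delta <- delta + 0.2 * 0.5 * (ccf[j - 1] - ccf[j + 1]) / den
      }
      qual[f] <- max(qual[f], ccf[j])
    }
    pos[f] <- (e0 + shifts[i] + delta - 1) # 0-based column of the edge
  }
  flagged <- qual < quality_threshold
  if (any(flagged)) {
    runs <- rle(flagged)
    if (any(runs$lengths[runs$values] > 3) || all(flagged))
      stop("track_edge: lost track for more than 3 consecutive frames")
    good <- which(!flagged)
    pos[flagged] <- stats::approx(good, pos[good], xout = which(flagged),
                                  rule = 2)$y
  }
  structure(data.frame(frame = seq_len(n) - 1L,
                       position_px = sgn * pos, # increases into the pipette
                       quality = qual, flagged = flagged),
            class = c("track_result", "data.frame"),
            geom = geom)
}

#' Convert a pixel track into an aspiration trace
#'
#' Depth is the axial displacement of the leading edge relative to its
#' position in the onset frame — the frame in which the step is
#' commanded, where the embryo is still at rest (the instant elongation
#' appears one frame later). That frame supplies the zero reference and
#' is itself dropped, so the returned depths are absolute (they include
#' the instant jump) and times count from the onset.
#'
#' @param track [track_edge()] result.
#' @param pixel_size metres per pixel.
#' @param frame_rate frames per second.
#' @param onset_frame 0-based index of the last at-rest frame.
#' @param protocol optional [pressure_protocol()]; adds the pressure
#'   column.
#' @return An [aspiration_trace()] covering the frames after the onset.
#' @export
to_trace <- function(track, pixel_size, frame_rate = 75, onset_frame = 0,
                     protocol = NULL) {
  n <- nrow(track)
  if (onset_frame < 0 || onset_frame >= n - 1)
    stop("to_trace: onset_frame outside the sequence")
  ref <- track$position_px[track$frame == onset_frame]
  keep <- track$frame > onset_frame
  depths <- (track$position_px[keep] - ref) * pixel_size
  times <- (track$frame[keep] - onset_frame) / frame_rate
  aspiration_trace(times, depths,
                   pressures = if (!is.null(protocol))
                     rep(protocol$step_pressure, sum(keep)) else NULL,
                   rate = frame_rate)
}
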