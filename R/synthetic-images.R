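# Synthetic image fixtures: aspiration videos (bright-field) and
# confocal z-stacks with a cortical granule ring. Images are numeric
# matrices in [0, 1], row = y (origin top-left), column = x; stacks and
# videos are lists of matrices plus metadata attributes.

#' Scene geometry for a rendered aspiration video
#'
#' @param width,height frame size in pixels.
#' @param opening_column x-position (0-based px) of the pipette opening.
#' @param lumen_center_row y-position (0-based px) of the pipette axis.
#' @param inner_radius pipette inner radius, px.
#' @param wall_thickness pipette wall thickness, px.
#' @param embryo_radius embryo radius, px; must exceed `inner_radius`
#'   (an embryo smaller than the lumen would simply be swallowed).
#' @param pixel_size metres per pixel (default 0.5e-6).
#' @param entry_side side the pipette enters from (`"left"` or `"right"`).
#' @param bg,wall_level,embryo_level grey levels in [0, 1].
#' @return A `video_scene` list.
#' @export
video_scene <- function(width = 220, height = 120, opening_column = 110,
                        lumen_center_row = 60, inner_radius = 18,
                        wall_thickness = 5, embryo_radius = 40,
                        pixel_size = 0.5e-6, entry_side = c("left", "right"),
                        bg = 0.85, wall_level = 0.15, embryo_level = 0.45) {
  entry_side <- match.arg(entry_side)
  if (embryo_radius <= inner_radius)
    stop("video_scene: embryo_radius must exceed inner_radius (nonphysical scene)")
  if (opening_column + sqrt(embryo_radius^2 - inner_radius^2) + embryo_radius >= width - 1)
    stop("video_scene: embryo disk does not fit inside the frame")
  if (lumen_center_row - inner_radius - wall_thickness < 0 ||
      lumen_center_row + inner_radius + wall_thickness >= height)
    stop("video_scene: pipette walls do not fit inside the frame")
  if (opening_column <= 0 || opening_column >= width - 1)
    stop("video_scene: opening_column must lie inside the frame")
  structure(as.list(environment()), class = "video_scene")
}

# soft-edge indicator: 1 inside (d < 0), 0 outside, ~1 px transition
soft_in <- function(d, softness = 0.7) 1 / (1 + exp(d / softness))

render_frame <- function(scene, depth_px) {
  w <- scene$width; h <- scene$height
  col <- matrix(rep(0:(w - 1), each = h), nrow = h) # x coordinate
  row <- matrix(rep(0:(h - 1), times = w), nrow = h)
  if (scene$entry_side == "right") col <- (w - 1) - col # mirror x
  oc <- scene$opening_column; cr <- scene$lumen_center_row
  r_in <- scene$inner_radius; wt <- scene$wall_thickness

  img <- matrix(scene$bg, h, w)
  # pipette walls: two horizontal bars from x = 0 to the opening column
  dy <- abs(row - cr)
  wall_band <- pmax(r_in - dy, dy - (r_in + wt)) # < 0 inside wall annulus rows
  wall_mask <- soft_in(wall_band) * soft_in(col - oc)
  # embryo body: disk tangent to the opening from outside
  cx <- oc + sqrt(max(scene$embryo_radius^2 - r_in^2, 0))
  d_body <- sqrt((col - cx)^2 + (row - cr)^2) - scene$embryo_radius
  body_mask <- soft_in(d_body) * soft_in(oc - col)
  # aspirated tongue inside the lumen with a hemispherical leading cap
  edge_col <- oc - depth_px # leading edge moves into the pipette
  dyl <- pmin(abs(row - cr), r_in)
  cap <- r_in - sqrt(r_in^2 - dyl^2)
  tongue_mask <- soft_in(edge_col + cap - col) * soft_in(col - oc) *
    soft_in(dy - r_in + 0.5)
  cell <- pmin(body_mask + tongue_mask, 1)
  img <- img + (scene$wall_level - scene$bg) * wall_mask
  img <- img * (1 - cell) + scene$embryo_level * cell
  img
}

#' Render a synthetic aspiration video
#'
#' Produces a grayscale image sequence of an embryo held at a horizontal
#' pipette, with the aspirated tongue's leading edge displaced into the
#' lumen by `motion(t)` (metres, converted through the scene's pixel
#' size). Additive Gaussian pixel noise emulates the camera.
#'
#' @param motion numeric vector of aspiration depths (m), one per frame,
#'   or a function of time (s).
#' @param scene a [video_scene()].
#' @param n_frames number of frames (required when `motion` is a function).
#' @param frame_rate frames per second (default 75).
#' @param noise_sd pixel noise s.d. in grey levels (default 0.01).
#' @param seed integer seed.
#' @return `image_sequence`: list of matrices with attributes
#'   `pixel_size`, `frame_rate`, `scene`, `seed`.
#' @export
render_video <- function(motion, scene = video_scene(), n_frames = NULL,
                         frame_rate = 75, noise_sd = 0.01, seed = 1L) {
  if (noise_sd < 0) stop("render_video: noise_sd must be >= 0")
  if (is.function(motion)) {
    if (is.null(n_frames)) stop("render_video: n_frames required with a motion function")
    motion <- motion((seq_len(n_frames) - 1) / frame_rate)
  }
  depth_px <- motion / scene$pixel_size
  if (max(depth_px) > scene$opening_column - 2)
    stop("render_video: motion exceeds the pipette length in the frame")
  frames <- withr::with_seed(seed, lapply(depth_px, function(d) {
    f <- render_frame(scene, d)
    if (noise_sd > 0)
      f <- f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow(f), ncol(f))
    pmin(pmax(f, 0), 1)
  }))
  structure(frames, class = "image_sequence",
            pixel_size = scene$pixel_size, frame_rate = frame_rate,
            scene = scene, seed = seed)
}

#' Render a synthetic confocal z-stack with a cortical granule ring
#'
#' Each slice shows a cell whose cortex carries a smooth ring of
#' intensity `ring_level` centred at 95% of the cell radius plus
#' `n_puncta` Gaussian granule puncta placed on the same annulus at
#' random angles (re-drawn per slice). Slice `k` (0-based) is attenuated
#' by `exp(-k / attenuation_scale)`, emulating the loss of signal at
#' greater imaging depth that the contrast-normalisation step must undo.
#'
#' @param center cell center `c(row, col)` px (0-based).
#' @param radius cell radius px.
#' @param size image size `c(rows, cols)`.
#' @param ring_level peak intensity of the smooth cortical ring.
#' @param n_puncta granule puncta per slice (>= 0).
#' @param puncta_amp,puncta_sigma punctum peak amplitude and Gaussian
#'   width (px).
#' @param cyto_level interior (cytoplasm) intensity.
#' @param attenuation_scale depth-attenuation scale in slices
#'   (`Inf` disables attenuation).
#' @param n_slices number of slices (>= 1).
#' @param noise_sd additive Gaussian noise s.d.
#' @param seed integer seed.
#' @return `confocal_stack`: list of matrices with attributes `center`,
#'   `radius`, `seed`.
#' @export
render_confocal <- function(center = c(127, 127), radius = 60,
                            size = c(256, 256), ring_level = 0.35,
                            n_puncta = 40, puncta_amp = 0.5,
                            puncta_sigma = 1.5, cyto_level = 0.12,
                            attenuation_scale = Inf, n_slices = 8,
                            noise_sd = 0.005, seed = 1L) {
  if (n_slices < 1) stop("render_confocal: n_slices must be >= 1")
  if (n_puncta < 0) stop("render_confocal: n_puncta must be >= 0")
  h <- size[1]; w <- size[2]
  ring_r <- 0.95 * radius
  if (center[1] - radius < 1 || center[1] + radius > h - 2 ||
      center[2] - radius < 1 || center[2] + radius > w - 2)
    stop("render_confocal: cell does not fit inside the frame")
  col <- matrix(rep(0:(w - 1), each = h), nrow = h)
  row <- matrix(rep(0:(h - 1), times = w), nrow = h)
  rr <- sqrt((row - center[1])^2 + (col - center[2])^2)
  ring_sigma <- 0.05 * radius # smooth band matching the scoring annulus
  base <- cyto_level * soft_in(rr - radius, 1) +
    ring_level * exp(-((rr - ring_r)^2) / (2 * ring_sigma^2))

  slices <- withr::with_seed(seed, lapply(seq_len(n_slices) - 1L, function(k) {
    img <- base
    if (n_puncta > 0) {
      ang <- stats::runif(n_puncta, 0, 2 * pi)
      pr <- center[1] + ring_r * sin(ang)
      pc <- center[2] + ring_r * cos(ang)
      for (i in seq_len(n_puncta)) {
        # local Gaussian blob; restrict to a small window for speed
        r0 <- max(1, floor(pr[i] - 4 * puncta_sigma)):min(h - 1, ceiling(pr[i] + 4 * puncta_sigma))
        c0 <- max(1, floor(pc[i] - 4 * puncta_sigma)):min(w - 1, ceiling(pc[i] + 4 * puncta_sigma))
        blob <- puncta_amp * exp(-(outer((r0 - pr[i])^2, (c0 - pc[i])^2, "+")) /
                                   (2 * puncta_sigma^2))
        img[r0 + 1, c0 + 1] <- img[r0 + 1, c0 + 1] + blob
      }
    }
    att <- if (is.finite(attenuation_scale)) exp(-k / attenuation_scale) else 1
    img <- img * att
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), h, w)
    pmax(img, 0)
  }))
  structure(slices, class = "confocal_stack",
            center = center, radius = radius, seed = seed)
}

#' Write / read an image stack as multi-page TIFF with a JSON sidecar
#'
#' Stores frames as 8-bit (videos) or 16-bit (confocal) grayscale pages
#' and the acquisition metadata (pixel size, frame rate, seed) in a
#' `.json` sidecar next to the TIFF.
#'
#' @param stack an `image_sequence` or `confocal_stack` (list of matrices
#'   in [0, 1]).
#' @param path output `.tiff` path; sidecar written to `<path>.json`.
#' @param bits 8 or 16.
#' @export
write_stack <- function(stack, path, bits = 8L) {
  pages <- lapply(stack, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(n_frames = length(stack),
               pixel_size = attr(stack, "pixel_size"),
               frame_rate = attr(stack, "frame_rate"),
               seed = attr(stack, "seed"),
               class = class(stack))
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  structure(pages,
            class = if (identical(meta$class[[1]], "confocal_stack"))
              "confocal_stack" else "image_sequence",
            pixel_size = meta$pixel_size, frame_rate = meta$frame_rate,
            seed = meta$seed)
}
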