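# Edge detection and circle Hough transform shared by the pipette
# detector and the confocal cell locator. Smoothing and Otsu thresholds
# come from EBImage; the Canny stages (gradient, non-maximum
# suppression, hysteresis) and the gradient-direction circle Hough are
# implemented here since no installed package exposes them for plain
# matrices.

sobel_gradients <- function(img) {
  # filter2 convolves (kernel flipped), hence the sign: response is
  # +d/d(row) for this kernel orientation
  kd <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), 3, 3)
  gy <- EBImage::filter2(img, kd, boundary = "replicate")
  gx <- EBImage::filter2(img, t(kd), boundary = "replicate")
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny-style edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantised gradient direction, and two-threshold hysteresis. The
#' hysteresis thresholds default to the Otsu threshold of the gradient
#' magnitude (high) and half of it (low).
#'
#' @param img numeric matrix in [0, 1].
#' @param sigma Gaussian smoothing s.d. in px (default 2).
#' @param low,high hysteresis thresholds on gradient magnitude; `NULL`
#'   selects them from Otsu's method on the magnitude image.
#' @return logical matrix of edge pixels.
#' @export
canny_edges <- function(img, sigma = 2, low = NULL, high = NULL) {
  sm <- EBImage::gblur(img, sigma = sigma)
  g <- sobel_gradients(sm)
  mag <- g$mag
  if (is.null(high)) {
    rng <- range(mag)
    high <- if (rng[2] > rng[1])
      EBImage::otsu(mag / rng[2], range = c(0, 1)) * rng[2] else Inf
  }
  if (is.null(low)) low <- high / 2

  h <- nrow(mag); w <- ncol(mag)
  # quantise direction into 4 sectors and compare against the two
  # neighbours along the gradient
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- floor((ang + pi / 8) / (pi / 4)) %% 4 # 0:E-W,1:NE-SW,2:N-S,3:NW-SE
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mag
  nb <- function(dr, dc) pad[2:(h + 1) + dr, 2:(w + 1) + dc]
  n1 <- matrix(0, h, w); n2 <- matrix(0, h, w)
  for (s in 0:3) {
    off <- switch(s + 1,
                  c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
    m <- sector == s
    n1[m] <- nb(off[1], off[2])[m]
    n2[m] <- nb(-off[1], -off[2])[m]
  }
  thin <- mag >= n1 & mag >= n2
  strong <- thin & mag >= high
  weak <- thin & mag >= low
  # hysteresis: keep weak-edge components connected to a strong pixel
  lab <- EBImage::bwlabel(weak * 1)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & matrix(lab %in% keep, h, w)
}

#' Circle Hough transform with gradient-direction voting
#'
#' For each edge pixel, votes are cast at the candidate center
#' `p + r * grad_hat` for each radius in `radii`, where `grad_hat` is
#' the unit gradient (pointing toward increasing intensity); the
#' accumulator is lightly smoothed and its global maximum returned.
#' For a bright object on a dark background this selects the outer
#' boundary: its gradient points inward, so only outer-boundary pixels
#' vote coherently at the object center, and interior structure (such
#' as the inner edge of a cortical ring) scatters its votes elsewhere.
#' `sides = "both"` restores the classical two-sided voting.
#'
#' @param edges logical edge map (e.g. from [canny_edges()]).
#' @param img image the edges came from (for gradient directions).
#' @param radii integer radii to scan, px.
#' @param min_votes minimum accumulator mass in a 5x5 window around the
#'   peak, as a fraction of `2*pi*r`, below which detection fails
#'   (default 0.25).
#' @param sides `"inward"` (default) or `"both"`.
#' @return list `center` (row, col; 0-based), `radius`, `votes`.
#' @export
hough_circle <- function(edges, img, radii, min_votes = 0.25,
                         sides = c("inward", "both")) {
  sides <- match.arg(sides)
  g <- sobel_gradients(EBImage::gblur(img, 2))
  h <- nrow(edges); w <- ncol(edges)
  idx <- which(edges)
  if (length(idx) == 0) stop("hough_circle: empty edge map")
  er <- (idx - 1) %% h + 1
  ec <- (idx - 1) %/% h + 1
  gx <- g$gx[idx]; gy <- g$gy[idx]
  mg <- pmax(sqrt(gx^2 + gy^2), 1e-12)
  ur <- gy / mg; uc <- gx / mg # unit gradient (row dir = y uses gy)

  best <- list(votes = -Inf)
  for (r in radii) {
    acc <- matrix(0L, h, w)
    for (sgn in if (sides == "inward") 1 else c(-1, 1)) {
      cr <- round(er + sgn * r * ur)
      cc <- round(ec + sgn * r * uc)
      ok <- cr >= 1 & cr <= h & cc >= 1 & cc <= w
      tab <- table((cc[ok] - 1L) * h + cr[ok])
      acc[as.integer(names(tab))] <- acc[as.integer(names(tab))] + as.integer(tab)
    }
    acc_s <- EBImage::gblur(acc, 1.5)
    m <- which.max(acc_s)
    if (acc_s[m] > best$votes) {
      pr <- (m - 1) %% h + 1; pc <- (m - 1) %/% h + 1
      win <- acc[max(1, pr - 2):min(h, pr + 2), max(1, pc - 2):min(w, pc + 2)]
      best <- list(center = c(pr, pc) - 1, radius = r,
                   votes = acc_s[m], mass = sum(win))
    }
  }
  if (best$mass < min_votes * 2 * pi * best$radius)
    stop("hough_circle: no circle above the vote threshold")
  best[c("center", "radius", "votes")]
}
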