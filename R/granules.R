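# Cortical-granule scoring of confocal z-stacks: per-slice contrast
# normalisation, projection, cell detection (Otsu -> Canny -> circle
# Hough) and the circumferential intensity profile at 95% of the cell
# radius whose mean and s.d. summarise granule signal.

#' Per-slice contrast normalisation of a z-stack
#'
#' Rescales each slice independently by its 1st-99th intensity
#' percentiles to [0, 1] (clipped), which removes the depth-dependent
#' signal attenuation of confocal imaging. Constant slices pass through
#' unchanged.
#'
#' @param stack `confocal_stack` or list of numeric matrices.
#' @param probs lower/upper rescaling percentiles (default `c(0.01, 0.99)`).
#' @return Normalised stack, attributes preserved.
#' @export
normalize_stack <- function(stack, probs = c(0.01, 0.99)) {
  if (length(stack) == 0) stop("normalize_stack: empty stack")
  out <- lapply(stack, function(s) {
    q <- stats::quantile(s, probs, names = FALSE)
    if (q[2] - q[1] < 1e-12) return(s) # constant slice: pass through
    pmin(pmax((s - q[1]) / (q[2] - q[1]), 0), 1)
  })
  attributes(out) <- attributes(stack)
  out
}

#' Project a z-stack to a single image
#'
#' @param stack list of matrices (normalise first with
#'   [normalize_stack()]).
#' @param method `"max"` (default; granules are sparse bright puncta, so
#'   a maximum projection retains every punctum at full amplitude) or
#'   `"mean"`.
#' @return A single matrix.
#' @export
project_stack <- function(stack, method = c("max", "mean")) {
  method <- match.arg(method)
  arr <- simplify2array(stack)
  if (length(dim(arr)) == 2) return(arr)
  apply(arr, c(1, 2), if (method == "max") max else mean)
}

#' Locate the cell in a projection image
#'
#' Otsu binarisation isolates the cell from background; the binary mask
#' is hole-filled and reduced to its largest connected component so that
#' interior structure (the granule ring, puncta) cannot contribute
#' spurious boundaries; Canny edge detection on that mask extracts the
#' cell outline and a circle Hough transform over `radii` returns the
#' highest-vote circle. Fails with an error (never a default geometry)
#' when no circle reaches the vote threshold.
#'
#' @param image projection matrix in [0, 1].
#' @param radii candidate radii in px (default 20 px to half the short
#'   image side).
#' @param min_votes vote threshold passed to [hough_circle()].
#' @return A `cell_geometry` list: `center` (row, col; 0-based),
#'   `radius` px.
#' @export
locate_cell <- function(image, radii = NULL, min_votes = 0.25) {
  if (is.null(radii))
    radii <- seq(20L, floor(min(dim(image)) / 2) - 2L, by = 1L)
  rng <- range(image)
  if (rng[2] - rng[1] < 1e-9) stop("locate_cell: blank image, no cell found")
  img01 <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(img01, range = c(0, 1))
  mask <- EBImage::fillHull(EBImage::bwlabel((img01 > thr) * 1))
  sizes <- tabulate(mask[mask > 0])
  if (!length(sizes)) stop("locate_cell: thresholding left no foreground")
  disk <- (mask == which.max(sizes)) * 1
  edges <- canny_edges(disk, sigma = 2)
  if (!any(edges)) stop("locate_cell: no edges found after thresholding")
  hc <- hough_circle(edges, disk, radii, min_votes = min_votes)
  structure(list(center = hc$center, radius = hc$radius, votes = hc$votes),
            class = "cell_geometry")
}

bilinear <- function(image, r, c) {
  # r, c are 0-based continuous coordinates (row, col)
  h <- nrow(image); w <- ncol(image)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r0 <- pmin(pmax(r0, 0), h - 2); c0 <- pmin(pmax(c0, 0), w - 2)
  i00 <- image[cbind(r0 + 1, c0 + 1)]
  i10 <- image[cbind(r0 + 2, c0 + 1)]
  i01 <- image[cbind(r0 + 1, c0 + 2)]
  i11 <- image[cbind(r0 + 2, c0 + 2)]
  i00 * (1 - fr) * (1 - fc) + i10 * fr * (1 - fc) +
    i01 * (1 - fr) * fc + i11 * fr * fc
}

#' Circumferential cortical intensity profile
#'
#' Samples the image along a circular path at 95% of the cell radius
#' with a radial band of width 10% of the radius (realised as
#' `n_radii` equally spaced radii spanning [0.90R, 1.00R]): at each of
#' `n_angles` equally spaced angles the bilinearly interpolated
#' intensities across the band are averaged, giving the angular profile.
#' The returned score is the mean and s.d. of that profile — the mean
#' tracks overall cortical granule brightness, the s.d. its angular
#' granularity (punctate rings score a higher s.d. than smooth rings of
#' equal brightness).
#'
#' @param image projection matrix.
#' @param geom [locate_cell()] result (or list with `center`, `radius`).
#' @param n_angles angular samples; default one per circumference pixel,
#'   `ceiling(2 * pi * 0.95 * R)`.
#' @param n_radii radial samples across the band (default 7).
#' @return A `granule_score`: `profile`, `mean`, `sd`, `geom`.
#' @export
circumferential_profile <- function(image, geom, n_angles = NULL, n_radii = 7) {
  R <- geom$radius
  ctr <- geom$center
  if (is.null(n_angles)) n_angles <- ceiling(2 * pi * 0.95 * R)
  radii <- seq(0.90 * R, 1.00 * R, length.out = n_radii)
  if (ctr[1] - max(radii) < 0 || ctr[1] + max(radii) > nrow(image) - 1 ||
      ctr[2] - max(radii) < 0 || ctr[2] + max(radii) > ncol(image) - 1)
    stop("circumferential_profile: annulus clipped by the image border")
  ang <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  prof <- vapply(ang, function(a) {
    mean(bilinear(image, ctr[1] + radii * sin(a), ctr[2] + radii * cos(a)))
  }, numeric(1))
  structure(list(profile = prof, mean = mean(prof), sd = stats::sd(prof),
                 geom = geom),
            class = "granule_score")
}

#' Score one confocal stack end to end
#'
#' Convenience wrapper: [normalize_stack()] -> [project_stack()] ->
#' [locate_cell()] -> [circumferential_profile()].
#'
#' @param stack a `confocal_stack`.
#' @param ... passed to [locate_cell()].
#' @return A `granule_score`.
#' @export
score_stack <- function(stack, ...) {
  img <- project_stack(normalize_stack(stack))
  circumferential_profile(img, locate_cell(img, ...))
}

#' Compare granule scores between two groups
#'
#' Two-sided Wilcoxon rank-sum comparison of a score (default the
#' profile mean) between groups, with optional quartile stratification
#' by a covariate such as the fitted `k1` stiffness: embryos are split
#' into quartiles of the covariate and the groups compared within each
#' quartile, mirroring the stiffest-quartile analyses used for
#' antibody-injection experiments.
#'
#' @param scores_a,scores_b numeric score vectors (>= 3 each).
#' @param covariate_a,covariate_b optional covariates for quartile
#'   stratification (quartile cut points from the pooled covariate).
#' @return list `overall` (a [wilcoxon_rank_sum()] report plus medians)
#'   and, when covariates are given, `by_quartile` (list of reports).
#' @export
compare_groups <- function(scores_a, scores_b,
                           covariate_a = NULL, covariate_b = NULL) {
  if (length(scores_a) < 3 || length(scores_b) < 3)
    stop("compare_groups: need >= 3 scores per group")
  overall <- wilcoxon_rank_sum(scores_a, scores_b)
  overall$median_a <- stats::median(scores_a)
  overall$median_b <- stats::median(scores_b)
  out <- list(overall = overall)
  if (!is.null(covariate_a) && !is.null(covariate_b)) {
    cuts <- stats::quantile(c(covariate_a, covariate_b), probs = c(0.25, 0.5, 0.75))
    qa <- findInterval(covariate_a, cuts) + 1L
    qb <- findInterval(covariate_b, cuts) + 1L
    out$by_quartile <- lapply(1:4, function(q) {
      xa <- scores_a[qa == q]; xb <- scores_b[qb == q]
      if (length(xa) < 1 || length(xb) < 1)
        return(list(test = "wilcoxon_rank_sum", p_value = NA_real_,
                    n_a = length(xa), n_b = length(xb)))
      r <- wilcoxon_rank_sum(xa, xb)
      r$n_a <- length(xa); r$n_b <- length(xb)
      r
    })
  }
  out
}
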