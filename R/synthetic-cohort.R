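# Seeded synthetic-data generators: embryo cohorts and aspiration traces.
# Every generator takes an explicit seed and restores the caller's RNG
# state, so fixtures are bit-reproducible and never perturb a session.

#' Specification of a synthetic embryo cohort
#'
#' @description
#' Defines the two-class structure of a simulated zygote cohort. Viable
#' embryos cluster tightly (log-normal, multiplicative spread) around a
#' per-feature center; the defaults are the human viable cluster
#' `k1 = 0.30` N/m, `eta1 = 0.59` N s/m, `k0 = 0.12` N/m (mouse:
#' `k1 = 0.17`, `eta1 = 1.3`, `k0 = 0.06`). Non-viable embryos have no
#' typical phenotype: they are drawn from a dispersed two-component
#' mixture, one component stiffer and one softer than the viable center.
#' The series viscosity `eta0` is drawn from one shared distribution for
#' both classes, making it uninformative for viability by construction.
#' Cell-cycle intervals `c1` (duration of first cytokinesis), `c2`
#' (first-to-second mitosis) and `c3` (second-to-third mitosis), in hours,
#' are tight around the viable center (defaults `0.20, 11.32, 2.91` h)
#' for viable embryos and widely dispersed (uniform band) for non-viable
#' ones. Blastocyst labels equal the mechanical class flipped with
#' probability `label_noise`, so the mechanics-label association is strong
#' but imperfect, as in real cohorts.
#'
#' @param species `"human"` or `"mouse"`; selects the default centers.
#' @param n_viable,n_nonviable class sizes (>= 0).
#' @param viable_center named list/vector `k1`, `eta1`, `k0` (N/m, N s/m,
#'   N/m); default per species.
#' @param viable_spread multiplicative dispersion of the viable class
#'   (log-normal sdlog), default 0.15.
#' @param nonviable_mixture list with `weights` (2, summing to 1),
#'   `factors` (center multipliers, default stiff 1.8 / soft 0.55) and
#'   `spread` (sdlog, default 0.4).
#' @param eta0_center,eta0_spread shared series-viscosity distribution
#'   (N s/m); class-independent.
#' @param cellcycle_center named `c1`, `c2`, `c3` in hours.
#' @param cellcycle_spread relative s.d. of viable cell-cycle intervals
#'   (default 0.10).
#' @param cellcycle_band multiplicative band `[lo, hi]` of the non-viable
#'   uniform cell-cycle distribution, default `c(0.3, 3)`.
#' @param label_noise probability in `[0, 1]` that a record's blastocyst
#'   label disagrees with its mechanical class (default 0.1).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @seealso [sample_cohort()]
#' @export
cohort_spec <- function(species = c("human", "mouse"),
                        n_viable = 80, n_nonviable = 120,
                        viable_center = NULL,
                        viable_spread = 0.15,
                        nonviable_mixture = list(weights = c(0.5, 0.5),
                                                 factors = c(1.8, 0.55),
                                                 spread = 0.4),
                        eta0_center = NULL, eta0_spread = 0.4,
                        cellcycle_center = c(c1 = 0.20, c2 = 11.32, c3 = 2.91),
                        cellcycle_spread = 0.10,
                        cellcycle_band = c(0.3, 3),
                        label_noise = 0.1,
                        seed = 1L) {
  species <- match.arg(species)
  if (is.null(viable_center))
    viable_center <- if (species == "human")
      c(k1 = 0.30, eta1 = 0.59, k0 = 0.12) else c(k1 = 0.17, eta1 = 1.3, k0 = 0.06)
  viable_center <- unlist(viable_center)[c("k1", "eta1", "k0")]
  if (is.null(eta0_center)) eta0_center <- if (species == "human") 10 else 5
  for (nm in names(viable_center))
    if (!is.finite(viable_center[[nm]]) || viable_center[[nm]] <= 0)
      stop("cohort_spec: viable_center '", nm, "' must be > 0")
  if (eta0_center <= 0) stop("cohort_spec: eta0_center must be > 0")
  if (any(unlist(cellcycle_center) <= 0)) stop("cohort_spec: cellcycle_center must be > 0")
  if (n_viable < 0 || n_nonviable < 0) stop("cohort_spec: counts must be >= 0")
  if (label_noise < 0 || label_noise > 1) stop("cohort_spec: label_noise must be in [0, 1]")
  if (abs(sum(nonviable_mixture$weights) - 1) > 1e-9)
    stop("cohort_spec: nonviable_mixture weights must sum to 1")
  structure(list(species = species, n_viable = n_viable, n_nonviable = n_nonviable,
                 viable_center = viable_center, viable_spread = viable_spread,
                 nonviable_mixture = nonviable_mixture,
                 eta0_center = eta0_center, eta0_spread = eta0_spread,
                 cellcycle_center = unlist(cellcycle_center)[c("c1", "c2", "c3")],
                 cellcycle_spread = cellcycle_spread,
                 cellcycle_band = cellcycle_band,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a synthetic embryo cohort
#'
#' Draws one embryo record per row according to a [cohort_spec()].
#' Mechanical features of viable embryos are log-normal around the viable
#' center; non-viable mechanics come from the stiff/soft mixture; `eta0`
#' is sampled identically for both classes. The `blastocyst` column is the
#' mechanical class flipped independently per embryo with probability
#' `label_noise`.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns `embryo_id`, `species`, `k0`, `k1`,
#'   `eta0`, `eta1`, `c1`, `c2`, `c3`, `blastocyst` (logical) and
#'   `mech_class` (the latent mechanical class the labels were derived
#'   from, useful for diagnostics).
#' @export
#' @examples
#' coh <- sample_cohort(cohort_spec("human", n_viable = 5, n_nonviable = 5, seed = 7))
#' coh[, c("embryo_id", "k1", "eta1", "k0", "blastocyst")]
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    nv <- spec$n_viable; nn <- spec$n_nonviable
    ctr <- spec$viable_center
    rln <- function(n, center, sdlog) center * exp(stats::rnorm(n, 0, sdlog))

    draw_mech <- function(n, centers, sdlog) {
      data.frame(k1 = rln(n, centers[["k1"]], sdlog),
                 eta1 = rln(n, centers[["eta1"]], sdlog),
                 k0 = rln(n, centers[["k0"]], sdlog))
    }
    viable <- draw_mech(nv, ctr, spec$viable_spread)

    mix <- spec$nonviable_mixture
    comp <- sample.int(2L, nn, replace = TRUE, prob = mix$weights)
    nonviable <- draw_mech(nn, ctr, mix$spread)
    for (f in c("k1", "eta1", "k0"))
      nonviable[[f]] <- nonviable[[f]] * mix$factors[comp]

    mech <- rbind(viable, nonviable)
    mech$eta0 <- rln(nv + nn, spec$eta0_center, spec$eta0_spread)

    cc_ctr <- spec$cellcycle_center
    band <- spec$cellcycle_band
    cc <- matrix(0, nv + nn, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
    for (f in colnames(cc)) {
      cc[seq_len(nv), f] <-
        pmax(stats::rnorm(nv, cc_ctr[[f]], spec$cellcycle_spread * cc_ctr[[f]]), 0)
    }
    for (f in colnames(cc)) {
      cc[nv + seq_len(nn), f] <-
        stats::runif(nn, band[1] * cc_ctr[[f]], band[2] * cc_ctr[[f]])
    }

    mech_class <- rep(c(TRUE, FALSE), c(nv, nn))
    flip <- stats::runif(nv + nn) < spec$label_noise
    blastocyst <- xor(mech_class, flip)

    out <- data.frame(
      embryo_id = sprintf("E%04d", seq_len(nv + nn)),
      species = spec$species,
      k0 = mech$k0, k1 = mech$k1, eta0 = mech$eta0, eta1 = mech$eta1,
      c1 = cc[, "c1"], c2 = cc[, "c2"], c3 = cc[, "c3"],
      blastocyst = blastocyst,
      mech_class = mech_class,
      stringsAsFactors = FALSE)
    out
  })
}

#' Simulate one aspiration-depth trace
#'
#' Evaluates the closed-form creep response of a model on a regular time
#' grid and adds i.i.d. zero-mean Gaussian measurement noise, emulating
#' the depth series extracted from a 75 frames-per-second aspiration
#' video.
#'
#' @param params [visco_params()] of the simulated embryo.
#' @param protocol [pressure_protocol()] applied.
#' @param noise_sd measurement noise s.d. in metres (>= 0).
#' @param duration trace length in seconds.
#' @param rate sampling rate in Hz (default 75).
#' @param model model generating the response (default `"modified_zener"`).
#' @param seed integer seed.
#' @return An [aspiration_trace()] with a `pressure_pa` column (step at
#'   t = 0).
#' @export
render_trace <- function(params, protocol, noise_sd = 1e-7, duration = 5,
                         rate = 75, model = "modified_zener", seed = 1L) {
  if (noise_sd < 0) stop("render_trace: noise_sd must be >= 0")
  if (duration <= 0 || rate <= 0) stop("render_trace: duration and rate must be > 0")
  F0 <- step_force(protocol)
  times <- seq(0, duration, by = 1 / rate)
  clean <- creep(times, model, params, F0)
  noisy <- withr::with_seed(seed, clean + stats::rnorm(length(times), 0, noise_sd))
  aspiration_trace(times, noisy,
                   pressures = rep(protocol$step_pressure, length(times)),
                   rate = rate)
}

#' Write / read a cohort table
#'
#' Plain-CSV serialisation of the cohort schema (`embryo_id`, `species`,
#' `k0`, `k1`, `eta0`, `eta1`, `c1`, `c2`, `c3`, `blastocyst`).
#'
#' @param cohort data.frame from [sample_cohort()].
#' @param path file path.
#' @return `read_cohort` returns the data.frame with `blastocyst` logical.
#' @export
write_cohort <- function(cohort, path) {
  cols <- c("embryo_id", "species", "k0", "k1", "eta0", "eta1",
            "c1", "c2", "c3", "blastocyst")
  utils::write.csv(cohort[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$blastocyst <- as.logical(df$blastocyst)
  df
}

#' Write / read an aspiration trace CSV (`time_s`, `pressure_pa`, `depth_m`)
#'
#' @param trace an [aspiration_trace()].
#' @param path file path.
#' @param rate sampling rate recorded on read, Hz.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_s = trace$time_s,
                   pressure_pa = if (!is.null(trace$pressure_pa)) trace$pressure_pa else NA,
                   depth_m = trace$depth_m)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, rate = 75) {
  df <- utils::read.csv(path)
  aspiration_trace(df$time_s, df$depth_m, pressures = df$pressure_pa, rate = rate)
}
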