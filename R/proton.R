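# Analytic proton depth-dose curves and the Bragg-peak pull-back estimator
# of stopping power relative to water.

#' Construct a depth-dose curve
#'
#' @param depth_mm ascending depth-in-water grid in mm (>= 10 samples).
#' @param dose nonnegative dose values; normalised so the maximum is 1.
#' @return an object of class `depth_dose`.
#' @export
depth_dose <- function(depth_mm, dose) {
  depth_mm <- as.numeric(depth_mm); dose <- as.numeric(dose)
  if (length(depth_mm) != length(dose)) stop("depth and dose lengths differ")
  if (length(depth_mm) < 10L) stop("depth-dose curve needs >= 10 samples")
  if (any(diff(depth_mm) <= 0)) stop("depth grid must be strictly ascending")
  if (any(dose < 0)) stop("dose must be nonnegative")
  mx <- max(dose)
  if (mx <= 0) stop("all-zero dose curve")
  structure(list(depth_mm = depth_mm, dose = dose / mx), class = "depth_dose")
}

#' @export
print.depth_dose <- function(x, ...) {
  cat(sprintf("<depth_dose> %d samples, depth 0-%.1f mm, peak at %.1f mm\n",
              length(x$depth_mm), max(x$depth_mm),
              x$depth_mm[which.max(x$dose)]))
  invisible(x)
}

#' Construct a monoenergetic beam model
#'
#' @param range_cm distal 80% range in water, cm (> 0); the study beam has
#'   15.0 cm.
#' @param sigma_cm range-straggling width in cm; default the empirical
#'   power law `0.012 * range_cm^0.935` (a stated modelling choice).
#' @param p power-law exponent of the range-energy relation (> 1, default
#'   1.77).
#' @return an object of class `beam_model`.
#' @export
beam_model <- function(range_cm, sigma_cm = NULL, p = 1.77) {
  if (range_cm <= 0) stop("range must be positive")
  if (is.null(sigma_cm)) sigma_cm <- 0.012 * range_cm^0.935
  if (sigma_cm <= 0) stop("sigma must be positive")
  if (p <= 1) stop("power-law exponent must exceed 1")
  structure(list(range_cm = range_cm, sigma_cm = sigma_cm, p = p),
            class = "beam_model")
}

#' Analytic Bragg curve of a monoenergetic beam
#'
#' Depth dose modelled as the Gaussian-range-straggling convolution of the
#' power-law stopping curve `(R0 - z)^(1/p - 1)` (z < R0), normalised to
#' peak 1. R0 is calibrated internally so that the distal 80% depth of the
#' convolved curve equals the model's `range_cm`. The integrable
#' singularity at R0 is handled by exact per-cell averaging of the
#' unconvolved curve before discrete convolution. This is an analytic
#' stand-in for measured or Monte Carlo curves; only pull-back differences
#' of such curves are used downstream, so absolute shape fidelity beyond
#' the distal falloff is not required.
#'
#' @param b a `beam_model`.
#' @param grid_mm depth grid in mm; default 0.1 mm spacing over
#'   `[0, R + 5 sigma]`. Spacing must not exceed `sigma/2`.
#' @return a `depth_dose` curve.
#' @export
bragg_curve <- function(b, grid_mm = NULL) {
  stopifnot(inherits(b, "beam_model"))
  R_mm <- b$range_cm * 10
  sig_mm <- b$sigma_cm * 10
  if (is.null(grid_mm)) grid_mm <- seq(0, R_mm + 5 * sig_mm, by = 0.1)
  h <- diff(grid_mm)
  if (any(h > sig_mm / 2 + 1e-12))
    stop(sprintf("depth grid too coarse: spacing %.3g mm exceeds sigma/2 = %.3g mm",
                 max(h), sig_mm / 2))
  a <- 1 / b$p - 1                                  # exponent, in (-1, 0)
  R0 <- R_mm
  for (it in 1:6) {
    dose <- convolved_powerlaw(grid_mm, R0, a, sig_mm)
    d80 <- distal_cross(grid_mm, dose / max(dose), 0.8)
    if (abs(d80 - R_mm) < 1e-4) break
    R0 <- R0 + (R_mm - d80)
  }
  depth_dose(grid_mm, dose)
}

# Gaussian convolution of (R0 - z)^a on `grid` using exact cell averages of
# the singular integrand: int (R0-u)^a du = -(R0-u)^(a+1)/(a+1).
convolved_powerlaw <- function(grid, R0, a, sig) {
  h <- grid[2L] - grid[1L]
  edges <- c(grid - h / 2, grid[length(grid)] + h / 2)
  prim <- function(u) {
    w <- pmax(R0 - u, 0)
    -w^(a + 1) / (a + 1)
  }
  qbar <- (prim(edges[-1L]) - prim(edges[-length(edges)])) / h
  kr <- ceiling(4 * sig / h)
  kx <- (-kr:kr) * h
  kern <- exp(-kx^2 / (2 * sig^2))
  kern <- kern / sum(kern)
  n <- length(qbar)
  padded <- c(rep(qbar[1L], kr), qbar, rep(0, kr))   # entrance plateau, zero distal
  out <- stats::filter(padded, kern, method = "convolution", sides = 2L)
  as.numeric(out[(kr + 1L):(kr + n)])
}

#' Insert a slab of material into the beam path
#'
#' First-order slab model: a slab of physical thickness `thickness_cm` and
#' stopping power ratio `rsp` pulls the whole curve upstream by its
#' water-equivalent thickness `WET = thickness_cm * rsp`; the shape is
#' preserved (straggling growth inside the sample is neglected, which
#' cancels in the pull-back difference). The model has no orientation: a
#' 1-D slab is the same from any side.
#'
#' @param c a `depth_dose` curve (no slab).
#' @param thickness_cm slab physical thickness in cm (>= 0).
#' @param rsp stopping power relative to water (>= 0); `WET` must be
#'   smaller than the curve's range.
#' @return a `depth_dose` curve on the same depth grid.
#' @export
apply_slab <- function(c, thickness_cm, rsp) {
  stopifnot(inherits(c, "depth_dose"))
  if (thickness_cm < 0 || rsp < 0) stop("thickness and rsp must be >= 0")
  wet_mm <- thickness_cm * rsp * 10
  if (wet_mm >= max(c$depth_mm))
    stop("slab water-equivalent thickness exceeds the curve range")
  if (wet_mm == 0) return(c)
  dose <- stats::approx(c$depth_mm, c$dose, xout = c$depth_mm + wet_mm,
                        yleft = c$dose[1L], yright = 0)$y
  depth_dose(c$depth_mm, dose)
}

#' Distal range of a depth-dose curve
#'
#' Depth beyond the peak where the dose first falls to `level` times the
#' peak, located by linear interpolation between the bracketing samples —
#' the standard clinical range surrogate (d80 at the default level 0.8).
#'
#' @param c a `depth_dose` curve.
#' @param level fraction of the peak (0 < level <= 1; default 0.8).
#' @return depth in cm.
#' @export
distal_range <- function(c, level = 0.8) {
  stopifnot(inherits(c, "depth_dose"))
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  distal_cross(c$depth_mm, c$dose, level) / 10
}

distal_cross <- function(depth_mm, dose, level) {
  pk <- which.max(dose)
  thr <- dose[pk] * level
  if (level == 1) return(depth_mm[pk])
  below <- which(dose < thr & seq_along(dose) > pk)
  if (!length(below))
    stop(sprintf("no distal crossing of the %.0f%% level", level * 100))
  i <- below[1L]
  f <- (dose[i - 1L] - thr) / (dose[i - 1L] - dose[i])
  depth_mm[i - 1L] + f * (depth_mm[i] - depth_mm[i - 1L])
}

#' Stopping power relative to water from Bragg-peak pull-back
#'
#' The pull-back of the distal range when a sample intercepts the beam,
#' divided by the sample's physical thickness:
#' `rsp = (d80(reference) - d80(with_sample)) / thickness_cm`.
#'
#' @param reference `depth_dose` without the sample.
#' @param with_sample `depth_dose` with the sample in the beam.
#' @param thickness_cm sample thickness along the beam in cm (> 0).
#' @param level range-definition level (default 0.8, i.e. d80).
#' @return estimated relative stopping power. A negative pull-back beyond
#'   `-0.01` cm triggers a warning (a sample less dense than water is
#'   legitimate; the sign is preserved).
#' @export
estimate_rsp <- function(reference, with_sample, thickness_cm, level = 0.8) {
  if (thickness_cm <= 0) stop("thickness_cm must be > 0")
  pull_back <- distal_range(reference, level) - distal_range(with_sample, level)
  if (pull_back < -0.01)
    warning(sprintf("negative pull-back (%.3f cm): sample appears less stopping than empty beam",
                    pull_back))
  pull_back / thickness_cm
}

#' Add multiplicative measurement noise to a curve
#'
#' I.i.d. Gaussian multiplicative noise (chamber-reading jitter) with an
#' explicit seed; the result is renormalised to peak 1. The caller's RNG
#' state is left untouched.
#'
#' @param c a `depth_dose` curve.
#' @param relative_sd relative noise sd (>= 0).
#' @param seed integer seed (required).
#' @return a `depth_dose` curve.
#' @export
add_noise <- function(c, relative_sd, seed) {
  stopifnot(inherits(c, "depth_dose"))
  if (relative_sd < 0) stop("relative_sd must be >= 0")
  if (missing(seed) || is.null(seed)) stop("an explicit seed is required")
  if (relative_sd == 0) return(c)
  noisy <- with_seed(seed, c$dose * (1 + stats::rnorm(length(c$dose), 0, relative_sd)))
  noisy[noisy < 0] <- 0
  depth_dose(c$depth_mm, noisy)
}

# run code under a temporary RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Read / write depth-dose curves as 2-column CSV
#'
#' Files have a header `depth_mm,dose`.
#'
#' @param path CSV file.
#' @return for `read_depth_dose`, a `depth_dose` curve.
#' @export
read_depth_dose <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("depth_mm", "dose") %in% names(d)))
    stop("depth-dose CSV needs columns depth_mm, dose")
  depth_dose(d$depth_mm, d$dose)
}

#' @rdname read_depth_dose
#' @param c a `depth_dose` curve to write.
#' @export
write_depth_dose <- function(c, path) {
  stopifnot(inherits(c, "depth_dose"))
  utils::write.csv(data.frame(depth_mm = c$depth_mm, dose = c$dose),
                   path, row.names = FALSE)
  invisible(path)
}
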