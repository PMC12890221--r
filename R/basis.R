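#' Construct a distance-basis system for spatial interaction curves
#'
#' A spatial interaction curve (SIC) is represented as a linear combination
#' of `P` nonnegative basis functions on the distance interval
#' `[0, r_max]` (micrometres). Two families are supported: clamped cubic
#' B-splines on an open uniform knot sequence (the default, giving a
#' partition of unity on the support) and unnormalized Gaussian kernels
#' with equally spaced centers and a shared bandwidth equal to the center
#' spacing. All basis functions are identically zero beyond `r_max`, so
#' every SIC has compact support.
#'
#' `r_min` is a reporting cutoff, not a fitting restriction: models are fit
#' with all observed distances, but curves are conventionally summarized on
#' `[r_min, r_max]` because distances below one or two cell diameters are
#' dominated by crowding and segmentation artifacts.
#'
#' @param family `"bspline"` or `"gaussian"`.
#' @param P Number of basis functions (at least 4 for `bspline`, at least 2
#'   for `gaussian`).
#' @param r_max Upper end of the support, in micrometres.
#' @param r_min Minimum reporting radius, in micrometres (default 25).
#' @return An object of class `sic_basis`.
#' @examples
#' b <- sic_basis("bspline", P = 6, r_max = 150)
#' rowSums(basis_matrix(b, c(10, 75, 140)))  # partition of unity
#' @export
sic_basis <- function(family = c("bspline", "gaussian"), P = 6,
                      r_max = 150, r_min = 25) {
  family <- match.arg(family)
  if (!is.numeric(P) || length(P) != 1L || P != round(P)) {
    stop("`P` must be a single integer.", call. = FALSE)
  }
  P <- as.integer(P)
  min_p <- if (family == "bspline") 4L else 2L
  if (P < min_p) {
    stop(sprintf("`P` must be >= %d for the %s family.", min_p, family),
         call. = FALSE)
  }
  if (!is.numeric(r_max) || !is.numeric(r_min) || r_max <= r_min || r_min < 0) {
    stop("Require r_max > r_min >= 0.", call. = FALSE)
  }
  out <- list(family = family, P = P, r_max = as.numeric(r_max),
              r_min = as.numeric(r_min))
  if (family == "bspline") {
    # clamped cubic: P + 4 knots, P - 4 interior knots equally spaced
    inner <- if (P > 4L) seq(0, r_max, length.out = P - 2L)[-c(1L, P - 2L)] else numeric(0)
    out$knots <- c(rep(0, 4L), inner, rep(r_max, 4L))
  } else {
    out$centers <- seq(0, r_max, length.out = P)
    out$bandwidth <- r_max / (P - 1L)
  }
  structure(out, class = "sic_basis")
}

#' @export
print.sic_basis <- function(x, ...) {
  cat(sprintf("<sic_basis> %s, P = %d, support [0, %g] um, r_min = %g um\n",
              x$family, x$P, x$r_max, x$r_min))
  invisible(x)
}

#' Evaluate the basis functions at given distances
#'
#' @param basis A [sic_basis()] object.
#' @param s Numeric vector of nonnegative distances (micrometres).
#' @return A `length(s) x P` matrix of basis values; rows for `s > r_max`
#'   are zero.
#' @export
basis_matrix <- function(basis, s) {
  stopifnot(inherits(basis, "sic_basis"))
  s <- as.numeric(s)
  if (length(s) && (anyNA(s) || any(s < 0))) {
    stop("Distances must be nonnegative and non-missing.", call. = FALSE)
  }
  out <- matrix(0, nrow = length(s), ncol = basis$P)
  inside <- s <= basis$r_max
  if (!any(inside)) return(out)
  si <- s[inside]
  if (basis$family == "bspline") {
    # splineDesign is right-open at the last knot; evaluate the boundary
    # by its left limit (clamped basis: last function -> 1 at r_max)
    at_end <- si == basis$r_max
    vals <- matrix(0, length(si), basis$P)
    if (any(!at_end)) {
      vals[!at_end, ] <- splines::splineDesign(basis$knots, si[!at_end],
                                               ord = 4L)
    }
    if (any(at_end)) vals[at_end, basis$P] <- 1
    out[inside, ] <- vals
  } else {
    d <- outer(si, basis$centers, "-")
    out[inside, ] <- exp(-d^2 / (2 * basis$bandwidth^2))
  }
  out
}

#' Evaluate a spatial interaction curve on a distance grid
#'
#' Computes `SIC(s) = sum_p coef[p] * phi_p(s)`, the additive contribution
#' of one source cell at distance `s` to the log-intensity of the target
#' type. Positive values mean attraction, negative repulsion;
#' [intensity_multiplier()] converts values to density fold-changes.
#'
#' @param basis A [sic_basis()] object.
#' @param coef Numeric coefficient vector of length `basis$P`.
#' @param s Distances (micrometres) at which to evaluate.
#' @return Numeric vector of SIC values, zero beyond the basis support.
#' @export
eval_sic <- function(basis, coef, s) {
  stopifnot(inherits(basis, "sic_basis"))
  coef <- as.numeric(coef)
  if (length(coef) != basis$P) {
    stop(sprintf("`coef` must have length P = %d.", basis$P), call. = FALSE)
  }
  drop(basis_matrix(basis, s) %*% coef)
}

#' Convert a log-intensity SIC value to a density fold-change
#'
#' SIC values live on the log scale of the conditional intensity, so a
#' value `v` corresponds to an `exp(v)`-fold multiplicative change in the
#' expected local density of the target type (e.g. 0.2 is about a 22%
#' increase, -0.3 about a 26% decrease).
#'
#' @param sic_value Numeric vector of SIC values.
#' @return `exp(sic_value)`.
#' @export
intensity_multiplier <- function(sic_value) {
  stopifnot(is.numeric(sic_value), all(is.finite(sic_value)))
  exp(sic_value)
}

#' Default reporting grid for a basis system
#'
#' 1-um spacing on `[r_min, r_max]`.
#' @param basis A [sic_basis()] object.
#' @param by Grid spacing in micrometres.
#' @param from Optional lower end (defaults to `r_min`).
#' @return Numeric vector of distances.
#' @export
sic_grid <- function(basis, by = 1, from = NULL) {
  stopifnot(inherits(basis, "sic_basis"))
  if (is.null(from)) from <- basis$r_min
  seq(from, basis$r_max, by = by)
}

#' Coefficients of a smooth positive interaction bump
#'
#' Builds a coefficient vector whose SIC is a single nonnegative bump with
#' a given peak location and height — the ground-truth shape used by the
#' simulator and benchmarks. Coefficients are proportional to the basis
#' values at the peak (hence nonnegative), rescaled so the curve maximum
#' on a fine grid equals `height`.
#'
#' @param basis A [sic_basis()] object.
#' @param peak Peak location in micrometres.
#' @param height Peak SIC value (log-intensity units).
#' @return Numeric vector of length `basis$P`.
#' @export
sic_bump_coefficients <- function(basis, peak = 40, height = 0.8) {
  stopifnot(inherits(basis, "sic_basis"), peak >= 0, peak <= basis$r_max)
  w <- drop(basis_matrix(basis, peak))
  if (all(w == 0)) stop("Peak outside basis support.", call. = FALSE)
  grid <- seq(0, basis$r_max, length.out = 1000L)
  cur_max <- max(drop(basis_matrix(basis, grid) %*% w))
  w * (height / cur_max)
}

#' Serialize / restore a basis configuration
#'
#' @param basis A [sic_basis()] object.
#' @param path File path for the JSON configuration.
#' @return `write_basis()` returns `path` invisibly; `read_basis()` returns
#'   a reconstructed [sic_basis()].
#' @export
write_basis <- function(basis, path) {
  stopifnot(inherits(basis, "sic_basis"))
  cfg <- list(family = basis$family, P = basis$P,
              r_max = basis$r_max, r_min = basis$r_min)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  sic_basis(cfg$family, P = cfg$P, r_max = cfg$r_max, r_min = cfg$r_min)
}
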