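coef_block <- function(fit, source) {
  k <- match(source, fit$sources)
  if (is.na(k)) {
    stop(sprintf("Unknown source label '%s'.", source), call. = FALSE)
  }
  P <- fit$basis$P
  (k - 1L) * P + seq_len(P)
}

#' Posterior draws of a spatial interaction curve
#'
#' Reconstructs the SIC draw-by-draw on a distance grid for a unit at a
#' given hierarchy level: each posterior draw of the unit's coefficient
#' vector is expanded through the basis.
#'
#' @param fit A [fit_sic_hier()] or [fit_sic_flat()] object.
#' @param level `"cohort"`, `"patient"` or `"image"` (flat fits only have
#'   `"image"`).
#' @param unit Unit identifier at that level; may be omitted when there
#'   is exactly one.
#' @param source Source cell-type label (defaults to the only source).
#' @param grid Distance grid in micrometres (default: the basis
#'   reporting grid, [sic_grid()]).
#' @return A draws x grid matrix of SIC values; the grid is attached as
#'   attribute `"grid"`.
#' @export
sic_curves <- function(fit, level = c("cohort", "patient", "image"),
                       unit = NULL, source = NULL, grid = NULL) {
  level <- match.arg(level)
  if (is.null(source)) {
    if (length(fit$sources) > 1L) {
      stop("Multiple sources present; specify `source`.", call. = FALSE)
    }
    source <- fit$sources[1L]
  }
  if (is.null(grid)) grid <- sic_grid(fit$basis)
  arr <- switch(level,
    cohort = fit$psi_draws, patient = fit$gamma_draws,
    image = fit$delta_draws)
  if (is.null(arr)) {
    stop(sprintf("Fit has no %s level.", level), call. = FALSE)
  }
  units <- dimnames(arr)[[2]]
  if (is.null(unit)) {
    if (length(units) > 1L) {
      stop(sprintf("Multiple %ss present; specify `unit`.", level),
           call. = FALSE)
    }
    unit <- units[1L]
  }
  u <- match(unit, units)
  if (is.na(u)) {
    stop(sprintf("Unknown %s '%s'.", level, unit), call. = FALSE)
  }
  co <- arr[, u, coef_block(fit, source), drop = FALSE]
  co <- matrix(co, nrow = dim(arr)[1])
  B <- basis_matrix(fit$basis, grid)
  out <- co %*% t(B)
  attr(out, "grid") <- grid
  out
}

#' Simultaneous credible band from functional draws
#'
#' Builds a band with joint posterior coverage over the whole grid from
#' the max-standardized-deviation quantile: per grid point compute the
#' posterior mean and sd, take `c* = ` the `level` quantile over draws of
#' `max_s |f(s) - mean(s)| / sd(s)`, and set the band to
#' `mean +/- c* sd`. Grid points with zero posterior sd get a zero-width
#' band. Unlike pointwise intervals, exiting this band anywhere is a
#' single joint event at rate `1 - level`.
#'
#' @param curve_draws A draws x grid matrix (e.g. from [sic_curves()]).
#' @param level Joint coverage level in (0, 1), default 0.95.
#' @param grid Optional distance grid (defaults to the `"grid"`
#'   attribute of `curve_draws`, else column index).
#' @return A tibble with columns `distance`, `mean`, `lower`, `upper`;
#'   the multiplier is attached as attribute `"c_mult"` and the level as
#'   `"level"`.
#' @export
simultaneous_band <- function(curve_draws, level = 0.95, grid = NULL) {
  stopifnot(is.matrix(curve_draws), level > 0, level < 1)
  if (nrow(curve_draws) < 2L) {
    stop("At least 2 draws are required for a band.", call. = FALSE)
  }
  if (is.null(grid)) {
    grid <- attr(curve_draws, "grid") %||% seq_len(ncol(curve_draws))
  }
  m <- colMeans(curve_draws)
  sd <- apply(curve_draws, 2, stats::sd)
  pos <- sd > 0
  if (any(pos)) {
    z <- abs(sweep(curve_draws[, pos, drop = FALSE], 2, m[pos])) /
      rep(sd[pos], each = nrow(curve_draws))
    cmax <- apply(z, 1, max)
    cstar <- unname(stats::quantile(cmax, level, type = 7))
  } else {
    cstar <- 0
  }
  out <- tibble::tibble(distance = grid, mean = m,
                        lower = m - cstar * sd, upper = m + cstar * sd)
  attr(out, "c_mult") <- cstar
  attr(out, "level") <- level
  out
}

#' Tidy simultaneous band for a fitted interaction curve
#'
#' Convenience wrapper: [sic_curves()] then [simultaneous_band()], with
#' identifying columns added.
#'
#' @inheritParams sic_curves
#' @param level_tag Hierarchy level (`"cohort"`, `"patient"`, `"image"`).
#' @param prob Joint coverage level.
#' @return A tibble with `level`, `unit`, `source`, `target`, `distance`,
#'   `mean`, `lower`, `upper`.
#' @export
sic_band <- function(fit, level_tag = "cohort", unit = NULL,
                     source = NULL, grid = NULL, prob = 0.95) {
  cd <- sic_curves(fit, level = level_tag, unit = unit, source = source,
                   grid = grid)
  band <- simultaneous_band(cd, level = prob)
  units <- switch(level_tag, cohort = fit$cohorts,
                  patient = fit$patients, image = fit$images)
  src <- source %||% fit$sources[1L]
  out <- dplyr::bind_cols(
    tibble::tibble(level = level_tag,
                   unit = unit %||% units[1L],
                   source = src, target = fit$target)[rep(1, nrow(band)), ],
    band)
  attr(out, "c_mult") <- attr(band, "c_mult")
  attr(out, "level") <- attr(band, "level")
  out
}

#' Detection call from a credible band
#'
#' An interaction is detected on `[a, b]` when the simultaneous band
#' excludes zero at any grid point in the interval: lower envelope above
#' zero (attraction) or upper envelope below zero (repulsion).
#'
#' @param band A band tibble with `distance`, `lower`, `upper` (from
#'   [simultaneous_band()] or [sic_band()]).
#' @param interval Length-2 numeric `[a, b]` in micrometres.
#' @return A list with `detected` (flag), `sign` (`"positive"`,
#'   `"negative"`, `"both"` or `"none"`), and `where`: a tibble of grid
#'   points where zero is excluded with the local sign.
#' @export
detect_interaction <- function(band, interval) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  sel <- band$distance >= interval[1] & band$distance <= interval[2]
  if (!any(sel)) {
    stop("Interval does not intersect the band grid.", call. = FALSE)
  }
  b <- band[sel, ]
  pos <- b$lower > 0
  neg <- b$upper < 0
  sign <- if (any(pos) && any(neg)) "both" else if (any(pos)) "positive"
    else if (any(neg)) "negative" else "none"
  list(detected = any(pos) || any(neg), sign = sign,
       where = tibble::tibble(distance = b$distance[pos | neg],
                              sign = ifelse(pos[pos | neg], "positive",
                                            "negative")))
}

#' Prioritization summaries of an interaction curve
#'
#' Measures used to rank source-target pairs in exploratory screens:
#' peak location and signed magnitude of the posterior mean curve on the
#' interval; persistence, the fraction of the interval where the
#' simultaneous band excludes zero; and overall strength, the
#' trapezoidal integral of `|mean|` over the zero-excluding region.
#'
#' @param band A band tibble (with `distance`, `mean`, `lower`, `upper`).
#' @param interval Length-2 numeric interval `I` in micrometres.
#' @return A one-row tibble: `peak_distance`, `peak_value`,
#'   `persistence`, `strength`.
#' @export
sic_summary_measures <- function(band, interval) {
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  sel <- band$distance >= interval[1] & band$distance <= interval[2]
  if (!any(sel)) stop("Empty interval on the band grid.", call. = FALSE)
  b <- band[sel, ]
  i_pk <- which.max(abs(b$mean))
  excl <- b$lower > 0 | b$upper < 0
  # trapezoid weights restricted to the excluded-zero region
  strength <- 0
  if (any(excl)) {
    d <- b$distance; f <- abs(b$mean) * excl
    strength <- sum(diff(d) * (f[-1] + f[-length(f)]) / 2)
  }
  persistence <- if (length(excl) > 1) {
    d <- b$distance
    sum(diff(d) * (excl[-1] + excl[-length(excl)]) / 2) /
      (max(d) - min(d))
  } else as.numeric(excl)
  tibble::tibble(peak_distance = b$distance[i_pk],
                 peak_value = b$mean[i_pk],
                 persistence = persistence,
                 strength = strength)
}

#' Heterogeneity decomposition via median absolute deviations
#'
#' Quantifies how much interaction curves vary across the hierarchy:
#' between-patient MAD is the median over patients and grid points of
#' `|posterior-mean patient SIC - posterior-mean cohort SIC|`;
#' within-patient MAD is the median over images and grid points of
#' `|posterior-mean image SIC - posterior-mean patient SIC|`. Posterior
#' means (not draws) are used for the deviations.
#'
#' @param fit A [fit_sic_hier()] object.
#' @param grid Distance grid (default [sic_grid()] of the fit's basis).
#' @return A tibble with one row per source: `source`, `target`,
#'   `between_patient_mad`, `within_patient_mad` (`NA` when fewer than 2
#'   patients / no patient has 2 images).
#' @export
sic_heterogeneity <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "sic_fit"))
  if (is.null(grid)) grid <- sic_grid(fit$basis)
  B <- basis_matrix(fit$basis, grid)
  out <- lapply(fit$sources, function(src) {
    blk <- coef_block(fit, src)
    psi_m <- apply(fit$psi_draws[, , blk, drop = FALSE], c(2, 3), mean)
    gam_m <- apply(fit$gamma_draws[, , blk, drop = FALSE], c(2, 3), mean)
    del_m <- apply(fit$delta_draws[, , blk, drop = FALSE], c(2, 3), mean)
    coh_cur <- psi_m %*% t(B)               # cohorts x grid
    pat_cur <- gam_m %*% t(B)               # patients x grid
    img_cur <- del_m %*% t(B)               # images x grid
    gof <- fit$gofn; nof <- fit$nofm
    between <- if (length(fit$patients) >= 2) {
      stats::median(abs(pat_cur - coh_cur[gof, , drop = FALSE]))
    } else NA_real_
    within <- if (any(duplicated(nof))) {
      stats::median(abs(img_cur - pat_cur[nof, , drop = FALSE]))
    } else NA_real_
    tibble::tibble(source = src, target = fit$target,
                   between_patient_mad = between,
                   within_patient_mad = within)
  })
  dplyr::bind_rows(out)
}

#' Export bands for several units as one tidy table
#'
#' @param fit A fitted model object.
#' @param level_tag Hierarchy level to summarize.
#' @param source Source label (default: all sources).
#' @param grid,prob As in [sic_band()].
#' @return A tibble of stacked [sic_band()] results over all units at
#'   the level (and all requested sources).
#' @export
sic_band_all <- function(fit, level_tag = "image", source = NULL,
                         grid = NULL, prob = 0.95) {
  units <- switch(level_tag, cohort = fit$cohorts,
                  patient = fit$patients, image = fit$images)
  sources <- source %||% fit$sources
  purrr::map_dfr(sources, function(src) {
    purrr::map_dfr(units, function(u) {
      sic_band(fit, level_tag, unit = u, source = src, grid = grid,
               prob = prob)
    })
  })
}
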