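#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior coefficient summaries of a hierarchical fit
#'
#' One row per interaction coefficient (level x unit x source x basis
#' index) and per variance component, with posterior mean, sd and
#' equal-tailed 95% interval.
#'
#' @param x A [fit_sic_hier()] object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `level`, `unit`, `source`,
#'   `basis_index`, `estimate`, `std.error`, `conf.low`, `conf.high`.
#' @export
tidy.sic_fit <- function(x, ...) {
  P <- x$basis$P
  level_rows <- function(arr, level, units) {
    purrr::map_dfr(seq_along(units), function(u) {
      purrr::map_dfr(seq_along(x$sources), function(k) {
        blk <- (k - 1L) * P + seq_len(P)
        purrr::map_dfr(seq_len(P), function(p) {
          v <- arr[, u, blk[p]]
          tibble::tibble(
            term = sprintf("%s[%s,%s,%d]", level, units[u],
                           x$sources[k], p),
            level = level, unit = units[u], source = x$sources[k],
            basis_index = p, estimate = mean(v),
            std.error = stats::sd(v),
            conf.low = unname(stats::quantile(v, 0.025)),
            conf.high = unname(stats::quantile(v, 0.975)))
        })
      })
    })
  }
  sig <- purrr::map_dfr(colnames(x$sigma_draws), function(nm) {
    v <- x$sigma_draws[, nm]
    tibble::tibble(term = nm, level = "hyper", unit = NA_character_,
                   source = NA_character_, basis_index = NA_integer_,
                   estimate = mean(v), std.error = stats::sd(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)))
  })
  dplyr::bind_rows(
    level_rows(x$psi_draws, "cohort", x$cohorts),
    level_rows(x$gamma_draws, "patient", x$patients),
    level_rows(x$delta_draws, "image", x$images),
    sig)
}

#' One-row fit summary with sampler diagnostics
#'
#' @param x A [fit_sic_hier()] or [fit_sic_flat()] object.
#' @param ... Unused.
#' @return A one-row tibble: model kind, hierarchy sizes, draw count,
#'   acceptance rate, divergences, and (hierarchical fits) max split-Rhat
#'   and min effective sample size over the interaction coefficients.
#' @export
glance.sic_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_images = length(x$images),
    n_patients = length(x$patients),
    n_cohorts = length(x$cohorts),
    n_draws = nrow(x$beta0_draws),
    accept_rate = x$diagnostics$accept_rate,
    divergences = x$diagnostics$divergences,
    max_rhat = x$diagnostics$max_rhat,
    min_ess = x$diagnostics$min_ess)
}

#' @rdname glance.sic_fit
#' @export
glance.sic_flat_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_images = length(x$images),
    n_patients = NA_integer_,
    n_cohorts = NA_integer_,
    n_draws = nrow(x$beta0_draws),
    accept_rate = x$diagnostics$accept_rate,
    divergences = x$diagnostics$divergences,
    max_rhat = NA_real_,
    min_ess = NA_real_)
}

#' Export posterior draws and diagnostics to disk
#'
#' Writes the interaction-coefficient and variance-component draws as a
#' long columnar CSV (one row per draw x parameter: `draw`, `level`,
#' `unit`, `source`, `basis_index`, `value`) and the sampler
#' diagnostics as a JSON sidecar.
#'
#' @param fit A [fit_sic_hier()] object.
#' @param draws_path CSV path for the draws table.
#' @param diagnostics_path Optional JSON path for the diagnostics.
#' @return `draws_path`, invisibly.
#' @export
write_sic_fit <- function(fit, draws_path, diagnostics_path = NULL) {
  stopifnot(inherits(fit, "sic_fit"))
  P <- fit$basis$P
  long <- function(arr, level, units) {
    purrr::map_dfr(seq_along(units), function(u) {
      purrr::map_dfr(seq_along(fit$sources), function(k) {
        blk <- (k - 1L) * P + seq_len(P)
        purrr::map_dfr(seq_len(P), function(p) {
          tibble::tibble(draw = seq_len(dim(arr)[1]), level = level,
                         unit = units[u], source = fit$sources[k],
                         basis_index = p, value = arr[, u, blk[p]])
        })
      })
    })
  }
  sig <- purrr::map_dfr(colnames(fit$sigma_draws), function(nm) {
    tibble::tibble(draw = seq_len(nrow(fit$sigma_draws)), level = "hyper",
                   unit = nm, source = NA_character_,
                   basis_index = NA_integer_, value = fit$sigma_draws[, nm])
  })
  out <- dplyr::bind_rows(
    long(fit$psi_draws, "cohort", fit$cohorts),
    long(fit$gamma_draws, "patient", fit$patients),
    long(fit$delta_draws, "image", fit$images), sig)
  readr::write_csv(out, draws_path, progress = FALSE)
  if (!is.null(diagnostics_path)) {
    jsonlite::write_json(fit$diagnostics, diagnostics_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(draws_path)
}

#' @rdname tidy.sic_fit
#' @export
tidy.sic_flat_fit <- function(x, ...) {
  P <- x$basis$P
  purrr::map_dfr(seq_along(x$images), function(u) {
    purrr::map_dfr(seq_along(x$sources), function(k) {
      blk <- (k - 1L) * P + seq_len(P)
      purrr::map_dfr(seq_len(P), function(p) {
        v <- x$delta_draws[, u, blk[p]]
        tibble::tibble(
          term = sprintf("image[%s,%s,%d]", x$images[u], x$sources[k], p),
          level = "image", unit = x$images[u], source = x$sources[k],
          basis_index = p, estimate = mean(v), std.error = stats::sd(v),
          conf.low = unname(stats::quantile(v, 0.025)),
          conf.high = unname(stats::quantile(v, 0.975)))
      })
    })
  })
}
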