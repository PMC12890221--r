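boundary_distance <- function(x, y, window) {
  pmin(x - window$x_min, window$x_max - x,
       y - window$y_min, window$y_max - y)
}

# numeric cores, shared by the exported estimators and the envelope
# simulation loop (which calls them thousands of times)

gcross_core <- function(fx, fy, tx, ty, r, window, b = NULL) {
  if (is.null(b)) b <- boundary_distance(fx, fy, window)
  if (!length(tx)) return(rep(0, length(r)))
  d2 <- outer(fx, tx, "-")^2 + outer(fy, ty, "-")^2
  nn <- sqrt(d2[cbind(seq_along(fx),
                      max.col(-d2, ties.method = "first"))])
  eligible <- outer(b, r, ">=")
  denom <- colSums(eligible)
  est <- colSums(outer(nn, r, "<=") & eligible) / denom
  est[denom == 0] <- NA_real_
  est
}

kcross_core <- function(fx, fy, tx, ty, r, window) {
  a <- window$x_max - window$x_min
  bb <- window$y_max - window$y_min
  area <- a * bb
  dx <- abs(outer(fx, tx, "-"))
  dy <- abs(outer(fy, ty, "-"))
  d <- sqrt(dx^2 + dy^2)
  w <- area / ((a - dx) * (bb - dy))
  o <- order(d)
  cw <- cumsum(w[o])
  idx <- findInterval(r, d[o])
  k <- ifelse(idx == 0, 0, cw[pmax(idx, 1)]) /
    ((length(fx) / area) * (length(tx) / area)) / area
  sqrt(k / pi)
}

#' Border-corrected G-cross estimate
#'
#' Empirical distribution, over cells of type `from`, of the distance to
#' the nearest cell of type `to`, with the reduced-sample (border)
#' correction: at radius `r` only from-cells at least `r` from the
#' window edge enter the estimate. With zero to-cells the curve is
#' identically 0.
#'
#' @param cells A cell tibble (`x`, `y`, `cell_type`) for one image, or
#'   a [sic_study()] restricted to one image.
#' @param from,to Cell-type labels (nearest-neighbour distances run from
#'   `from`-cells to `to`-cells).
#' @param r Radius grid in micrometres.
#' @param window One-row window data frame.
#' @return A tibble with `r`, `est` (the corrected estimate, `NA` where
#'   no from-cell is eligible) and `theo`, the Poisson expectation
#'   `1 - exp(-lambda_to * pi * r^2)`.
#' @export
gcross_estimate <- function(cells, from, to, r, window) {
  if (inherits(cells, "sic_study")) cells <- cells$cells
  fp <- cells[cells$cell_type == from, ]
  tp <- cells[cells$cell_type == to, ]
  if (nrow(fp) == 0L) stop("No cells of the `from` type.", call. = FALSE)
  area <- window_area(window)
  theo <- 1 - exp(-nrow(tp) / area * pi * r^2)
  tibble::tibble(r = r,
                 est = gcross_core(fp$x, fp$y, tp$x, tp$y, r, window),
                 theo = theo)
}

#' Translation-corrected K-cross estimate on the L scale
#'
#' Cumulative cross-type pair counts
#' `K(r) = (1 / (lambda_from lambda_to |W|)) sum_(i,j) w_ij 1[d_ij <= r]`
#' with translation edge weights
#' `w_ij = |W| / ((a - |dx|)(b - |dy|))`, reported as
#' `L(r) = sqrt(K(r) / pi)` so that complete spatial randomness gives
#' `L(r) = r` on average.
#'
#' @inheritParams gcross_estimate
#' @return A tibble with `r`, `est` (L-scale) and `theo = r`.
#' @export
kcross_estimate <- function(cells, from, to, r, window) {
  if (inherits(cells, "sic_study")) cells <- cells$cells
  fp <- cells[cells$cell_type == from, ]
  tp <- cells[cells$cell_type == to, ]
  if (nrow(fp) == 0L || nrow(tp) == 0L) {
    stop("Both types must be present for K-cross.", call. = FALSE)
  }
  tibble::tibble(r = r,
                 est = kcross_core(fp$x, fp$y, tp$x, tp$y, r, window),
                 theo = r)
}

#' Global CSR envelope test for cross-type summaries
#'
#' Simulates `n_sim` patterns under complete spatial randomness of the
#' `to` type (to-cells redrawn uniformly at their observed count,
#' from-cells held fixed) and recomputes the chosen summary for each.
#' Inference uses the extreme-rank global envelope: every curve
#' (observed and simulated) gets a depth — its most extreme pointwise
#' rank, from below or above, across the whole `r` range — and the
#' observed pattern is rejected when its depth falls in the `alpha`
#' most extreme fraction of all `n_sim + 1` exchangeable curves. The
#' reported envelopes are the pointwise extremes of the retained
#' (non-extreme) curves, so rejection corresponds to the observed curve
#' exiting the global envelope somewhere; ties are handled
#' conservatively.
#'
#' @inheritParams gcross_estimate
#' @param statistic `"gcross"` or `"kcross"`.
#' @param n_sim Number of CSR simulations (>= 19; default 99).
#' @param alpha Global significance level (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `sic_envelope`: `r`, `observed`, `theo`,
#'   `lower`, `upper`, `rejected`, `p_value`, `untestable`, `n_sim`,
#'   `statistic`.
#' @export
envelope_test <- function(cells, from, to, window,
                          statistic = c("gcross", "kcross"),
                          r = seq(0, 75, by = 1.5), n_sim = 99,
                          alpha = 0.05, seed = NULL) {
  statistic <- match.arg(statistic)
  if (inherits(cells, "sic_study")) cells <- cells$cells
  stopifnot(n_sim >= 19)
  n_from <- sum(cells$cell_type == from)
  n_to <- sum(cells$cell_type == to)
  if (n_from < 1L || n_to < 1L) {
    return(structure(list(r = r, observed = NULL, theo = NULL,
                          lower = NULL, upper = NULL, rejected = NA,
                          p_value = NA_real_, untestable = TRUE,
                          n_sim = n_sim, statistic = statistic),
                     class = "sic_envelope"))
  }
  est_fn <- if (statistic == "gcross") gcross_estimate else kcross_estimate
  obs <- est_fn(cells, from, to, r, window)
  fp <- cells[cells$cell_type == from, c("x", "y")]
  bdist <- boundary_distance(fp$x, fp$y, window)
  sims <- withr::with_seed(seed %||% sample.int(1e6, 1), {
    vapply(seq_len(n_sim), function(s) {
      tx <- stats::runif(n_to, window$x_min, window$x_max)
      ty <- stats::runif(n_to, window$y_min, window$y_max)
      if (statistic == "gcross") {
        gcross_core(fp$x, fp$y, tx, ty, r, window, b = bdist)
      } else {
        kcross_core(fp$x, fp$y, tx, ty, r, window)
      }
    }, numeric(length(r)))
  })
  curves <- cbind(obs$est, sims)           # (r) x (n_sim + 1), obs first
  usable <- apply(is.finite(curves), 1, all)
  if (!any(usable)) {
    return(structure(list(r = r, observed = obs$est, theo = obs$theo,
                          lower = rep(NA_real_, length(r)),
                          upper = rep(NA_real_, length(r)),
                          rejected = NA, p_value = NA_real_,
                          untestable = TRUE, n_sim = n_sim,
                          statistic = statistic),
                     class = "sic_envelope"))
  }
  cu <- curves[usable, , drop = FALSE]
  n_tot <- n_sim + 1L
  # two-sided pointwise mid-ranks, then the extreme-rank-length (ERL)
  # ordering: curves compared lexicographically on their sorted rank
  # vectors, which breaks the massive ties of the raw extreme rank
  R <- matrix(0, n_tot, nrow(cu))
  for (i in seq_len(nrow(cu))) {
    v <- cu[i, ]
    rl <- rank(v, ties.method = "average")
    R[, i] <- pmin(rl, n_tot + 1 - rl)
  }
  S <- t(apply(R, 1, sort))                # each row ascending
  lex_leq <- function(a, b) {
    d <- a - b
    nz <- which(d != 0)
    if (!length(nz)) TRUE else d[nz[1]] < 0
  }
  more_extreme <- vapply(seq_len(n_tot), function(j) {
    lex_leq(S[j, ], S[1, ])
  }, logical(1))
  p_value <- mean(more_extreme)
  rejected <- p_value <= alpha
  # envelope of the retained curves at the global level
  n_drop <- floor(alpha * n_tot)
  ord <- do.call(order, as.data.frame(S))  # most extreme first
  keep <- ord[-seq_len(n_drop)]
  if (length(keep) < 2L) keep <- seq_len(n_tot)
  lower <- rep(NA_real_, length(r)); upper <- rep(NA_real_, length(r))
  lower[usable] <- apply(cu[, keep, drop = FALSE], 1, min)
  upper[usable] <- apply(cu[, keep, drop = FALSE], 1, max)
  structure(list(r = r, observed = obs$est, theo = obs$theo,
                 lower = lower, upper = upper, rejected = rejected,
                 p_value = p_value, untestable = FALSE, n_sim = n_sim,
                 statistic = statistic), class = "sic_envelope")
}

#' @export
print.sic_envelope <- function(x, ...) {
  if (isTRUE(x$untestable)) {
    cat("<sic_envelope> untestable (degenerate counts)\n")
  } else {
    cat(sprintf("<sic_envelope> %s, n_sim = %d, rejected = %s\n",
                x$statistic, x$n_sim, x$rejected))
  }
  invisible(x)
}

#' Score one replicate against simulation ground truth
#'
#' Computes the detection / coverage / type-I flags used by the
#' benchmark. For a credible band, detection uses
#' [detect_interaction()] and coverage asks whether the band contains
#' the true curve at every grid point of the interval; for an envelope
#' test, detection is the rejection flag and coverage is undefined.
#'
#' @param x A band tibble (with `distance`, `lower`, `upper`) or a
#'   [envelope_test()] result.
#' @param truth_fn Function mapping distances to the true SIC (use a
#'   zero function for null replicates), or a numeric vector aligned
#'   with the band grid.
#' @param interval Length-2 scoring interval in micrometres.
#' @param null_truth Logical: is this a null replicate (true curve
#'   identically zero on the interval)?
#' @return A one-row tibble: `detected`, `covered`, `type1_flag`.
#' @export
score_replicate <- function(x, truth_fn, interval, null_truth = FALSE) {
  if (inherits(x, "sic_envelope")) {
    det <- isTRUE(x$rejected)
    cov <- NA
  } else {
    sel <- x$distance >= interval[1] & x$distance <= interval[2]
    b <- x[sel, ]
    tv <- if (is.function(truth_fn)) truth_fn(b$distance) else
      truth_fn[sel]
    det <- detect_interaction(x, interval)$detected
    cov <- all(tv >= b$lower & tv <= b$upper)
  }
  tibble::tibble(detected = det, covered = cov,
                 type1_flag = null_truth && det)
}

# run all requested methods on one simulated study, image-level scoring
benchmark_one_study <- function(sim, methods, interval, mcmc, seed) {
  study <- sim$study
  cfg <- sim$config
  basis <- cfg$basis
  grid <- seq(interval[1], interval[2], by = 1)
  is_null <- cfg$null_interaction
  truth_fun <- function(img) {
    co <- sim$truth$delta[img, ]
    function(s) eval_sic(basis, co, s)
  }
  out <- list()
  need_fit <- any(c("sic_hier", "sic_flat") %in% methods)
  if (need_fit) {
    dat <- build_sic_data(study, cfg$target_label, cfg$source_label,
                          basis, seed = derive_seed(seed, 91L))
  }
  score_fit <- function(fit, method) {
    sc <- purrr::map_dfr(fit$images, function(img) {
      band <- sic_band(fit, "image", unit = img, grid = grid)
      score_replicate(band, truth_fun(img), interval,
                      null_truth = is_null)
    })
    tibble::tibble(method = method,
                   power = mean(sc$detected),
                   coverage = mean(sc$covered),
                   type1 = if (is_null) mean(sc$detected) else NA_real_)
  }
  if ("sic_hier" %in% methods) {
    fit <- fit_sic_hier(dat, study$hierarchy,
                        chains = mcmc$chains, warmup = mcmc$warmup,
                        draws = mcmc$draws,
                        seed = derive_seed(seed, 7L))
    out$sic_hier <- score_fit(fit, "sic_hier")
  }
  if ("sic_flat" %in% methods) {
    fit <- fit_sic_flat(dat, chains = mcmc$chains, warmup = mcmc$warmup,
                        draws = mcmc$draws,
                        seed = derive_seed(seed, 11L))
    out$sic_flat <- score_fit(fit, "sic_flat")
  }
  for (stat in intersect(methods, c("gcross", "kcross"))) {
    flags <- purrr::map_lgl(seq_len(nrow(study$hierarchy)), function(i) {
      img <- study$hierarchy$image_id[i]
      win <- study$windows[study$windows$image_id == img, ]
      env <- envelope_test(
        dplyr::filter(study$cells, .data$image_id == img),
        from = cfg$target_label, to = cfg$source_label, window = win,
        statistic = stat, r = seq(interval[1], interval[2], by = 1.5),
        seed = derive_seed(seed, 13L * i + match(stat, c("gcross", "kcross"))))
      isTRUE(env$rejected)
    })
    out[[stat]] <- tibble::tibble(
      method = stat, power = mean(flags), coverage = NA_real_,
      type1 = if (is_null) mean(flags) else NA_real_)
  }
  dplyr::bind_rows(out)
}

#' Benchmark detection power, coverage and type-I error across methods
#'
#' For each condition (source density x target density x images per
#' patient) and replicate, simulates one study with the known bump
#' interaction and one matched null study, runs the requested methods,
#' scores every image (detection = band or envelope excludes zero
#' anywhere on the interval), and aggregates per-replicate rates to
#' condition medians. Fully seeded: each (condition, replicate) pair
#' derives its own seeds, so results are invariant to execution order
#' and individual replicates are resumable.
#'
#' @param conditions Tibble with columns `source_count`, `target_count`,
#'   `images_per_patient` (one row per condition).
#' @param replicates Replicates per condition.
#' @param methods Subset of `c("sic_hier", "sic_flat", "gcross",
#'   "kcross")`.
#' @param seed Master integer seed.
#' @param n_patients Patients per simulated study.
#' @param interval Scoring interval in micrometres (default `c(0, 75)`).
#' @param mcmc List with `chains`, `warmup`, `draws` for the model fits.
#' @param scenarios Which studies to simulate per replicate: `"alt"`
#'   (known bump interaction), `"null"` (zero interaction), or both
#'   (default). Power/coverage come from alternative studies, type-I
#'   error from null studies.
#' @param config_fn Optional function(condition row) returning a
#'   [sic_sim_config()]; overrides the default generator settings.
#' @return A list of class `sic_benchmark`: `summary` (medians per
#'   condition x method) and `replicates` (per-replicate rates).
#' @export
run_benchmark <- function(conditions, replicates = 10,
                          methods = c("sic_hier", "gcross"),
                          seed = 1, n_patients = 10,
                          interval = c(0, 75),
                          mcmc = list(chains = 2, warmup = 400,
                                      draws = 400),
                          scenarios = c("alt", "null"),
                          config_fn = NULL) {
  methods <- match.arg(methods,
                       c("sic_hier", "sic_flat", "gcross", "kcross"),
                       several.ok = TRUE)
  conditions <- tibble::as_tibble(conditions)
  reps <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (rep_i in seq_len(replicates)) {
      base_seed <- derive_seed(seed, ci * 100003L + rep_i)
      make_cfg <- function(null) {
        if (!is.null(config_fn)) {
          cfg <- config_fn(cond)
          cfg$null_interaction <- null
          cfg
        } else {
          sic_sim_config(
            n_patients = n_patients,
            images_per_patient = cond$images_per_patient,
            source_count = cond$source_count,
            target_count = cond$target_count,
            null_interaction = null)
        }
      }
      scenarios <- match.arg(scenarios, c("alt", "null"),
                             several.ok = TRUE)
      res <- purrr::map_dfr(c(alt = FALSE, null = TRUE)[scenarios],
                            function(null) {
        sim <- simulate_study(make_cfg(null),
                              seed = derive_seed(base_seed, 1L + null))
        sc <- benchmark_one_study(sim, methods, interval,
                                  mcmc = mcmc,
                                  seed = derive_seed(base_seed,
                                                     3L + null))
        sc$null <- null
        sc
      })
      res$condition <- ci
      res$replicate <- rep_i
      reps[[length(reps) + 1L]] <- res
    }
  }
  reps <- dplyr::bind_rows(reps)
  reps <- dplyr::bind_cols(
    reps, conditions[reps$condition, , drop = FALSE])
  alt <- dplyr::filter(reps, !.data$null)
  nul <- dplyr::filter(reps, .data$null)
  summ <- dplyr::full_join(
    dplyr::summarise(
      dplyr::group_by(alt, .data$condition, .data$method),
      median_power = stats::median(.data$power),
      median_coverage = stats::median(.data$coverage),
      .groups = "drop"),
    dplyr::summarise(
      dplyr::group_by(nul, .data$condition, .data$method),
      median_type1 = stats::median(.data$type1),
      .groups = "drop"),
    by = c("condition", "method"))
  summ <- dplyr::bind_cols(summ,
                           conditions[summ$condition, , drop = FALSE])
  structure(list(summary = summ, replicates = reps),
            class = "sic_benchmark")
}

#' @export
print.sic_benchmark <- function(x, ...) {
  cat("<sic_benchmark>\n")
  print(x$summary)
  invisible(x)
}
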