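#' Prior configuration for the hierarchical logistic model
#'
#' Weakly informative defaults on the log-intensity scale, where
#' interaction-curve values rarely exceed about 2 in magnitude:
#' Normal(0, 5^2) on intercepts and covariate coefficients,
#' half-Normal(0, 1) on the three hierarchy standard deviations, and
#' Normal(0, 5^2) on per-image coefficients in the flat (unpooled)
#' model, so the ablation differs from the hierarchical model only in
#' replacing the learned pooling scales by a fixed weak one.
#'
#' @param scale_intercept Prior sd for per-image intercepts `beta0`.
#' @param scale_covariate Prior sd for covariate coefficients `beta`.
#' @param scale_sigma Half-Normal scale for `sigma_cohort`,
#'   `sigma_patient`, `sigma_image`.
#' @param scale_flat Prior sd for image coefficients in [fit_sic_flat()].
#' @return A list of class `sic_priors`.
#' @export
sic_priors <- function(scale_intercept = 5, scale_covariate = 5,
                       scale_sigma = 1, scale_flat = 5) {
  stopifnot(scale_intercept > 0, scale_covariate > 0, scale_sigma > 0,
            scale_flat > 0)
  structure(list(scale_intercept = scale_intercept,
                 scale_covariate = scale_covariate,
                 scale_sigma = scale_sigma,
                 scale_flat = scale_flat), class = "sic_priors")
}

#' Log-intensity linear predictor for one location
#'
#' `beta0 + z' beta + sum_k q_k' delta_k`: the modelled log conditional
#' intensity at a location, given an image-level coefficient slice. The
#' logistic linear predictor is this value plus the row's offset
#' `-log(lambda_dummy)`.
#'
#' @param coefs List with `beta0` (scalar), `beta` (length-J vector, may
#'   be empty), `delta` (length `K*P` vector matching the `q_*` columns).
#' @param row One row of a [build_sic_data()] tibble.
#' @return Scalar log intensity.
#' @export
log_intensity <- function(coefs, row) {
  q <- as.numeric(row[grep("^q_", names(row), value = TRUE)])
  z <- as.numeric(row[grep("^z_", names(row), value = TRUE)])
  beta <- coefs[["beta"]] %||% numeric(0)
  if (length(q) != length(coefs[["delta"]])) {
    stop("`delta` length does not match the feature columns.",
         call. = FALSE)
  }
  if (length(z) != length(beta)) {
    stop("`beta` length does not match the covariate columns.",
         call. = FALSE)
  }
  coefs[["beta0"]] + sum(z * beta) + sum(q * coefs[["delta"]])
}

# ---- internal model assembly --------------------------------------------

# standardize continuous covariates, leave 0/1 columns alone
standardize_covariates <- function(Z) {
  info <- list(center = rep(0, ncol(Z)), scale = rep(1, ncol(Z)))
  for (j in seq_len(ncol(Z))) {
    v <- Z[, j]
    if (!all(v %in% c(0, 1))) {
      info$center[j] <- mean(v)
      info$scale[j] <- stats::sd(v)
      if (info$scale[j] == 0) info$scale[j] <- 1
      Z[, j] <- (v - info$center[j]) / info$scale[j]
    }
  }
  list(Z = Z, info = info)
}

# Assemble design arrays, index maps and the joint log-posterior /
# gradient closure for the three-level model. Parameter layout
# (unconstrained): beta0 (M) | beta (J) | psi (G*KP) |
# gamma_raw (N*KP) | delta_raw (M*KP) | log sigma (3: cohort, patient,
# image). The cohort level is centered (psi sampled directly: it pools
# all patients and is well identified, so centering avoids the
# sigma_cohort funnel); patient and image deviations are non-centered:
# gamma = psi[g(n)] + s_p gamma_raw; delta = gamma[n(m)] + s_i delta_raw.
make_hier_model <- function(data, hierarchy, priors = sic_priors()) {
  basis <- attr(data, "basis")
  sources <- attr(data, "sources")
  stopifnot(!is.null(basis), !is.null(sources))
  hierarchy <- tibble::as_tibble(hierarchy)
  images <- sort(unique(data$image_id))
  unmapped <- setdiff(images, hierarchy$image_id)
  if (length(unmapped)) {
    stop("Image(s) not in the hierarchy map: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  hier <- hierarchy[match(images, hierarchy$image_id), ]
  patients <- sort(unique(hier$patient_id))
  pat_cohort <- dplyr::distinct(hier, .data$patient_id, .data$cohort_id)
  cohorts <- sort(unique(hier$cohort_id))
  M <- length(images); N <- length(patients); G <- length(cohorts)
  nofm <- match(hier$patient_id, patients)
  gofn <- match(pat_cohort$cohort_id[match(patients, pat_cohort$patient_id)],
                cohorts)

  qcols <- feature_cols(data, sources, basis$P)
  stopifnot(all(qcols %in% names(data)))
  Q <- as.matrix(data[qcols])
  KP <- ncol(Q)
  zcols <- covariate_cols(data)
  J <- length(zcols)
  if (J > 0) {
    st <- standardize_covariates(as.matrix(data[zcols]))
    Z <- st$Z; z_info <- st$info
  } else {
    Z <- NULL; z_info <- NULL
  }
  y <- as.numeric(data$response)
  off <- as.numeric(data$offset)
  img <- match(data$image_id, images)

  idx <- list(beta0 = seq_len(M),
              beta = if (J) M + seq_len(J) else integer(0),
              psi = M + J + seq_len(G * KP),
              gamma = M + J + G * KP + seq_len(N * KP),
              delta = M + J + (G + N) * KP + seq_len(M * KP),
              log_sigma = M + J + (G + N + M) * KP + 1:3)
  D <- M + J + (G + N + M) * KP + 3L
  sb <- priors$scale_intercept; sz <- priors$scale_covariate
  ss <- priors$scale_sigma

  lp_grad <- function(theta) {
    beta0 <- theta[idx$beta0]
    beta <- theta[idx$beta]
    Psi <- matrix(theta[idx$psi], G, KP)
    Gam_raw <- matrix(theta[idx$gamma], N, KP)
    Del_raw <- matrix(theta[idx$delta], M, KP)
    ls <- theta[idx$log_sigma]
    sc <- exp(ls[1]); sp <- exp(ls[2]); si <- exp(ls[3])

    Gam <- Psi[gofn, , drop = FALSE] + sp * Gam_raw
    Del <- Gam[nofm, , drop = FALSE] + si * Del_raw

    eta <- beta0[img] + off + rowSums(Q * Del[img, , drop = FALSE])
    if (J) eta <- eta + drop(Z %*% beta)
    le <- log1pexp(eta)
    lp <- sum(y * eta) - sum(le) -
      0.5 * sum(beta0^2) / sb^2 -
      0.5 * sum(Psi^2) / sc^2 - G * KP * ls[1] -
      0.5 * sum(Gam_raw^2) - 0.5 * sum(Del_raw^2) -
      0.5 * (sc^2 + sp^2 + si^2) / ss^2 + sum(ls)
    if (J) lp <- lp - 0.5 * sum(beta^2) / sz^2

    r <- y - exp(eta - le)                 # y - inv_logit(eta)
    g <- numeric(D)
    acc <- rowsum(cbind(r, Q * r), img)    # one grouping pass
    g[idx$beta0] <- acc[, 1] - beta0 / sb^2
    if (J) g[idx$beta] <- drop(crossprod(Z, r)) - beta / sz^2
    G_del <- acc[, -1, drop = FALSE]       # M x KP: dloglik / dDelta
    G_gam <- rowsum(G_del, nofm)           # N x KP
    G_psi <- rowsum(G_gam, gofn)           # G x KP
    g[idx$psi] <- as.vector(G_psi - Psi / sc^2)
    g[idx$gamma] <- as.vector(sp * G_gam - Gam_raw)
    g[idx$delta] <- as.vector(si * G_del - Del_raw)
    g[idx$log_sigma] <- c(
      sum(Psi^2) / sc^2 - G * KP - sc^2 / ss^2 + 1,
      sp * sum(G_gam * Gam_raw) - sp^2 / ss^2 + 1,
      si * sum(G_del * Del_raw) - si^2 / ss^2 + 1)
    list(lp = lp, grad = g)
  }

  # empirical intercept init: logit(mean response) - offset, per image
  p1 <- tapply(y, img, mean)
  off1 <- tapply(off, img, mean)
  beta0_emp <- stats::qlogis(pmin(pmax(p1, 0.02), 0.98)) - off1
  init_fn <- function(seed) {
    withr::with_seed(seed, {
      th <- stats::rnorm(D, 0, 0.1)
      th[idx$beta0] <- beta0_emp + stats::rnorm(M, 0, 0.1)
      th[idx$log_sigma] <- log(0.5) + stats::rnorm(3, 0, 0.1)
      th
    })
  }

  list(lp_grad = lp_grad, init_fn = init_fn, idx = idx, D = D,
       images = images, patients = patients, cohorts = cohorts,
       nofm = nofm, gofn = gofn, KP = KP, J = J, zcols = zcols,
       z_info = z_info, basis = basis, sources = sources,
       target = attr(data, "target"))
}

# single-image unpooled model: beta0 | beta (J) | delta (KP)
make_flat_model <- function(data_img, basis, sources,
                            priors = sic_priors()) {
  qcols <- feature_cols(data_img, sources, basis$P)
  Q <- as.matrix(data_img[qcols])
  KP <- ncol(Q)
  zcols <- covariate_cols(data_img)
  J <- length(zcols)
  if (J > 0) {
    st <- standardize_covariates(as.matrix(data_img[zcols]))
    Z <- st$Z
  } else Z <- NULL
  y <- as.numeric(data_img$response)
  off <- as.numeric(data_img$offset)
  D <- 1L + J + KP
  sb <- priors$scale_intercept; sz <- priors$scale_covariate
  sf <- priors$scale_flat
  idx <- list(beta0 = 1L, beta = if (J) 1L + seq_len(J) else integer(0),
              delta = 1L + J + seq_len(KP))

  lp_grad <- function(theta) {
    beta0 <- theta[1L]
    beta <- theta[idx$beta]
    delta <- theta[idx$delta]
    eta <- beta0 + off + drop(Q %*% delta)
    if (J) eta <- eta + drop(Z %*% beta)
    lp <- sum(y * eta) - sum(log1pexp(eta)) -
      0.5 * beta0^2 / sb^2 - 0.5 * sum(delta^2) / sf^2
    if (J) lp <- lp - 0.5 * sum(beta^2) / sz^2
    r <- y - stats::plogis(eta)
    g <- numeric(D)
    g[1L] <- sum(r) - beta0 / sb^2
    if (J) g[idx$beta] <- drop(crossprod(Z, r)) - beta / sz^2
    g[idx$delta] <- drop(crossprod(Q, r)) - delta / sf^2
    list(lp = lp, grad = g)
  }
  p1 <- mean(y); off1 <- mean(off)
  beta0_emp <- stats::qlogis(pmin(pmax(p1, 0.02), 0.98)) - off1
  init_fn <- function(seed) {
    withr::with_seed(seed, {
      th <- stats::rnorm(D, 0, 0.1)
      th[1L] <- beta0_emp + stats::rnorm(1, 0, 0.1)
      th
    })
  }
  list(lp_grad = lp_grad, init_fn = init_fn, idx = idx, D = D, KP = KP)
}

# ---- fitting -------------------------------------------------------------

#' Fit the three-level hierarchical interaction model
#'
#' Bernoulli-logit likelihood over data and dummy locations with logit
#' `log lambda(v) - log lambda_dummy`; interaction coefficients pooled
#' partially across images, patients and cohorts
#' (`psi ~ N(0, sigma_cohort^2)`, `gamma ~ N(psi, sigma_patient^2)`,
#' `delta ~ N(gamma, sigma_image^2)`, elementwise per basis index).
#' Intercepts are per-image and unpooled — baseline density varies by
#' image and curves are defined relative to it. Sampling uses adaptive
#' Hamiltonian Monte Carlo with a non-centered parameterization;
#' convergence is flagged (not fatal) when split-Rhat of any interaction
#' coefficient exceeds 1.05.
#'
#' @param data A [build_sic_data()] tibble (one or more images).
#' @param hierarchy Tibble with `image_id`, `patient_id`, `cohort_id`
#'   covering every image in `data` (e.g. `study$hierarchy`).
#' @param priors A [sic_priors()] object.
#' @param chains,warmup,draws Sampler layout (default 4 x 1000 + 1000).
#' @param seed Integer seed; chains use seeds derived from it.
#' @param max_leapfrog Maximum leapfrog steps per trajectory (the length
#'   is jittered uniformly in `1:max_leapfrog`).
#' @return An object of class `sic_fit` with posterior draw arrays
#'   (`psi_draws`, `gamma_draws`, `delta_draws`, dims draws x unit x
#'   coefficient), intercept/covariate/sigma draws, unit labels, and
#'   sampler diagnostics. Use [sic_curves()], [sic_band()], [tidy()],
#'   [glance()] downstream.
#' @export
fit_sic_hier <- function(data, hierarchy, priors = sic_priors(),
                         chains = 4, warmup = 1000, draws = 1000,
                         seed = 1, max_leapfrog = 12) {
  mod <- make_hier_model(data, hierarchy, priors)
  smp <- hmc_sample(mod$lp_grad, mod$init_fn, chains = chains,
                    warmup = warmup, draws = draws, seed = seed,
                    L_max = max_leapfrog)
  th <- smp$draws
  S <- nrow(th)
  M <- length(mod$images); N <- length(mod$patients)
  G <- length(mod$cohorts); KP <- mod$KP

  sig <- exp(th[, mod$idx$log_sigma, drop = FALSE])
  colnames(sig) <- c("sigma_cohort", "sigma_patient", "sigma_image")
  psi <- array(th[, mod$idx$psi], c(S, G, KP))
  gam_raw <- array(th[, mod$idx$gamma], c(S, N, KP))
  del_raw <- array(th[, mod$idx$delta], c(S, M, KP))
  gam <- psi[, mod$gofn, , drop = FALSE] + gam_raw * sig[, 2]
  del <- gam[, mod$nofm, , drop = FALSE] + del_raw * sig[, 3]
  dimnames(psi) <- list(NULL, mod$cohorts, NULL)
  dimnames(gam) <- list(NULL, mod$patients, NULL)
  dimnames(del) <- list(NULL, mod$images, NULL)

  # diagnostics on the interaction coefficients and sigmas
  diag_cols <- c(mod$idx$psi, mod$idx$gamma, mod$idx$delta,
                 mod$idx$log_sigma)
  per_chain <- lapply(smp$chains, `[[`, "draws")
  rhat <- vapply(diag_cols, function(j) {
    split_rhat(do.call(cbind, lapply(per_chain, function(m) m[, j])))
  }, numeric(1))
  ess <- vapply(diag_cols, function(j) {
    ess_basic(do.call(cbind, lapply(per_chain, function(m) m[, j])))
  }, numeric(1))
  max_rhat <- max(rhat, na.rm = TRUE)
  if (is.finite(max_rhat) && max_rhat > 1.05) {
    warning(sprintf(
      "Sampler convergence flagged: max split-Rhat = %.3f (> 1.05).",
      max_rhat))
  }

  structure(list(
    model = "hierarchical",
    basis = mod$basis, sources = mod$sources, target = mod$target,
    images = mod$images, patients = mod$patients, cohorts = mod$cohorts,
    nofm = mod$nofm, gofn = mod$gofn,
    beta0_draws = th[, mod$idx$beta0, drop = FALSE],
    beta_draws = if (mod$J) {
      b <- th[, mod$idx$beta, drop = FALSE]; colnames(b) <- mod$zcols; b
    },
    z_info = mod$z_info,
    sigma_draws = sig,
    psi_draws = psi, gamma_draws = gam, delta_draws = del,
    diagnostics = list(max_rhat = max_rhat, min_ess = min(ess),
                       divergences = smp$divergences,
                       accept_rate = smp$accept_rate,
                       chains = chains, warmup = warmup, draws = draws),
    seed = seed), class = "sic_fit")
}

#' Fit per-image models without hierarchical pooling
#'
#' The "flat" ablation baseline: the same Bernoulli-logit likelihood, fit
#' independently for each image with weakly informative independent
#' Normal priors on the image coefficients. Returns one coefficient draw
#' array per image; no patient or cohort level exists.
#'
#' @inheritParams fit_sic_hier
#' @return An object of class `sic_flat_fit` with `delta_draws`
#'   (draws x image x coefficient), `beta0_draws`, labels and per-image
#'   diagnostics.
#' @export
fit_sic_flat <- function(data, priors = sic_priors(),
                         chains = 2, warmup = 500, draws = 500,
                         seed = 1, max_leapfrog = 12) {
  basis <- attr(data, "basis")
  sources <- attr(data, "sources")
  images <- sort(unique(data$image_id))
  fits <- vector("list", length(images))
  for (i in seq_along(images)) {
    di <- data[data$image_id == images[i], ]
    mod <- make_flat_model(di, basis, sources, priors)
    smp <- hmc_sample(mod$lp_grad, mod$init_fn, chains = chains,
                      warmup = warmup, draws = draws,
                      seed = derive_seed(seed, 37L * i),
                      L_max = max_leapfrog)
    fits[[i]] <- list(draws = smp$draws, idx = mod$idx,
                      accept_rate = smp$accept_rate,
                      divergences = smp$divergences)
  }
  S <- nrow(fits[[1]]$draws)
  KP <- length(fits[[1]]$idx$delta)
  del <- array(NA_real_, c(S, length(images), KP),
               dimnames = list(NULL, images, NULL))
  beta0 <- matrix(NA_real_, S, length(images))
  for (i in seq_along(images)) {
    del[, i, ] <- fits[[i]]$draws[, fits[[i]]$idx$delta, drop = FALSE]
    beta0[, i] <- fits[[i]]$draws[, 1]
  }
  structure(list(
    model = "flat", basis = basis, sources = sources,
    target = attr(data, "target"), images = images,
    beta0_draws = beta0, delta_draws = del,
    diagnostics = list(
      accept_rate = mean(vapply(fits, `[[`, numeric(1), "accept_rate")),
      divergences = sum(vapply(fits, `[[`, integer(1), "divergences")),
      chains = chains, warmup = warmup, draws = draws),
    seed = seed), class = "sic_flat_fit")
}

#' @export
print.sic_fit <- function(x, ...) {
  cat(sprintf(
    "<sic_fit> hierarchical: %d images / %d patients / %d cohorts; %s -> %s\n",
    length(x$images), length(x$patients), length(x$cohorts),
    paste(x$sources, collapse = "+"), x$target))
  cat(sprintf("  draws: %d; max Rhat %.3f; divergences %d; accept %.2f\n",
              nrow(x$beta0_draws), x$diagnostics$max_rhat,
              x$diagnostics$divergences, x$diagnostics$accept_rate))
  invisible(x)
}

#' @export
print.sic_flat_fit <- function(x, ...) {
  cat(sprintf("<sic_flat_fit> %d independent image fits; %s -> %s\n",
              length(x$images), paste(x$sources, collapse = "+"),
              x$target))
  invisible(x)
}
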