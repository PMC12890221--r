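#' Configuration for a simulated hierarchical study
#'
#' Collects the study conditions under which synthetic multitype point
#' patterns are generated: the window, the hierarchy sizes, expected
#' per-image cell counts, the true cohort-level interaction coefficients,
#' and the between-patient / between-image coefficient spreads. Defaults
#' follow the benchmark layout of the framework's simulation studies: a
#' 1500 x 1500 um window, a single positive interaction bump peaking near
#' 40 um with height 0.8, and homogeneous Poisson source cells.
#'
#' @param n_patients Number of patients (single cohort by default).
#' @param images_per_patient Images per patient (recycled over patients,
#'   so e.g. `1:3` alternates).
#' @param window_size Side length `S` of the square window, micrometres.
#' @param source_count,target_count Expected cells per image for the
#'   source and target type.
#' @param basis A [sic_basis()] object for the true curves.
#' @param psi_true True cohort-level coefficient vector (length
#'   `basis$P`); default is [sic_bump_coefficients()].
#' @param sigma_patient,sigma_image Coefficient spread across patients
#'   within cohort and images within patient (log-intensity scale).
#' @param beta0 Baseline log-intensity; `NULL` (default) calibrates it so
#'   that the expected realized target count approximates
#'   `target_count`: starting from `log(target_count / window_size^2)`,
#'   the average intensity inflation induced by a positive interaction
#'   curve is removed via Campbell's formula for Poisson sources,
#'   `E exp(sum SIC) = exp(lambda_src * int (exp(SIC(s)) - 1) 2 pi s ds)`.
#'   Without this correction, studies with attractive curves would carry
#'   several times the nominal target density and the density conditions
#'   would not mean what they say.
#' @param source_label,target_label Cell-type labels used in the output.
#' @param null_interaction If `TRUE`, all interaction coefficients are
#'   forced to zero (type-I error scenarios).
#' @param compartments Optional compartment field from
#'   [simulate_compartment_field()], added as an unobserved baseline
#'   offset (confounding scenarios).
#' @return A list of class `sic_sim_config`.
#' @export
sic_sim_config <- function(n_patients = 40,
                           images_per_patient = 2,
                           window_size = 1500,
                           source_count = 150,
                           target_count = 50,
                           basis = sic_basis(),
                           psi_true = NULL,
                           sigma_patient = 0.2,
                           sigma_image = 0.1,
                           beta0 = NULL,
                           source_label = "source",
                           target_label = "target",
                           null_interaction = FALSE,
                           compartments = NULL) {
  stopifnot(inherits(basis, "sic_basis"), n_patients >= 1,
            all(images_per_patient >= 1), window_size > 0,
            source_count >= 0, target_count >= 0,
            sigma_patient >= 0, sigma_image >= 0)
  if (is.null(psi_true)) psi_true <- sic_bump_coefficients(basis)
  stopifnot(length(psi_true) == basis$P)
  if (is.null(beta0)) {
    beta0 <- log(max(target_count, 1e-8) / window_size^2)
    if (!isTRUE(null_interaction)) {
      s <- seq(0, basis$r_max, length.out = 512L)
      sic <- eval_sic(basis, psi_true, s)
      lam_src <- source_count / window_size^2
      ds <- s[2] - s[1]
      beta0 <- beta0 - lam_src * sum((exp(sic) - 1) * 2 * pi * s) * ds
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    images_per_patient = as.integer(images_per_patient),
    window_size = window_size,
    source_count = source_count,
    target_count = target_count,
    basis = basis,
    psi_true = as.numeric(psi_true),
    sigma_patient = sigma_patient,
    sigma_image = sigma_image,
    beta0 = beta0,
    source_label = source_label,
    target_label = target_label,
    null_interaction = isTRUE(null_interaction),
    compartments = compartments), class = "sic_sim_config")
}

#' Draw hierarchical ground-truth coefficients
#'
#' Patient-level coefficients are Normal around the cohort truth with sd
#' `sigma_patient`; image-level coefficients are Normal around their
#' patient's with sd `sigma_image`, elementwise — the same generative
#' hierarchy the model assumes.
#'
#' @param config A [sic_sim_config()].
#' @param seed Integer seed.
#' @return A list with `psi` (cohort vector), `gamma` (patients x P
#'   matrix), `delta` (images x P matrix), and the hierarchy tibble
#'   (`image_id`, `patient_id`, `cohort_id`).
#' @export
draw_hier_coefficients <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sic_sim_config"))
  P <- config$basis$P
  n_img_per <- rep_len(config$images_per_patient, config$n_patients)
  patients <- sprintf("pat%03d", seq_len(config$n_patients))
  image_pat <- rep(seq_len(config$n_patients), n_img_per)
  images <- sprintf("img%03d", seq_along(image_pat))
  psi <- if (config$null_interaction) rep(0, P) else config$psi_true
  draw <- function() {
    gamma <- matrix(stats::rnorm(config$n_patients * P, mean = rep(psi, each = config$n_patients),
                                 sd = config$sigma_patient),
                    config$n_patients, P)
    delta <- gamma[image_pat, , drop = FALSE] +
      matrix(stats::rnorm(length(image_pat) * P, sd = config$sigma_image),
             length(image_pat), P)
    list(gamma = gamma, delta = delta)
  }
  gd <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (config$null_interaction) {
    gd$gamma[] <- 0
    gd$delta[] <- 0
  }
  rownames(gd$gamma) <- patients
  rownames(gd$delta) <- images
  list(psi = psi, gamma = gd$gamma, delta = gd$delta,
       hierarchy = tibble::tibble(image_id = images,
                                  patient_id = patients[image_pat],
                                  cohort_id = "cohort1"))
}

#' Simulate a homogeneous Poisson source pattern
#'
#' @param window One-row data frame with `x_min`, `x_max`, `y_min`,
#'   `y_max`.
#' @param expected_count Expected number of points (>= 0).
#' @param seed Integer seed.
#' @return A tibble with columns `x`, `y`.
#' @export
simulate_source <- function(window, expected_count, seed = NULL) {
  stopifnot(expected_count >= 0)
  draw <- function() {
    n <- stats::rpois(1L, expected_count)
    tibble::tibble(x = stats::runif(n, window$x_min, window$x_max),
                   y = stats::runif(n, window$y_min, window$y_max))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Voronoi compartment field with baseline log-intensity offsets
#'
#' Partitions the window into the Voronoi cells of uniformly placed
#' seeds and assigns each compartment a log-intensity offset. Offsets
#' are drawn i.i.d. Normal with sd set by the effect-strength tier
#' (weak 0.3, moderate 0.7, strong 1.2) and centred to mean zero, so
#' the field shifts density between compartments without changing the
#' overall baseline. Emulates tissue architecture (tumor islands,
#' stromal regions) that confounds interaction estimates when
#' unmodelled.
#'
#' @param window One-row window data frame.
#' @param n_compartments Number of Voronoi cells (>= 1).
#' @param strength `"weak"`, `"moderate"`, `"strong"`, or a numeric sd.
#' @param seed Integer seed.
#' @return A list of class `sic_compartments` with `seeds` (tibble),
#'   `offsets` (numeric), and a `field(x, y)` function returning the
#'   offset at arbitrary locations.
#' @export
simulate_compartment_field <- function(window, n_compartments = 3,
                                       strength = "moderate", seed = NULL) {
  stopifnot(n_compartments >= 1)
  sd <- if (is.numeric(strength)) {
    strength
  } else {
    switch(match.arg(strength, c("weak", "moderate", "strong")),
           weak = 0.3, moderate = 0.7, strong = 1.2)
  }
  draw <- function() {
    seeds <- tibble::tibble(
      x = stats::runif(n_compartments, window$x_min, window$x_max),
      y = stats::runif(n_compartments, window$y_min, window$y_max))
    offsets <- stats::rnorm(n_compartments, sd = sd)
    list(seeds = seeds, offsets = offsets - mean(offsets))
  }
  parts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (n_compartments == 1L) parts$offsets <- 0
  field <- function(x, y) {
    d2 <- outer(x, parts$seeds$x, "-")^2 + outer(y, parts$seeds$y, "-")^2
    parts$offsets[max.col(-d2, ties.method = "first")]
  }
  structure(list(seeds = parts$seeds, offsets = parts$offsets,
                 field = field, strength_sd = sd),
            class = "sic_compartments")
}

# log-intensity surface for the conditional target process
target_log_intensity <- function(x, y, source, delta, basis, beta0,
                                 compartments = NULL) {
  locs <- tibble::tibble(x = x, y = y)
  q <- interaction_features(locs, source, basis)
  lp <- beta0 + drop(q %*% delta)
  if (!is.null(compartments)) lp <- lp + compartments$field(x, y)
  lp
}

#' Simulate the target pattern given sources by Poisson thinning
#'
#' Realizes an inhomogeneous Poisson process with
#' `log lambda(v) = beta0 + q(v) . delta (+ compartment offset)` by
#' rejection: candidates are drawn homogeneously at
#' `lambda_max = 1.2 * max(lambda)` over a fine evaluation grid and kept
#' with probability `lambda(v) / lambda_max`. The run aborts if any
#' candidate's intensity exceeds the bound (grid-maximum failure), so
#' accepted patterns are exact draws.
#'
#' @param source Tibble of source-cell coordinates (`x`, `y`).
#' @param delta True image-level coefficient vector (length `basis$P`).
#' @param basis A [sic_basis()] object.
#' @param beta0 Baseline log-intensity.
#' @param window One-row window data frame.
#' @param seed Integer seed.
#' @param compartments Optional [simulate_compartment_field()] result.
#' @param grid_n Evaluation-grid resolution per axis for the intensity
#'   bound (default 256).
#' @return A tibble with columns `x`, `y`.
#' @export
simulate_target <- function(source, delta, basis, beta0, window,
                            seed = NULL, compartments = NULL,
                            grid_n = 256L) {
  stopifnot(length(delta) == basis$P, is.finite(beta0))
  gx <- seq(window$x_min, window$x_max, length.out = grid_n)
  gy <- seq(window$y_min, window$y_max, length.out = grid_n)
  # coarse bound pass: evaluate on the grid in manageable chunks
  lp_max <- -Inf
  for (yy in split(gy, ceiling(seq_along(gy) / 32))) {
    g <- expand.grid(x = gx, y = yy)
    lp <- target_log_intensity(g$x, g$y, source, delta, basis, beta0,
                               compartments)
    if (!all(is.finite(lp))) stop("Non-finite intensity on grid.",
                                  call. = FALSE)
    lp_max <- max(lp_max, max(lp))
  }
  lambda_max <- 1.2 * exp(lp_max)
  area <- window_area(window)
  if (!is.finite(lambda_max) || lambda_max * area > 5e6) {
    stop("Intensity bound exceeds 5e6 expected candidates; ",
         "the coefficient/baseline combination is explosive.",
         call. = FALSE)
  }
  draw <- function() {
    n_cand <- stats::rpois(1L, lambda_max * area)
    cx <- stats::runif(n_cand, window$x_min, window$x_max)
    cy <- stats::runif(n_cand, window$y_min, window$y_max)
    lam <- numeric(n_cand)
    for (ch in split(seq_len(n_cand),
                     ceiling(seq_len(n_cand) / 50000))) {
      lam[ch] <- exp(target_log_intensity(cx[ch], cy[ch], source, delta,
                                          basis, beta0, compartments))
    }
    if (any(lam > lambda_max)) {
      stop("Intensity bound violated during thinning; increase grid_n.",
           call. = FALSE)
    }
    keep <- stats::runif(n_cand) < lam / lambda_max
    tibble::tibble(x = cx[keep], y = cy[keep])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a full hierarchical study with known interaction curves
#'
#' Per image: draws a homogeneous Poisson source pattern, then the
#' conditional target pattern under that image's true coefficients.
#' Per-image seeds are derived deterministically from the master seed
#' via a counter, so any single image is reproducible in isolation.
#'
#' @param config A [sic_sim_config()].
#' @param seed Master integer seed.
#' @return A list with `study` (a [sic_study()]), `truth` (the
#'   [draw_hier_coefficients()] output plus the config), and
#'   `config`.
#' @export
simulate_study <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sic_sim_config"))
  S <- config$window_size
  truth <- draw_hier_coefficients(config, seed = derive_seed(seed, 0L))
  hier <- truth$hierarchy
  win1 <- tibble::tibble(x_min = 0, x_max = S, y_min = 0, y_max = S)
  cells <- vector("list", nrow(hier))
  for (i in seq_len(nrow(hier))) {
    src <- simulate_source(win1, config$source_count,
                           seed = derive_seed(seed, 2L * i - 1L))
    tgt <- simulate_target(src, truth$delta[i, ], config$basis,
                           config$beta0, win1,
                           seed = derive_seed(seed, 2L * i),
                           compartments = config$compartments)
    cells[[i]] <- dplyr::bind_rows(
      dplyr::mutate(src, cell_type = config$source_label),
      dplyr::mutate(tgt, cell_type = config$target_label))
    cells[[i]]$image_id <- hier$image_id[i]
    cells[[i]]$patient_id <- hier$patient_id[i]
    cells[[i]]$cohort_id <- hier$cohort_id[i]
  }
  cells <- dplyr::bind_rows(cells)
  windows <- dplyr::bind_cols(tibble::tibble(image_id = hier$image_id), win1)
  study <- sic_study(cells, windows = windows)
  list(study = study, truth = truth, config = config)
}

#' Serialize / restore simulation ground truth
#'
#' Writes the true coefficients and hierarchy of a simulated study as a
#' JSON sidecar so scoring can be reproduced without rerunning the
#' generator.
#'
#' @param truth The `truth` element of [simulate_study()] output.
#' @param path JSON file path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` the
#'   restored list.
#' @export
write_truth <- function(truth, path) {
  out <- list(psi = truth$psi,
              gamma = truth$gamma, patients = rownames(truth$gamma),
              delta = truth$delta, images = rownames(truth$delta),
              hierarchy = truth$hierarchy)
  jsonlite::write_json(out, path, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- as.matrix(raw$gamma)
  delta <- as.matrix(raw$delta)
  rownames(gamma) <- raw$patients
  rownames(delta) <- raw$images
  list(psi = as.numeric(raw$psi), gamma = gamma, delta = delta,
       hierarchy = tibble::as_tibble(raw$hierarchy))
}
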