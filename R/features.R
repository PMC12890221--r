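#' Sample dummy points from a homogeneous Poisson process
#'
#' Dummy points turn intensity estimation into binary classification:
#' observed target cells get response 1, dummies response 0, and the
#' logistic model with offset `-log(lambda_dummy)` recovers the
#' log-intensity. The count is Poisson(`lambda_dummy * area`) and
#' locations are i.i.d. uniform on the window.
#'
#' @param window A one-row data frame with `x_min`, `x_max`, `y_min`,
#'   `y_max` (micrometres).
#' @param lambda_dummy Dummy intensity in points per square micrometre
#'   (> 0).
#' @param seed Optional integer seed; the draw is reproducible given the
#'   seed and leaves the global RNG state untouched.
#' @return A tibble with columns `x`, `y`.
#' @export
sample_dummy_points <- function(window, lambda_dummy, seed = NULL) {
  if (!is.numeric(lambda_dummy) || lambda_dummy <= 0) {
    stop("`lambda_dummy` must be positive.", call. = FALSE)
  }
  area <- window_area(window)
  draw <- function() {
    n <- stats::rpois(1L, lambda_dummy * area)
    tibble::tibble(
      x = stats::runif(n, window$x_min, window$x_max),
      y = stats::runif(n, window$y_min, window$y_max))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Interaction features: basis-weighted counts of source cells
#'
#' For each location `v` and basis function `phi_p`, computes
#' `q_p(v) = sum_{x in source} phi_p(||v - x||)`. Only source cells within
#' `r_max` of `v` contribute (compact basis support). No edge correction
#' is applied: the model conditions on the observed source cells, so
#' features near the window boundary are attenuated by construction.
#'
#' @param locations Data frame with columns `x`, `y` (the evaluation
#'   points: target cells and dummies).
#' @param source Data frame with columns `x`, `y` (source-cell
#'   coordinates).
#' @param basis A [sic_basis()] object.
#' @return A `nrow(locations) x P` numeric matrix.
#' @export
interaction_features <- function(locations, source, basis) {
  stopifnot(inherits(basis, "sic_basis"))
  n <- nrow(locations)
  out <- matrix(0, n, basis$P)
  if (n == 0L || is.null(source) || nrow(source) == 0L) return(out)
  d <- sqrt(outer(locations$x, source$x, "-")^2 +
            outer(locations$y, source$y, "-")^2)
  hit <- which(d <= basis$r_max)
  if (!length(hit)) return(out)
  loc_idx <- ((hit - 1L) %% n) + 1L
  vals <- basis_matrix(basis, d[hit])
  acc <- rowsum(vals, group = loc_idx)
  out[as.integer(rownames(acc)), ] <- acc
  out
}

#' Binary tissue-compartment covariate from local reference density
#'
#' Smooths the reference pattern (e.g. tumor cells) with an isotropic
#' Gaussian kernel, evaluates the density at each location, and flags
#' locations whose density exceeds the per-image threshold (default: the
#' median over the supplied locations). Used to adjust fits for baseline
#' density differences across tissue compartments.
#'
#' @param locations Data frame with columns `x`, `y`.
#' @param reference Data frame with columns `x`, `y` of the reference
#'   cell type; if empty, the covariate is all zeros (with a warning).
#' @param bandwidth Gaussian kernel standard deviation in micrometres.
#' @param threshold `"median"` (default) or a numeric cutoff on the
#'   kernel density scale.
#' @return Integer vector of 0/1 flags, one per location.
#' @export
compartment_covariate <- function(locations, reference, bandwidth = 50,
                                  threshold = "median") {
  stopifnot(bandwidth > 0)
  n <- nrow(locations)
  if (is.null(reference) || nrow(reference) == 0L) {
    warning("Empty reference pattern; compartment covariate is all zeros.")
    return(integer(n))
  }
  d2 <- outer(locations$x, reference$x, "-")^2 +
    outer(locations$y, reference$y, "-")^2
  dens <- rowSums(exp(-d2 / (2 * bandwidth^2))) / (2 * pi * bandwidth^2)
  cut <- if (identical(threshold, "median")) stats::median(dens) else threshold
  as.integer(dens > cut)
}

# deterministic seed stream: a Lehmer-style hash of (seed, counter) kept
# below 2^31 (products stay exact in double precision)
derive_seed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  m <- 2147483629
  x <- (as.numeric(seed) %% m * 48271 +
          as.numeric(counter) %% m * 16807 + 11213) %% m
  as.integer(x)
}

#' Build the logistic-approximation dataset for a study
#'
#' For every image, stacks the observed target cells (response 1) with
#' freshly sampled dummy points (response 0) and attaches, per location:
#' the offset `-log(lambda_dummy)`, the interaction-feature block
#' `q_<source>_<p>` for each source type, and any covariate columns
#' `z_*`. Under the logistic approximation,
#' `P(response = 1 | v) = lambda(v) / (lambda(v) + lambda_dummy)`, so the
#' logit equals `log lambda(v) + offset`.
#'
#' @param study A [sic_study()].
#' @param target Target cell-type label (the type being modelled).
#' @param sources Character vector of source cell-type labels (must not
#'   contain `target`).
#' @param basis A [sic_basis()] object.
#' @param lambda_dummy Dummy intensity; `NULL` (default) uses
#'   `4 * N_target / area` per image, a standard quadrature density.
#' @param compartment_from Optional cell-type label; adds a binary
#'   `z_compartment` covariate from [compartment_covariate()].
#' @param compartment_bandwidth Kernel bandwidth for the compartment
#'   covariate, micrometres.
#' @param covariate_fn Optional `function(locations, image_id)` returning
#'   a data frame of extra covariates (one row per location); columns are
#'   prefixed with `z_` if not already.
#' @param seed Integer study seed; per-image dummy draws use seeds
#'   derived deterministically from it.
#' @return A tibble with columns `image_id`, `x`, `y`, `response`,
#'   `offset`, the `q_*` feature columns, and any `z_*` covariates. The
#'   basis, target and source labels are attached as attributes.
#' @export
build_sic_data <- function(study, target, sources, basis,
                           lambda_dummy = NULL,
                           compartment_from = NULL,
                           compartment_bandwidth = 50,
                           covariate_fn = NULL,
                           seed = NULL) {
  stopifnot(inherits(study, "sic_study"), inherits(basis, "sic_basis"))
  if (target %in% sources) {
    stop("`target` must not appear in `sources`.", call. = FALSE)
  }
  images <- study$windows$image_id
  rows <- vector("list", length(images))
  for (i in seq_along(images)) {
    img <- images[i]
    win <- study$windows[study$windows$image_id == img, ]
    cells_img <- dplyr::filter(study$cells, .data$image_id == img)
    tgt <- dplyr::filter(cells_img, .data$cell_type == target)
    area <- window_area(win)
    lam <- if (is.null(lambda_dummy)) {
      4 * max(nrow(tgt), 1L) / area
    } else {
      lambda_dummy
    }
    dum <- sample_dummy_points(win, lam, seed = derive_seed(seed, i))
    locs <- tibble::tibble(
      x = c(tgt$x, dum$x), y = c(tgt$y, dum$y),
      response = rep(c(1L, 0L), c(nrow(tgt), nrow(dum))))
    block <- tibble::tibble(image_id = img, x = locs$x, y = locs$y,
                            response = locs$response, offset = -log(lam))
    if (length(sources)) {
      q <- lapply(sources, function(src) {
        interaction_features(locs,
                             dplyr::filter(cells_img,
                                           .data$cell_type == src),
                             basis)
      })
      qmat <- do.call(cbind, q)
      colnames(qmat) <- unlist(lapply(sources, function(src) {
        paste0("q_", src, "_", seq_len(basis$P))
      }))
      block <- dplyr::bind_cols(block, tibble::as_tibble(qmat))
    }
    if (!is.null(compartment_from)) {
      ref <- dplyr::filter(cells_img, .data$cell_type == compartment_from)
      block$z_compartment <- compartment_covariate(
        locs, ref, bandwidth = compartment_bandwidth)
    }
    if (!is.null(covariate_fn)) {
      z <- tibble::as_tibble(covariate_fn(locs, img))
      names(z) <- ifelse(startsWith(names(z), "z_"), names(z),
                         paste0("z_", names(z)))
      block <- dplyr::bind_cols(block, z)
    }
    rows[[i]] <- block
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "basis") <- basis
  attr(out, "target") <- target
  attr(out, "sources") <- sources
  out
}

feature_cols <- function(data, sources, P) {
  unlist(lapply(sources, function(src) paste0("q_", src, "_", seq_len(P))))
}

covariate_cols <- function(data) {
  grep("^z_", names(data), value = TRUE)
}
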