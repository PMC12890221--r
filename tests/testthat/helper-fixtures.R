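# shared fixtures: small studies and quiet fitting wrappers

tiny_cells <- function() {
  tibble::tibble(
    x = c(10, 20, 30, 40, 15, 25),
    y = c(10, 20, 30, 40, 15, 25),
    cell_type = c("T", "B", "T", "T", "B", "T"),
    image_id = c("img1", "img1", "img1", "img1", "img2", "img2"),
    patient_id = "pat1",
    cohort_id = "grp1")
}

small_window <- function(S = 1000) {
  tibble::tibble(x_min = 0, x_max = S, y_min = 0, y_max = S)
}

# a small simulated study for model tests (4 patients x 2 images)
small_sim <- function(seed = 42, n_patients = 4, images_per_patient = 2,
                      source_count = 150, target_count = 50, ...) {
  cfg <- sic_sim_config(n_patients = n_patients,
                        images_per_patient = images_per_patient,
                        source_count = source_count,
                        target_count = target_count, ...)
  simulate_study(cfg, seed = seed)
}

# convergence warnings are expected at reduced sampler settings
fit_hier_quiet <- function(...) suppressWarnings(fit_sic_hier(...))
fit_flat_quiet <- function(...) suppressWarnings(fit_sic_flat(...))

# two independent uniform point types on a square (CSR fixture)
csr_cells <- function(n_from, n_to, S = 500, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    x = runif(n_from + n_to, 0, S),
    y = runif(n_from + n_to, 0, S),
    cell_type = rep(c("A", "B"), c(n_from, n_to))))
}

# independent Cox-de Boor recursion for B-spline evaluation (oracle)
bspline_cox_de_boor <- function(knots, x, ord = 4L) {
  nb <- length(knots) - ord
  N <- matrix(0, length(x), length(knots) - 1L)
  for (i in seq_len(length(knots) - 1L)) {
    N[, i] <- as.numeric(knots[i] <= x & x < knots[i + 1L])
  }
  for (k in 2:ord) {
    Nk <- matrix(0, length(x), length(knots) - k)
    for (i in seq_len(length(knots) - k)) {
      d1 <- knots[i + k - 1L] - knots[i]
      d2 <- knots[i + k] - knots[i + 1L]
      t1 <- if (d1 > 0) (x - knots[i]) / d1 * N[, i] else 0
      t2 <- if (d2 > 0) (knots[i + k] - x) / d2 * N[, i + 1L] else 0
      Nk[, i] <- t1 + t2
    }
    N <- Nk
  }
  N[, seq_len(nb), drop = FALSE]
}
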