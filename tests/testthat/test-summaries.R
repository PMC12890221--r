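# a hand-built fit object with known coefficient draws: no MCMC needed
fake_fit <- function(S = 200, basis = sic_basis(), seed = 1) {
  withr::local_seed(seed)
  images <- c("imgA", "imgB", "imgC", "imgD")
  patients <- c("p1", "p2")
  nofm <- c(1L, 1L, 2L, 2L)
  psi <- array(rnorm(S * 1 * basis$P, 0, 0.3), c(S, 1, basis$P),
               dimnames = list(NULL, "c1", NULL))
  gam <- array(rnorm(S * 2 * basis$P, 0, 0.3), c(S, 2, basis$P),
               dimnames = list(NULL, patients, NULL))
  del <- array(rnorm(S * 4 * basis$P, 0, 0.3), c(S, 4, basis$P),
               dimnames = list(NULL, images, NULL))
  structure(list(model = "hierarchical", basis = basis,
                 sources = "src", target = "tgt", images = images,
                 patients = patients, cohorts = "c1", nofm = nofm,
                 gofn = c(1L, 1L), beta0_draws = matrix(0, S, 4),
                 sigma_draws = matrix(0.3, S, 3,
                                      dimnames = list(NULL,
                                        c("sigma_cohort", "sigma_patient",
                                          "sigma_image"))),
                 psi_draws = psi, gamma_draws = gam, delta_draws = del,
                 diagnostics = list(max_rhat = 1, min_ess = S,
                                    divergences = 0L, accept_rate = 1,
                                    chains = 1, warmup = 0, draws = S)),
            class = "sic_fit")
}

test_that("curve draws equal draw-by-draw basis expansion", {
  fit <- fake_fit(S = 50)
  g <- seq(0, 150, by = 10)
  cd <- sic_curves(fit, "patient", unit = "p2", grid = g)
  B <- basis_matrix(fit$basis, g)
  for (s in c(1, 17, 50)) {
    expect_equal(cd[s, ], drop(B %*% fit$gamma_draws[s, 2, ]))
  }
  # zero coefficients give a zero row
  fit$delta_draws[3, 1, ] <- 0
  expect_equal(sic_curves(fit, "image", unit = "imgA", grid = g)[3, ],
               rep(0, length(g)))
  expect_error(sic_curves(fit, "image", unit = "nope"), "Unknown")
})

test_that("simultaneous band has exact degenerate and width properties", {
  g <- seq(25, 150, by = 5)
  one <- matrix(rep(sin(g / 20), each = 50), 50, length(g))
  attr(one, "grid") <- g
  band <- simultaneous_band(one)
  expect_equal(band$lower, band$mean)     # all draws identical: width 0
  expect_equal(band$upper, band$mean)
  expect_error(simultaneous_band(one[1, , drop = FALSE]), "2 draws")

  # i.i.d. standard normal draws: simultaneous multiplier beats 1.96
  withr::local_seed(2)
  iid <- matrix(rnorm(5000 * 50), 5000, 50)
  b2 <- simultaneous_band(iid, level = 0.95)
  expect_gt(attr(b2, "c_mult"), 1.96)

  # never narrower than the pointwise equal-tailed interval anywhere
  for (rep in 1:3) {
    m <- matrix(rnorm(400 * 20), 400, 20) %*% diag(runif(20, 0.5, 2))
    bb <- simultaneous_band(m, level = 0.9)
    lo <- apply(m, 2, quantile, 0.05)
    hi <- apply(m, 2, quantile, 0.95)
    expect_true(all(bb$lower <= lo + 1e-12))
    expect_true(all(bb$upper >= hi - 1e-12))
  }
})

test_that("simultaneous band attains joint coverage on functional draws", {
  # smooth correlated draws (Gaussian-process-like): fresh-draw joint
  # coverage within 3 points of nominal at 5000 draws
  g <- seq_len(50)
  K <- exp(-outer(g, g, "-")^2 / (2 * 8^2)) + diag(1e-8, 50)
  L <- chol(K)
  withr::local_seed(3)
  draw_mat <- function(n) matrix(rnorm(n * 50), n, 50) %*% L
  fit_draws <- draw_mat(5000)
  band <- simultaneous_band(fit_draws, level = 0.95)
  fresh <- draw_mat(5000)
  inside <- vapply(seq_len(nrow(fresh)), function(i) {
    all(fresh[i, ] >= band$lower & fresh[i, ] <= band$upper)
  }, logical(1))
  expect_gt(mean(inside), 0.92)
  expect_lt(mean(inside), 0.98)
})

test_that("detection scans the envelopes and is monotone in level", {
  g <- 0:100
  band <- tibble::tibble(distance = g, mean = 0, lower = -1, upper = 1)
  expect_false(detect_interaction(band, c(0, 100))$detected)
  band$lower[g >= 30 & g <= 50] <- 0.1    # positive exclusion on 30-50
  d <- detect_interaction(band, c(0, 100))
  expect_true(d$detected)
  expect_equal(d$sign, "positive")
  expect_equal(range(d$where$distance), c(30, 50))
  expect_false(detect_interaction(band, c(60, 100))$detected)
  expect_error(detect_interaction(band, c(200, 300)), "intersect")

  # monotone in level: detections at 99% are a subset of those at 95%
  withr::local_seed(4)
  for (rep in 1:20) {
    m <- matrix(rnorm(300 * 30, mean = runif(1, -0.2, 0.2)), 300, 30)
    b95 <- simultaneous_band(m, 0.95)
    b99 <- simultaneous_band(m, 0.99)
    d95 <- detect_interaction(b95, c(1, 30))$detected
    d99 <- detect_interaction(b99, c(1, 30))$detected
    expect_true(!d99 || d95)
  }
})

test_that("summary measures integrate the zero-excluding region", {
  g <- 0:100
  zero <- tibble::tibble(distance = g, mean = 0, lower = -1, upper = 1)
  s0 <- sic_summary_measures(zero, c(0, 100))
  expect_equal(s0$strength, 0)
  expect_equal(s0$persistence, 0)

  # single positive bump with exclusion exactly on the bump
  mean_c <- ifelse(g >= 40 & g <= 60, 0.5, 0)
  band <- tibble::tibble(distance = g, mean = mean_c,
                         lower = mean_c - 0.2, upper = mean_c + 0.2)
  s1 <- sic_summary_measures(band, c(0, 100))
  expect_equal(s1$persistence, 20 / 100, tolerance = 0.06)
  expect_equal(s1$peak_value, 0.5)
  expect_equal(s1$strength, 0.5 * 20, tolerance = 0.1 * 10)

  # peak of a known unimodal curve at its analytic maximizer
  quad <- exp(-(g - 37)^2 / 500)
  band2 <- tibble::tibble(distance = g, mean = quad, lower = quad - 0.1,
                          upper = quad + 0.1)
  expect_equal(sic_summary_measures(band2, c(0, 100))$peak_distance, 37)
})

test_that("heterogeneity MADs match the direct deviation computation", {
  fit <- fake_fit(S = 150, seed = 9)
  g <- seq(25, 150, by = 5)
  got <- sic_heterogeneity(fit, grid = g)
  B <- basis_matrix(fit$basis, g)
  coh <- drop(B %*% apply(fit$psi_draws[, 1, ], 2, mean))
  pat <- apply(fit$gamma_draws, c(2, 3), mean) %*% t(B)
  img <- apply(fit$delta_draws, c(2, 3), mean) %*% t(B)
  want_b <- median(abs(sweep(pat, 2, coh)))
  want_w <- median(abs(img - pat[fit$nofm, ]))
  expect_equal(got$between_patient_mad, want_b)
  expect_equal(got$within_patient_mad, want_w)

  # identical patient curves give zero between-patient MAD
  fit2 <- fit
  fit2$gamma_draws[, 2, ] <- fit2$gamma_draws[, 1, ]
  fit2$psi_draws[, 1, ] <- fit2$gamma_draws[, 1, ]
  expect_equal(sic_heterogeneity(fit2, grid = g)$between_patient_mad, 0)
})

test_that("generator heterogeneity is ordered by the patient-level spread", {
  # larger generating sigma_patient yields larger between-patient MAD of
  # the true coefficient curves in nearly all paired replicates
  basis <- sic_basis()
  g <- seq(25, 150, by = 5)
  B <- basis_matrix(basis, g)
  wins <- vapply(1:20, function(r) {
    mads <- vapply(c(0.5, 0.05), function(sp) {
      cfg <- sic_sim_config(n_patients = 8, images_per_patient = 1,
                            sigma_patient = sp, sigma_image = 0.01)
      tr <- draw_hier_coefficients(cfg, seed = 700 + r)
      pat <- tr$gamma %*% t(B)
      coh <- drop(B %*% tr$psi)
      median(abs(sweep(pat, 2, coh)))
    }, numeric(1))
    mads[1] > mads[2]
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("draws export is columnar and reconstructs the arrays", {
  fit <- fake_fit(S = 40)
  dp <- withr::local_tempfile(fileext = ".csv")
  jp <- withr::local_tempfile(fileext = ".json")
  write_sic_fit(fit, dp, jp)
  tab <- readr::read_csv(dp, show_col_types = FALSE)
  expect_equal(nrow(tab), 40 * (1 + 2 + 4) * 6 + 40 * 3)
  sl <- tab[tab$level == "image" & tab$unit == "imgB" &
              tab$basis_index == 2, ]
  expect_equal(sl$value, fit$delta_draws[, 2, 2])
  diag <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(diag$divergences, 0L)
})

test_that("tidy and glance expose coefficient and sampler summaries", {
  fit <- fake_fit(S = 100)
  td <- tidy(fit)
  expect_true(all(c("term", "level", "estimate", "conf.low") %in%
                    names(td)))
  expect_equal(sum(td$level == "image"), 4 * 6)
  expect_equal(sum(td$level == "hyper"), 3)
  gl <- glance(fit)
  expect_equal(gl$n_images, 4L)
  expect_equal(gl$n_draws, 100L)
})
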