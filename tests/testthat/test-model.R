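# shared small fitted study for the heavier posterior checks
sim8 <- small_sim(seed = 42)
dat8 <- build_sic_data(sim8$study, "target", "source",
                       sim8$config$basis, seed = 7)

test_that("log-intensity predictor equals the explicit dot product", {
  withr::local_seed(3)
  row <- dat8[5, ]
  delta <- rnorm(6)
  got <- log_intensity(list(beta0 = -7, beta = numeric(0), delta = delta),
                       row)
  want <- -7 + sum(as.numeric(row[paste0("q_source_", 1:6)]) * delta)
  expect_equal(got, want)
  expect_equal(
    log_intensity(list(beta0 = -7, delta = rep(0, 6)), row), -7)
  expect_error(
    log_intensity(list(beta0 = 0, delta = rep(0, 4)), row), "length")
})

test_that("model log posterior matches an independent evaluation", {
  # independently coded Bernoulli-logit likelihood + Gaussian priors on
  # the natural scale; compared through differences between parameter
  # points so normalizing constants cancel
  dat <- dplyr::bind_rows(
    head(dat8[dat8$image_id == "img001", ], 50),
    head(dat8[dat8$image_id == "img002", ], 50))
  attr(dat, "basis") <- attr(dat8, "basis")
  attr(dat, "sources") <- "source"
  attr(dat, "target") <- "target"
  hier <- sim8$study$hierarchy[1:2, ]
  pri <- sic_priors()
  mod <- spatsic:::make_hier_model(dat, hier, pri)

  oracle <- function(theta) {
    M <- 2; N <- 1; G <- 1; KP <- 6
    beta0 <- theta[1:2]
    psi <- matrix(theta[2 + 1:6], G, KP)
    graw <- matrix(theta[8 + 1:6], N, KP)
    draw <- matrix(theta[14 + 1:12], M, KP)
    ls <- theta[27:29]
    sc <- exp(ls[1]); sp <- exp(ls[2]); si <- exp(ls[3])
    gam <- psi + sp * graw
    del <- gam[rep(1, 2), ] + si * draw
    lp <- 0
    for (i in seq_len(nrow(dat))) {
      m <- match(dat$image_id[i], c("img001", "img002"))
      eta <- beta0[m] + dat$offset[i] +
        sum(as.numeric(dat[i, paste0("q_source_", 1:6)]) * del[m, ])
      lp <- lp + stats::dbinom(dat$response[i], 1, stats::plogis(eta),
                               log = TRUE)
    }
    lp + sum(stats::dnorm(beta0, 0, pri$scale_intercept, log = TRUE)) +
      sum(stats::dnorm(psi, 0, sc, log = TRUE)) +
      sum(stats::dnorm(graw, 0, 1, log = TRUE)) +
      sum(stats::dnorm(draw, 0, 1, log = TRUE)) +
      sum(stats::dnorm(c(sc, sp, si), 0, pri$scale_sigma, log = TRUE)) +
      sum(ls)                               # half-normal + log-jacobian
  }

  withr::local_seed(9)
  pts <- lapply(1:10, function(i) rnorm(mod$D, 0, 0.7))
  lp_mod <- vapply(pts, function(p) mod$lp_grad(p)$lp, numeric(1))
  lp_ora <- vapply(pts, oracle, numeric(1))
  expect_lt(max(abs((lp_mod - lp_mod[1]) - (lp_ora - lp_ora[1]))), 1e-8)
})

test_that("analytic gradients match central finite differences", {
  dat <- dat8[1:120, ]
  attr(dat, "basis") <- attr(dat8, "basis")
  attr(dat, "sources") <- "source"
  attr(dat, "target") <- "target"
  mod <- spatsic:::make_hier_model(dat, sim8$study$hierarchy[1:2, ])
  withr::local_seed(4)
  theta <- rnorm(mod$D, 0, 0.5)
  g <- mod$lp_grad(theta)$grad
  eps <- 1e-6
  for (j in sample.int(mod$D, 12)) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    fd <- (mod$lp_grad(up)$lp - mod$lp_grad(dn)$lp) / (2 * eps)
    expect_lt(abs(fd - g[j]), 1e-4 * max(1, abs(g[j])))
  }
})

test_that("covariate columns enter the likelihood with correct gradients", {
  simc <- small_sim(seed = 61, n_patients = 2, images_per_patient = 1,
                    source_count = 60, target_count = 30)
  datc <- build_sic_data(simc$study, "target", "source",
                         simc$config$basis, compartment_from = "source",
                         compartment_bandwidth = 100, seed = 5)
  expect_true("z_compartment" %in% names(datc))
  expect_true(all(datc$z_compartment %in% 0:1))
  mod <- spatsic:::make_hier_model(datc, simc$study$hierarchy)
  expect_equal(mod$J, 1L)
  withr::local_seed(6)
  theta <- rnorm(mod$D, 0, 0.4)
  g <- mod$lp_grad(theta)$grad
  eps <- 1e-6
  for (j in c(mod$idx$beta, sample.int(mod$D, 6))) {
    up <- theta; up[j] <- up[j] + eps
    dn <- theta; dn[j] <- dn[j] - eps
    fd <- (mod$lp_grad(up)$lp - mod$lp_grad(dn)$lp) / (2 * eps)
    expect_lt(abs(fd - g[j]), 1e-4 * max(1, abs(g[j])))
  }
})

test_that("degenerate single-image hierarchy collapses across levels", {
  # one cohort / one patient / one image, dense enough that the
  # likelihood dominates the image level. The patient level collapses
  # onto the image level within the posterior spread of their gap; the
  # cohort level tracks the same curve shape but keeps the deliberate
  # prior shrinkage of the half-Normal hierarchy scales (with a single
  # image the scales carry no information, so the cohort curve is a
  # shrunken copy, not an equal one).
  simd <- small_sim(seed = 23, n_patients = 1, images_per_patient = 1,
                    source_count = 200, target_count = 500)
  dat <- build_sic_data(simd$study, "target", "source",
                        simd$config$basis, seed = 3)
  fh <- fit_hier_quiet(dat, simd$study$hierarchy, chains = 2,
                       warmup = 500, draws = 500, seed = 5,
                       max_leapfrog = 24)
  g <- seq(25, 150, by = 2.5)
  cur_psi <- sic_curves(fh, "cohort", grid = g)
  cur_gam <- sic_curves(fh, "patient", grid = g)
  cur_del <- sic_curves(fh, "image", grid = g)
  gap_gd <- abs(colMeans(cur_gam) - colMeans(cur_del))
  sd_gd <- apply(cur_gam - cur_del, 2, sd)
  expect_true(all(gap_gd < pmax(sd_gd, 1e-3)))
  expect_gt(cor(colMeans(cur_psi), colMeans(cur_del)), 0.9)
  expect_lte(max(abs(colMeans(cur_psi))), max(abs(colMeans(cur_del))))
  # flat fit on the same image agrees with the hierarchical image level
  ff <- fit_flat_quiet(dat, chains = 2, warmup = 500, draws = 500,
                       seed = 6, max_leapfrog = 24)
  cur_flat <- sic_curves(ff, "image", grid = g)
  expect_lt(max(abs(colMeans(cur_flat) - colMeans(cur_del))), 0.1)
})

test_that("prior domination shrinks all interaction coefficients to zero", {
  pri <- sic_priors(scale_sigma = 1e-3)
  fit <- fit_hier_quiet(dat8, sim8$study$hierarchy, priors = pri,
                        chains = 1, warmup = 300, draws = 300, seed = 2)
  expect_lt(max(abs(apply(fit$delta_draws, c(2, 3), mean))), 0.05)
  expect_lt(max(abs(apply(fit$psi_draws, c(2, 3), mean))), 0.05)
})

test_that("interaction posterior reverts to the prior without likelihood", {
  # an image whose source type has zero cells: the feature block is
  # identically zero, so its coefficients carry no likelihood and the
  # flat posterior must reproduce the Normal(0, scale_flat^2) prior
  pts <- simulate_source(small_window(1500), 60, seed = 13)
  cells <- dplyr::mutate(pts, cell_type = "target", image_id = "i1",
                         patient_id = "p1", cohort_id = "c1")
  st <- sic_study(cells, windows = dplyr::bind_cols(
    tibble::tibble(image_id = "i1"), small_window(1500)))
  dat <- build_sic_data(st, "target", "source", sic_basis(), seed = 4)
  expect_true(all(dat[paste0("q_source_", 1:6)] == 0))
  ff <- fit_flat_quiet(dat, chains = 2, warmup = 500, draws = 1000,
                       seed = 8, max_leapfrog = 24)
  m <- apply(ff$delta_draws[, 1, ], 2, mean)
  s <- apply(ff$delta_draws[, 1, ], 2, sd)
  expect_true(all(abs(m) < 1.2))          # prior mean 0
  expect_true(all(s > 3) && all(s < 7))   # prior sd 5
})

test_that("dataset construction is invariant to cell-row permutation", {
  perm <- sim8$study$cells[sample.int(nrow(sim8$study$cells)), ]
  st2 <- sic_study(perm, windows = sim8$study$windows)
  dat2 <- build_sic_data(st2, "target", "source", sim8$config$basis,
                         seed = 7)
  key <- function(d) dplyr::arrange(d, image_id, x, y, response)
  expect_equal(key(dat2), key(dat8), ignore_attr = TRUE)
})

test_that("hierarchical pooling shrinks image estimates relative to flat fits", {
  fh <- fit_hier_quiet(dat8, sim8$study$hierarchy, chains = 2,
                       warmup = 300, draws = 300, seed = 10)
  ff <- fit_flat_quiet(dat8, chains = 2, warmup = 300, draws = 300,
                       seed = 11)
  del_h <- apply(fh$delta_draws, c(2, 3), mean)
  del_f <- apply(ff$delta_draws, c(2, 3), mean)
  # spread of image-level estimates within patients: pooled <= flat
  spread <- function(del) {
    pat <- sim8$study$hierarchy$patient_id
    mean(vapply(unique(pat), function(p) {
      rows <- del[pat == p, , drop = FALSE]
      mean(apply(rows, 2, stats::var))
    }, numeric(1)))
  }
  expect_lte(spread(del_h), spread(del_f))
})
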