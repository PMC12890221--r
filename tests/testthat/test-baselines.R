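test_that("G-cross matches a brute-force border-corrected loop", {
  w <- small_window(500)
  cells <- csr_cells(60, 80, seed = 3)
  r <- seq(0, 120, by = 4)
  got <- gcross_estimate(cells, "A", "B", r, w)
  fp <- cells[cells$cell_type == "A", ]
  tp <- cells[cells$cell_type == "B", ]
  nn <- vapply(seq_len(nrow(fp)), function(i) {
    min(sqrt((fp$x[i] - tp$x)^2 + (fp$y[i] - tp$y)^2))
  }, numeric(1))
  bd <- pmin(fp$x, 500 - fp$x, fp$y, 500 - fp$y)
  want <- vapply(r, function(ri) {
    ok <- bd >= ri
    if (!any(ok)) NA_real_ else mean(nn[ok] <= ri)
  }, numeric(1))
  expect_equal(got$est, want)

  # single from-point: step function at its nearest-neighbour distance
  one <- tibble::tibble(x = c(250, 250), y = c(250, 280),
                        cell_type = c("A", "B"))
  g1 <- gcross_estimate(one, "A", "B", c(10, 29, 30, 31, 60), w)
  expect_equal(g1$est, c(0, 0, 1, 1, 1))
  # saturation when to-points are everywhere dense
  dense <- csr_cells(20, 2000, seed = 4)
  gd <- gcross_estimate(dense, "A", "B", c(30, 60), w)
  expect_true(all(gd$est > 0.99))
  # zero to-points: identically zero
  no_to <- cells[cells$cell_type == "A", ]
  expect_true(all(gcross_estimate(no_to, "A", "B", r, w)$est == 0))
})

test_that("K-cross (L-scale) matches a brute-force translation-weighted loop", {
  w <- small_window(500)
  cells <- csr_cells(50, 70, seed = 5)
  r <- seq(5, 120, by = 5)
  got <- kcross_estimate(cells, "A", "B", r, w)
  fp <- cells[cells$cell_type == "A", ]
  tp <- cells[cells$cell_type == "B", ]
  want <- vapply(r, function(ri) {
    acc <- 0
    for (i in seq_len(nrow(fp))) for (j in seq_len(nrow(tp))) {
      dx <- abs(fp$x[i] - tp$x[j]); dy <- abs(fp$y[i] - tp$y[j])
      if (sqrt(dx^2 + dy^2) <= ri) {
        acc <- acc + 500^2 / ((500 - dx) * (500 - dy))
      }
    }
    sqrt(acc * 500^2 / (nrow(fp) * nrow(tp)) / pi)
  }, numeric(1))
  expect_equal(got$est, want, tolerance = 1e-12)
  expect_error(kcross_estimate(fp, "A", "B", r, w), "present")

  # single pair: K jumps at the pair distance
  pair <- tibble::tibble(x = c(100, 140), y = c(100, 100),
                         cell_type = c("A", "B"))
  kp <- kcross_estimate(pair, "A", "B", c(30, 39, 41, 80), w)
  expect_equal(kp$est[1:2], c(0, 0))
  expect_true(all(kp$est[3:4] > 0))
})

test_that("L-cross is approximately r under complete spatial randomness", {
  w <- small_window(1000)
  r <- seq(10, 100, by = 10)
  ests <- vapply(1:40, function(s) {
    kcross_estimate(csr_cells(80, 80, S = 1000, seed = 400 + s),
                    "A", "B", r, w)$est
  }, numeric(length(r)))
  expect_lt(max(abs(rowMeans(ests) - r)), 2.5)
})

test_that("envelope tests are reproducible, calibrated and powerful", {
  w <- small_window(1000)
  # determinism
  cells <- csr_cells(40, 60, S = 1000, seed = 7)
  e1 <- envelope_test(cells, "A", "B", w, "gcross", n_sim = 99, seed = 5)
  e2 <- envelope_test(cells, "A", "B", w, "gcross", n_sim = 99, seed = 5)
  expect_identical(e1$lower, e2$lower)
  expect_identical(e1$rejected, e2$rejected)
  expect_error(envelope_test(cells, "A", "B", w, "gcross", n_sim = 10),
               "n_sim")
  # degenerate counts are untestable, not an error
  eu <- envelope_test(cells[cells$cell_type == "A", ], "A", "B", w,
                      "gcross", n_sim = 99, seed = 1)
  expect_true(eu$untestable)

  # power: a strongly clustered pattern is rejected
  b <- sic_basis()
  src <- simulate_source(w, 60, seed = 21)
  tgt <- simulate_target(src, sic_bump_coefficients(b, height = 1.5), b,
                         log(80 / 1e6), w, seed = 22, grid_n = 64)
  clus <- dplyr::bind_rows(dplyr::mutate(src, cell_type = "B"),
                           dplyr::mutate(tgt, cell_type = "A"))
  ec <- envelope_test(clus, "A", "B", w, "gcross", n_sim = 99, seed = 9)
  expect_true(ec$rejected)
})

test_that("envelope type-I error is within the global-rank range", {
  # CSR truth, 200 replicates at n_sim = 99: rejection rate in [2%, 9%]
  w <- small_window(800)
  rej <- vapply(1:200, function(s) {
    cells <- csr_cells(50, 50, S = 800, seed = 5000 + s)
    envelope_test(cells, "A", "B", w, "gcross", n_sim = 99,
                  r = seq(0, 75, by = 3), seed = 6000 + s)$rejected
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("replicate scoring matches hand-computed flags", {
  g <- 0:50
  band_pos <- tibble::tibble(distance = g, mean = 0.5, lower = 0.2,
                             upper = 0.8)
  band_null <- tibble::tibble(distance = g, mean = 0, lower = -0.4,
                              upper = 0.4)
  truth0 <- function(s) rep(0, length(s))
  truth_in <- function(s) rep(0.3, length(s))
  # detected positive interaction, truth inside the band
  s1 <- score_replicate(band_pos, truth_in, c(0, 50))
  expect_true(s1$detected); expect_true(s1$covered)
  expect_false(s1$type1_flag)
  # null truth, no detection
  s2 <- score_replicate(band_null, truth0, c(0, 50), null_truth = TRUE)
  expect_false(s2$detected); expect_false(s2$type1_flag)
  expect_true(s2$covered)
  # null truth with a spurious detection flags a type-I error
  s3 <- score_replicate(band_pos, truth0, c(0, 50), null_truth = TRUE)
  expect_true(s3$type1_flag); expect_false(s3$covered)
  # band equal to truth +/- epsilon covers
  eps_band <- tibble::tibble(distance = g, mean = 0.3, lower = 0.3 - 1e-6,
                             upper = 0.3 + 1e-6)
  expect_true(score_replicate(eps_band, truth_in, c(0, 50))$covered)
  # envelope results score by their rejection flag
  fake_env <- structure(list(rejected = TRUE), class = "sic_envelope")
  s5 <- score_replicate(fake_env, truth0, c(0, 50), null_truth = TRUE)
  expect_true(s5$detected); expect_true(s5$type1_flag)
  expect_true(is.na(s5$covered))
})

test_that("benchmark plumbing aggregates and is order-invariant", {
  cond <- tibble::tibble(source_count = c(100, 50),
                         target_count = c(50, 30),
                         images_per_patient = c(1, 1))
  bm <- run_benchmark(cond, replicates = 1, methods = "gcross",
                      seed = 77, n_patients = 2)
  expect_s3_class(bm, "sic_benchmark")
  expect_equal(nrow(bm$summary), 2L)
  expect_true(all(bm$summary$median_power >= 0 &
                    bm$summary$median_power <= 1))
  expect_true(all(bm$replicates$power >= 0 & bm$replicates$power <= 1))
  # null-only runs: the power column reproduces the type-I column
  bn <- run_benchmark(cond[1, ], replicates = 2, methods = "gcross",
                      seed = 78, n_patients = 2, scenarios = "null")
  expect_equal(bn$replicates$power, bn$replicates$type1)
  # seeding contract: each (condition, replicate) pair is self-contained,
  # so rerunning a prefix of the replicates reproduces the same values
  b2 <- run_benchmark(cond[1, ], replicates = 2, methods = "gcross",
                      seed = 79, n_patients = 2)
  b1 <- run_benchmark(cond[1, ], replicates = 1, methods = "gcross",
                      seed = 79, n_patients = 2)
  expect_equal(dplyr::filter(b2$replicates, replicate == 1),
               b1$replicates)
})
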