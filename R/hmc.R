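# Adaptive Hamiltonian Monte Carlo on an unconstrained parameter vector.
# Leapfrog integrator, dual-averaging step-size adaptation (target accept
# 0.8), diagonal mass-matrix estimation during warmup, and uniformly
# jittered trajectory lengths. Kept internal: models in this package
# supply a joint log-density-and-gradient closure.

log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

hmc_chain <- function(lp_grad, init, warmup, draws, seed,
                      L_max = 12L, target_accept = 0.8, eps0 = 0.05) {
  withr::local_seed(seed)
  D <- length(init)
  theta <- init
  cur <- lp_grad(theta)
  if (!is.finite(cur$lp)) stop("Non-finite log posterior at init.",
                               call. = FALSE)
  inv_mass <- rep(1, D)

  # dual averaging state
  mu <- log(10 * eps0)
  log_eps <- log(eps0)
  log_eps_bar <- 0
  Hbar <- 0
  da_gamma <- 0.05; t0 <- 10; kappa <- 0.75; da_count <- 0

  # warmup: two variance-estimation windows, mass updated at the end of
  # each, step-size adaptation restarted after every update
  w_ends <- unique(floor(c(0.5, 0.85) * warmup))
  w_start <- floor(0.15 * warmup)
  L_min <- max(1L, floor(L_max / 2))
  mean_acc <- rep(0, D); m2_acc <- rep(0, D); n_acc <- 0

  total <- warmup + draws
  out <- matrix(NA_real_, draws, D)
  lp_out <- numeric(draws)
  divergences <- 0L
  acc_sum <- 0; acc_n <- 0

  for (it in seq_len(total)) {
    eps <- exp(if (it <= warmup) log_eps else log_eps_bar)
    L <- if (L_max > L_min) {
      L_min + sample.int(L_max - L_min + 1L, 1L) - 1L
    } else L_min
    p0 <- stats::rnorm(D) / sqrt(inv_mass)
    th <- theta; p <- p0; g <- cur$grad
    H0 <- -cur$lp + 0.5 * sum(p0^2 * inv_mass)
    ok <- TRUE
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      th <- th + eps * p * inv_mass
      prop <- lp_grad(th)
      if (!is.finite(prop$lp) || !all(is.finite(prop$grad))) { ok <- FALSE; break }
      g <- prop$grad
      p <- p + 0.5 * eps * g
    }
    if (ok) {
      H1 <- -prop$lp + 0.5 * sum(p^2 * inv_mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > 1000) { ok <- FALSE }
    }
    if (ok) {
      a <- min(1, exp(-dH))
      if (stats::runif(1) < a) { theta <- th; cur <- prop }
    } else {
      a <- 0
      divergences <- divergences + as.integer(it > warmup)
    }
    if (it > warmup) { acc_sum <- acc_sum + a; acc_n <- acc_n + 1 }

    if (it <= warmup) {
      da_count <- da_count + 1
      Hbar <- (1 - 1 / (da_count + t0)) * Hbar +
        (target_accept - a) / (da_count + t0)
      log_eps <- mu - sqrt(da_count) / da_gamma * Hbar
      eta <- da_count^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      if (it > w_start && it <= max(w_ends)) {
        n_acc <- n_acc + 1
        dlt <- theta - mean_acc
        mean_acc <- mean_acc + dlt / n_acc
        m2_acc <- m2_acc + dlt * (theta - mean_acc)
      }
      if (it %in% w_ends && n_acc > 10) {
        v <- m2_acc / (n_acc - 1)
        inv_mass <- (n_acc / (n_acc + 5)) * v +
          1e-3 * (5 / (n_acc + 5))
        inv_mass[inv_mass < 1e-8] <- 1e-8
        mean_acc[] <- 0; m2_acc[] <- 0; n_acc <- 0
        # restart step-size adaptation around the current step size
        mu <- log(10 * exp(log_eps))
        Hbar <- 0; da_count <- 0; log_eps_bar <- log_eps
      }
    } else {
      out[it - warmup, ] <- theta
      lp_out[it - warmup] <- cur$lp
    }
  }
  list(draws = out, lp = lp_out, accept_rate = acc_sum / max(acc_n, 1),
       divergences = divergences, step_size = exp(log_eps_bar),
       inv_mass = inv_mass)
}

hmc_sample <- function(lp_grad, init_fn, chains, warmup, draws, seed,
                       L_max = 12L, target_accept = 0.8) {
  res <- lapply(seq_len(chains), function(ch) {
    hmc_chain(lp_grad, init_fn(derive_seed(seed, 1000L + ch)),
              warmup, draws, seed = derive_seed(seed, ch),
              L_max = L_max, target_accept = target_accept)
  })
  list(chains = res,
       draws = do.call(rbind, lapply(res, `[[`, "draws")),
       accept_rate = mean(vapply(res, `[[`, numeric(1), "accept_rate")),
       divergences = sum(vapply(res, `[[`, integer(1), "divergences")))
}

# split-Rhat over a draws x chains matrix (one parameter)
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4 || stats::var(as.vector(x)) == 0) return(1)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# basic effective sample size (Geyer initial monotone sequence, pooled)
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 8) return(n * m)
  rho_sum <- 0
  ac <- rowMeans(vapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    s <- stats::var(x[, j])
    if (s == 0) return(rep(0, n))
    a <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    a / a[1]
  }, numeric(min(n, 201))))
  # sum paired autocorrelations while positive
  t <- 1
  while (t + 1 < length(ac)) {
    pair <- ac[t + 1] + ac[t + 2]
    if (is.na(pair) || pair < 0) break
    rho_sum <- rho_sum + pair
    t <- t + 2
  }
  max(1, (n * m) / (1 + 2 * rho_sum))
}
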