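test_that("reservoir construction honours spectral radius, scaling bounds and seeds", {
  for (sr in c(0.8, 0.9, 0.95, 0.99)) {
    rt <- init_reservoir(4, 80, SR = sr, input_scaling = 0.5, seed = 42)
    rho <- max(Mod(eigen(rt$Wres, only.values = TRUE)$values))
    expect_lt(abs(rho - sr), 1e-6)
  }
  rt1 <- init_reservoir(3, 50, seed = 7)
  rt2 <- init_reservoir(3, 50, seed = 7)
  expect_identical(rt1$Win, rt2$Win)
  expect_identical(rt1$Wres, rt2$Wres)
  expect_true(all(abs(rt1$Win) <= rt1$input_scaling))
  expect_error(init_reservoir(0, 10), "K")
})

test_that("reservoir states are zero for silence, bounded, and forget initial impulses", {
  rt <- init_reservoir(2, 60, SR = 0.9, seed = 1)
  X0 <- run_reservoir(rt, matrix(0, 30, 2))
  expect_true(all(X0 == 0))

  set.seed(2)
  X <- run_reservoir(rt, matrix(stats::rnorm(400), 200, 2))
  expect_true(all(X > -1 & X < 1))

  # single impulse then silence: state norm decays below 1e-6
  U <- rbind(c(5, 5), matrix(0, 400, 2))
  Xi <- run_reservoir(rt, U)
  norms <- sqrt(rowSums(Xi^2))
  expect_lt(norms[length(norms)], 1e-6)

  expect_error(run_reservoir(rt, matrix(0, 5, 3)), "dimensionality")
})

test_that("echo-state property: different initial conditions converge under the same drive", {
  rt <- init_reservoir(2, 50, SR = 0.9, seed = 3)
  set.seed(4)
  U <- matrix(stats::rnorm(1000), 500, 2)
  # drive one copy from zero state and one from a perturbed start by
  # prepending a burst only to the second
  X1 <- run_reservoir(rt, U)
  X2 <- run_reservoir(rt, rbind(matrix(3, 5, 2), U))
  gap <- sqrt(sum((X1[500, ] - X2[505, ])^2))
  expect_lt(gap, 1e-6)
})

test_that("ridge readout recovers planted weights and matches the normal-equations oracle", {
  set.seed(5)
  X <- matrix(stats::rnorm(100 * 5), 100, 5)
  Wstar <- matrix(stats::rnorm(15), 5, 3)
  W <- learn_readout(X, X %*% Wstar, regularization = 0)
  expect_lt(max(abs(W - Wstar)), 1e-8)

  for (i in 1:5) {
    Xs <- matrix(stats::rnorm(100), 20, 5)
    D <- matrix(stats::rnorm(40), 20, 2)
    eps <- stats::runif(1, 1e-6, 1)
    W <- learn_readout(Xs, D, eps)
    oracle <- solve(t(Xs) %*% Xs + eps * diag(5)) %*% t(Xs) %*% D
    expect_lt(max(abs(W - oracle)), 1e-10)
    # defining identity holds to machine precision
    expect_lt(max(abs((t(Xs) %*% Xs + eps * diag(5)) %*% W - t(Xs) %*% D)), 1e-9)
  }

  # shrinkage is monotone in the ridge term
  norms <- vapply(c(1e-6, 1, 1e6), function(e)
    norm(learn_readout(X, X %*% Wstar + 0.1, e), "F"), numeric(1))
  expect_true(all(diff(norms) < 0))

  # rank-deficient states without ridge is refused with advice
  Xr <- cbind(X[, 1], X[, 1], X[, 2])
  expect_error(learn_readout(Xr, X[, 1:2], 0), "regularization > 0")
})

test_that("learned transfer reproduces a known linear map and beats an untrained readout", {
  set.seed(6)
  K <- 4
  # symmetric positive-definite map: identifiable from the two frame
  # distributions alone (a rotation component would not be)
  R <- matrix(stats::rnorm(K * K, sd = 0.1), K, K)
  A <- diag(c(1.3, 0.8, 1.1, 0.9)) + (R + t(R)) / 2
  donor <- lapply(1:10, function(i)
    feature_seq(matrix(stats::rnorm(120 * K), 120, K), "toy", label = "d",
                clip_id = paste0("d", i)))
  limited <- lapply(1:4, function(i)
    feature_seq(matrix(stats::rnorm(120 * K), 120, K) %*% A, "toy", label = "l",
                clip_id = paste0("l", i)))
  # i.i.d. frames per clip: the clip-count shrinkage rationale does not
  # apply, so it is disabled for the exact-recovery check
  rt <- learn_transfer(donor, limited, esn_grid("small"), seed = 8,
                       shrink_prior = 0)

  probe <- matrix(stats::rnorm(200 * K), 200, K)
  out <- apply_transfer(rt, feature_seq(probe, "toy", clip_id = "p"), label = "l")
  expect_equal(ncol(out$values), K)          # N inputs -> N outputs
  expect_true(out$synthetic)
  expect_equal(out$label, "l")
  keep <- (rt$washout + 1):200
  rel_err <- sqrt(mean((out$values - probe[keep, ] %*% A)^2)) /
    sqrt(mean((probe[keep, ] %*% A)^2))
  expect_lt(rel_err, 0.05)

  # untrained (random) readout is at least 10x worse in MSE
  rt_rand <- rt
  set.seed(9)
  rt_rand$Wout <- matrix(stats::rnorm(length(rt$Wout)), nrow(rt$Wout))
  out_r <- apply_transfer(rt_rand, feature_seq(probe, "toy"), label = "l")
  mse_t <- mean((out$values - probe[keep, ] %*% A)^2)
  mse_r <- mean((out_r$values - probe[keep, ] %*% A)^2)
  expect_gt(mse_r / mse_t, 10)

  # zero input -> zero output through the linear readout
  z <- apply_transfer(rt, feature_seq(matrix(0, 50, K), "toy"), label = "l")
  expect_true(all(abs(z$values) < 1e-12))

  expect_error(apply_transfer(init_reservoir(K, 10), probe), "untrained")
})

test_that("augmentation bookkeeping adds exactly the requested synthetic items", {
  set.seed(10)
  mk <- function(lbl, n) lapply(seq_len(n), function(i)
    feature_seq(matrix(stats::rnorm(60 * 2), 60, 2), "toy", label = lbl,
                clip_id = sprintf("%s%02d", lbl, i)))
  corpus <- c(mk("donor", 40), mk("lim", 4))
  pairing <- structure(list(limited_class = "lim", donor_class = "donor",
                            divergence = 1, table = c(donor = 1)),
                       class = "transfer_pairing")
  rt <- learn_transfer(corpus[1:40], corpus[41:44], esn_grid("small"), seed = 2)
  out <- augment_class(corpus, augmentation_plan(pairing, 20), rt, seed = 3)
  labs <- vapply(out, `[[`, "", "label")
  synth <- vapply(out, `[[`, FALSE, "synthetic")
  expect_length(out, 64)
  expect_equal(sum(labs == "lim"), 24)
  expect_equal(sum(synth), 20)
  # originals untouched
  expect_identical(out[1:44], corpus)
  # target 0 is a no-op
  expect_identical(augment_class(corpus, augmentation_plan(pairing, 0), rt), corpus)
  # over-request resamples donors with a message
  expect_message(augment_class(corpus[37:44], augmentation_plan(pairing, 10), rt, seed = 4),
                 "resampling")
})

test_that("transfer moves the donor distribution toward the limited one (divergence drops)", {
  set.seed(11)
  K <- 3
  A <- diag(c(1.4, 0.8, 1.1))
  b <- c(1, -0.5, 0.25)
  donor <- lapply(1:12, function(i)
    feature_seq(matrix(stats::rnorm(150 * K), 150, K), "toy", label = "d",
                clip_id = paste0("d", i)))
  limited <- lapply(1:4, function(i)
    feature_seq(sweep(matrix(stats::rnorm(150 * K), 150, K) %*% A, 2, b, `+`),
                "toy", label = "l", clip_id = paste0("l", i)))
  rt <- learn_transfer(donor, limited, esn_grid("small"), seed = 12,
                       shrink_prior = 0)
  moved <- lapply(donor, apply_transfer, rt = rt, label = "l")

  g_lim <- fit_gmm(limited, n_components = 4, seed = 1)
  g_raw <- fit_gmm(donor, n_components = 4, seed = 1)
  g_mov <- fit_gmm(moved, n_components = 4, seed = 1)
  d_raw <- as.numeric(symmetrized_divergence(g_raw, g_lim, 2000, seed = 13))
  d_mov <- as.numeric(symmetrized_divergence(g_mov, g_lim, 2000, seed = 13))
  expect_lt(d_mov, d_raw)
})
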