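# Independent oracles and small fixtures used across the suite.

# Closed-form KL divergence between diagonal Gaussians.
gaussian_kl <- function(m1, v1, m2, v2) {
  0.5 * sum(v1 / v2 + (m2 - m1)^2 / v2 - 1 + log(v2 / v1))
}

# Brute-force HMM likelihood: explicit sum over every state path.
brute_force_loglik <- function(model, X) {
  S <- model$n_states
  T_ <- nrow(X)
  B <- matrix(0, T_, S)
  for (s in seq_len(S)) {
    e <- model$emissions[[s]]
    g <- gmm_density(e$weights, e$means, e$variances)
    B[, s] <- exp(gmm_logdens(g, X))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- model$pi_[paths[r, 1]] * B[1, paths[r, 1]]
    if (T_ > 1) {
      for (t in 2:T_) {
        p <- p * model$A[paths[r, t - 1], paths[r, t]] * B[t, paths[r, t]]
      }
    }
    total <- total + p
  }
  log(total)
}

# Single-component diagonal-Gaussian mixture.
single_gaussian <- function(mean, var, feature_set = "test") {
  gmm_density(1, matrix(mean, 1), matrix(var, 1), feature_set)
}

# A deterministic small left-right HMM for toy checks.
toy_lr_hmm <- function(S = 3, K = 1, sep = 3, stay = 0.8) {
  em <- lapply(seq_len(S), function(s) {
    list(weights = 1, means = matrix(rep(sep * s, K), 1),
         variances = matrix(rep(0.5, K), 1))
  })
  A <- diag(stay, S)
  for (s in seq_len(S - 1)) A[s, s + 1] <- 1 - stay
  A[S, S] <- 1
  activity_hmm(A, c(1, rep(0, S - 1)), em, "left_right")
}

# Short labeled Gaussian sequences for recognizer tests.
toy_labeled_seqs <- function(mus, n_per = 8, T_ = 30, sd_ = 1, seed = 1) {
  set.seed(seed)
  out <- list()
  k <- 0
  for (ci in seq_along(mus)) {
    for (j in seq_len(n_per)) {
      k <- k + 1
      K <- length(mus[[ci]])
      out[[k]] <- feature_seq(
        matrix(stats::rnorm(T_ * K, mean = rep(mus[[ci]], each = T_), sd = sd_),
               T_, K),
        "toy", clip_id = sprintf("c%d_%03d", ci, j),
        label = names(mus)[ci] %||% paste0("class", ci))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
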