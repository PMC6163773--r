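#' Hidden Markov model with diagonal-GMM emissions
#'
#' The classifier unit: `n_states` hidden states, a row-stochastic
#' transition matrix, an initial distribution, and one diagonal-covariance
#' Gaussian mixture per state. Left-right models permit only self-loops
#' and forward transitions; ergodic models permit every transition.
#'
#' @param A `S x S` transition matrix, rows summing to 1.
#' @param pi_ Length-`S` initial distribution.
#' @param emissions List of `S` per-state emission mixtures, each a list
#'   with `weights`, `means` (`C x K`), `variances` (`C x K`).
#' @param topology `"left_right"` or `"ergodic"`.
#' @param label Class label the model represents, or `NULL`.
#' @param feature_set Feature-set tag of the training frames.
#' @return An `activity_hmm` object.
#' @export
activity_hmm <- function(A, pi_, emissions, topology = c("left_right", "ergodic"),
                         label = NULL, feature_set = "unknown") {
  topology <- match.arg(topology)
  A <- as.matrix(A)
  S <- nrow(A)
  stopifnot(ncol(A) == S, length(pi_) == S, length(emissions) == S,
            max(abs(rowSums(A) - 1)) < 1e-6)
  if (topology == "left_right" && any(A[lower.tri(A)] > 0)) {
    stop("left-right topology forbids backward transitions")
  }
  structure(
    list(n_states = S, A = A, pi_ = as.numeric(pi_), emissions = emissions,
         topology = topology, label = label, feature_set = feature_set),
    class = "activity_hmm"
  )
}

#' @export
print.activity_hmm <- function(x, ...) {
  cat(sprintf("<activity_hmm [%s]: %d states x %d comps, label=%s>\n",
              x$topology, x$n_states, length(x$emissions[[1]]$weights),
              if (is.null(x$label)) "none" else x$label))
  invisible(x)
}

# Stack all (state, comp) emission parameters into flat matrices for one
# big per-frame GEMM; returns the flat layout plus the state index of each
# flat component.
flatten_emissions <- function(model) {
  em <- model$emissions
  list(
    means = do.call(rbind, lapply(em, `[[`, "means")),
    variances = do.call(rbind, lapply(em, `[[`, "variances")),
    logw = unlist(lapply(em, function(e) log(e$weights))),
    state = rep(seq_along(em), vapply(em, function(e) length(e$weights), 0L))
  )
}

# Per-frame log densities: list(state = n x S state log-densities,
# comp = n x M flat component log-densities incl. log weights).
emission_logdens <- function(model, X, flat = flatten_emissions(model)) {
  g <- gmm_density(rep(1 / length(flat$logw), length(flat$logw)),
                   flat$means, flat$variances)
  lcomp <- sweep(gmm_component_logdens(g, X), 2L, flat$logw, `+`)
  S <- model$n_states
  lstate <- matrix(-Inf, nrow(lcomp), S)
  for (s in seq_len(S)) {
    cols <- which(flat$state == s)
    lstate[, s] <- if (length(cols) == 1L) lcomp[, cols] else
      logsumexp_rows(lcomp[, cols, drop = FALSE])
  }
  list(state = lstate, comp = lcomp)
}

# Scaled forward pass, batched over N equal-length sequences.
# Bl: T x N x S array of state log-emissions. Returns per-sequence log
# likelihoods and, if keep_alpha, the normalized forward variables and
# scaling constants needed by the backward pass.
batch_forward <- function(model, Bl, keep_alpha = FALSE) {
  dims <- dim(Bl); T_ <- dims[1]; N <- dims[2]; S <- dims[3]
  m <- Bl[, , 1, drop = FALSE][, , 1]
  if (!is.matrix(m)) m <- matrix(m, T_, N)
  if (S > 1) for (s in 2:S) m <- pmax(m, Bl[, , s])
  Bstar <- array(0, dims)
  for (s in seq_len(S)) Bstar[, , s] <- exp(Bl[, , s] - m)

  ll <- numeric(N)
  alpha <- if (keep_alpha) array(0, dims) else NULL
  cs <- if (keep_alpha) matrix(0, T_, N) else NULL
  a <- matrix(model$pi_, N, S, byrow = TRUE) * matrix(Bstar[1, , ], N, S)
  cvec <- rowSums(a)
  a <- a / cvec
  ll <- ll + log(cvec) + m[1, ]
  if (keep_alpha) { alpha[1, , ] <- a; cs[1, ] <- cvec }
  if (T_ > 1) {
    for (t in 2:T_) {
      a <- (a %*% model$A) * matrix(Bstar[t, , ], N, S)
      cvec <- rowSums(a)
      a <- a / cvec
      ll <- ll + log(cvec) + m[t, ]
      if (keep_alpha) { alpha[t, , ] <- a; cs[t, ] <- cvec }
    }
  }
  list(loglik = ll, alpha = alpha, c = cs, Bstar = Bstar)
}

# Full batched E-step for N equal-length sequences: returns gamma
# (T x N x S), summed transition counts xi (S x S), and per-sequence ll.
batch_forward_backward <- function(model, Bl) {
  fw <- batch_forward(model, Bl, keep_alpha = TRUE)
  dims <- dim(Bl); T_ <- dims[1]; N <- dims[2]; S <- dims[3]
  beta <- matrix(1, N, S)
  gamma <- array(0, dims)
  xi <- matrix(0, S, S)
  g <- fw$alpha[T_, , , drop = FALSE][1, , ]
  gamma[T_, , ] <- matrix(g, N, S)
  if (T_ > 1) {
    for (t in (T_ - 1):1) {
      Bb <- matrix(fw$Bstar[t + 1, , ], N, S) * beta / fw$c[t + 1, ]
      at <- matrix(fw$alpha[t, , ], N, S)
      xi <- xi + crossprod(at, Bb) * model$A
      beta <- Bb %*% t(model$A)
      g <- at * beta
      gamma[t, , ] <- g / pmax(rowSums(g), 1e-300)
    }
  }
  list(gamma = gamma, xi = xi, loglik = fw$loglik)
}

# Group sequences by length so batched passes apply; returns list of
# (T, idx) groups.
length_groups <- function(X_list) {
  lens <- vapply(X_list, nrow, 0L)
  lapply(split(seq_along(X_list), lens), function(idx) {
    list(T = nrow(X_list[[idx[1]]]), idx = idx)
  })
}

# Arrange state log-emissions of a group into a T x N x S array.
group_emission_array <- function(lstate, T_, N, S) {
  array(lstate, dim = c(T_, N, S))
}

#' Forward log-likelihood of sequences under a model
#'
#' @param model An [activity_hmm()].
#' @param seqs A [feature_seq()], a matrix, or a list of either.
#' @return Numeric vector of per-sequence forward log-likelihoods.
#' @export
hmm_loglik <- function(model, seqs) {
  X_list <- as_matrix_list(seqs)
  out <- numeric(length(X_list))
  flat <- flatten_emissions(model)
  for (g in length_groups(X_list)) {
    X <- do.call(rbind, X_list[g$idx])
    ed <- emission_logdens(model, X, flat)
    Bl <- array(0, c(g$T, length(g$idx), model$n_states))
    for (s in seq_len(model$n_states)) {
      Bl[, , s] <- matrix(ed$state[, s], g$T, length(g$idx))
    }
    out[g$idx] <- batch_forward(model, Bl)$loglik
  }
  out
}

as_matrix_list <- function(seqs) {
  if (inherits(seqs, "feature_seq")) return(list(seqs$values))
  if (is.matrix(seqs)) return(list(seqs))
  lapply(seqs, function(s) if (inherits(s, "feature_seq")) s$values else as.matrix(s))
}

# K-means initialization of one state's emission mixture from a frame pool.
init_state_gmm <- function(X, n_components, var_floor = 1e-6) {
  n <- nrow(X)
  C <- max(1L, min(n_components, n))
  if (C == 1L || n <= C) {
    mu <- matrix(colMeans(X), 1)
    v <- pmax(matrix(colMeans(sweep(X, 2L, mu[1, ])^2), 1), var_floor)
    return(list(weights = rep(1 / C, C),
                means = mu[rep(1, C), , drop = FALSE] +
                  if (C > 1) matrix(stats::rnorm(C * ncol(X), sd = 1e-3), C) else 0,
                variances = v[rep(1, C), , drop = FALSE]))
  }
  km <- tryCatch(
    suppressWarnings(stats::kmeans(X, centers = C, iter.max = 50L)),
    error = function(e) NULL
  )
  if (is.null(km)) {  # fewer distinct frames than centers
    mu <- matrix(colMeans(X), 1)
    v <- pmax(matrix(colMeans(sweep(X, 2L, mu[1, ])^2), 1), var_floor)
    return(list(weights = rep(1 / C, C),
                means = mu[rep(1, C), , drop = FALSE] +
                  matrix(stats::rnorm(C * ncol(X), sd = 1e-3), C),
                variances = v[rep(1, C), , drop = FALSE]))
  }
  v <- matrix(0, C, ncol(X))
  glob <- colMeans(sweep(X, 2L, colMeans(X))^2)
  for (c_ in seq_len(C)) {
    Xc <- X[km$cluster == c_, , drop = FALSE]
    v[c_, ] <- if (nrow(Xc) > 1) colMeans(sweep(Xc, 2L, km$centers[c_, ])^2) else glob
  }
  list(weights = pmax(km$size, 1) / sum(pmax(km$size, 1)),
       means = km$centers, variances = pmax(v, var_floor))
}

init_hmm <- function(X_list, n_states, n_components, topology, seed,
                     label = NULL, feature_set = "unknown", var_floor = 1e-6) {
  local_seed(seed)
  S <- n_states
  if (topology == "left_right") {
    pools <- vector("list", S)
    for (X in X_list) {
      cuts <- floor(seq(0, nrow(X), length.out = S + 1))
      for (s in seq_len(S)) {
        pools[[s]] <- rbind(pools[[s]], X[(cuts[s] + 1):cuts[s + 1], , drop = FALSE])
      }
    }
    em <- lapply(pools, init_state_gmm, n_components = n_components,
                 var_floor = var_floor)
    A <- diag(0.5, S)
    for (s in seq_len(S - 1)) A[s, s + 1] <- 0.5
    A[S, S] <- 1
    pi_ <- c(1, rep(0, S - 1))
  } else {
    X <- do.call(rbind, X_list)
    km <- suppressWarnings(stats::kmeans(X, centers = S, iter.max = 50L))
    em <- lapply(seq_len(S), function(s) {
      Xs <- X[km$cluster == s, , drop = FALSE]
      if (nrow(Xs) < 2) Xs <- X
      init_state_gmm(Xs, n_components, var_floor)
    })
    A <- matrix(1 / S, S, S)
    pi_ <- rep(1 / S, S)
  }
  activity_hmm(A, pi_, em, topology, label = label, feature_set = feature_set)
}

# One Baum-Welch EM pass over all sequences; returns updated model and the
# total log-likelihood of the *incoming* model.
baum_welch_step <- function(model, X_list, var_floor = 1e-6) {
  S <- model$n_states
  flat <- flatten_emissions(model)
  M <- length(flat$logw)
  K <- ncol(X_list[[1]])
  xi_sum <- matrix(0, S, S)
  pi_sum <- numeric(S)
  Nw <- numeric(M)
  mu_num <- matrix(0, M, K)
  v_num <- matrix(0, M, K)
  ll_total <- 0
  for (g in length_groups(X_list)) {
    N <- length(g$idx); T_ <- g$T
    X <- do.call(rbind, X_list[g$idx])        # sequence-major stack
    ed <- emission_logdens(model, X, flat)
    Bl <- array(0, c(T_, N, S))
    for (s in seq_len(S)) Bl[, , s] <- matrix(ed$state[, s], T_, N)
    fb <- batch_forward_backward(model, Bl)
    ll_total <- ll_total + sum(fb$loglik)
    xi_sum <- xi_sum + fb$xi
    pi_sum <- pi_sum + colSums(matrix(fb$gamma[1, , ], N, S))
    # flatten gamma back to frame order (sequence-major rows)
    # rows of X are sequence-major; column-major read of the T x N slice
    # gives exactly that order
    Gam <- matrix(0, N * T_, S)
    for (s in seq_len(S)) Gam[, s] <- as.numeric(fb$gamma[, , s])
    resp <- Gam[, flat$state, drop = FALSE] *
      exp(ed$comp - ed$state[, flat$state, drop = FALSE])
    resp[!is.finite(resp)] <- 0
    Nw <- Nw + colSums(resp)
    mu_num <- mu_num + crossprod(resp, X)
    v_num <- v_num + crossprod(resp, X^2)
  }
  # M-step
  A_new <- model$A
  rs <- rowSums(xi_sum)
  upd <- rs > 1e-8
  A_new[upd, ] <- xi_sum[upd, , drop = FALSE] / rs[upd]
  # absorbing final row of a left-right model has no outgoing counts at
  # row-sum zero; keep its prior row
  pi_new <- pi_sum / sum(pi_sum)
  em_new <- model$emissions
  for (s in seq_len(S)) {
    cols <- which(flat$state == s)
    n_s <- Nw[cols]
    if (sum(n_s) < 1e-6) next
    keep <- n_s > 1e-6
    w <- n_s / sum(n_s)
    mu <- model$emissions[[s]]$means
    v <- model$emissions[[s]]$variances
    mu[keep, ] <- mu_num[cols[keep], , drop = FALSE] / n_s[keep]
    v[keep, ] <- pmax(v_num[cols[keep], , drop = FALSE] / n_s[keep] -
                        mu[keep, , drop = FALSE]^2, var_floor)
    em_new[[s]] <- list(weights = w, means = mu, variances = v)
  }
  list(model = activity_hmm(A_new, pi_new, em_new, model$topology,
                            label = model$label, feature_set = model$feature_set),
       loglik = ll_total)
}

# Shared Baum-Welch driver.
train_hmm <- function(X_list, n_states, n_components, topology, seed,
                      max_iter = 25L, tol = 1e-3, var_floor = 1e-6,
                      label = NULL, feature_set = "unknown") {
  model <- init_hmm(X_list, n_states, n_components, topology, seed,
                    label = label, feature_set = feature_set,
                    var_floor = var_floor)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    step <- baum_welch_step(model, X_list, var_floor = var_floor)
    ll_trace <- c(ll_trace, step$loglik)
    if (is.finite(ll_old) && abs(step$loglik - ll_old) < tol) {
      model <- step$model
      break
    }
    ll_old <- step$loglik
    model <- step$model
  }
  attr(model, "loglik_trace") <- ll_trace
  model
}

prepare_training_seqs <- function(seqs, n_states) {
  X_list <- as_matrix_list(seqs)
  lens <- vapply(X_list, nrow, 0L)
  short <- lens < n_states
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than ", n_states,
            " frames skipped")
    X_list <- X_list[!short]
  }
  if (length(X_list) == 0) stop("all sequences shorter than the state count")
  X_list
}

#' Train a class-specific left-right HMM
#'
#' Baum-Welch with k-means-initialized GMM emissions. Iteration caps
#' follow the standard thresholds used for this task: 50 k-means
#' iterations, 25 EM iterations, and a 0.001 log-likelihood change
#' stopping rule. The training log-likelihood is nondecreasing per
#' iteration and is stored as attribute `loglik_trace`.
#'
#' @param seqs List of [feature_seq()] objects (or matrices) of one class.
#' @param n_states Number of states.
#' @param n_components Gaussian components per state.
#' @param seed Integer seed (k-means and initialization).
#' @param max_iter,tol Baum-Welch iteration cap and log-likelihood
#'   tolerance.
#' @param label Class label to store.
#' @return An `activity_hmm` with `topology = "left_right"`.
#' @export
train_class_hmm <- function(seqs, n_states = 3L, n_components = 2L, seed = 1L,
                            max_iter = 25L, tol = 1e-3, label = NULL) {
  if (length(seqs) < 2L && !is.matrix(seqs) && !inherits(seqs, "feature_seq")) {
    stop("need at least two training sequences")
  }
  fset <- if (is.list(seqs) && inherits(seqs[[1]], "feature_seq"))
    seqs[[1]]$feature_set else "unknown"
  X_list <- prepare_training_seqs(seqs, n_states)
  train_hmm(X_list, n_states, n_components, "left_right", seed,
            max_iter = max_iter, tol = tol, label = label, feature_set = fset)
}

#' Train a universal (ergodic) background HMM on all classes jointly
#'
#' The component grid for universal models counts the *total* emission
#' complexity of the background model; components are distributed evenly
#' over states.
#'
#' @param seqs All training sequences, every class pooled.
#' @param n_states Number of states.
#' @param total_components Total Gaussian components across all states.
#' @inheritParams train_class_hmm
#' @return An `activity_hmm` with `topology = "ergodic"`.
#' @export
train_universal_hmm <- function(seqs, n_states = 5L, total_components = 64L,
                                seed = 1L, max_iter = 25L, tol = 1e-3) {
  fset <- if (is.list(seqs) && inherits(seqs[[1]], "feature_seq"))
    seqs[[1]]$feature_set else "unknown"
  X_list <- prepare_training_seqs(seqs, n_states)
  per_state <- max(1L, round(total_components / n_states))
  train_hmm(X_list, n_states, per_state, "ergodic", seed,
            max_iter = max_iter, tol = tol, label = "universal",
            feature_set = fset)
}

#' Adapt the universal model to one class (MAP adaptation)
#'
#' One posterior pass of the class data through the background model
#' collects per-component responsibilities `n_c`; emission means and
#' weights are then shifted toward the class-data statistics with the
#' data-dependent coefficient `alpha_c = n_c / (n_c + r)` of standard
#' universal-background practice: `mu_adapted = alpha x_bar + (1-alpha)
#' mu_bg` and `w_adapted proportional to alpha n_c/n + (1-alpha) w_bg`
#' (renormalized per state). Transitions and covariances are inherited
#' unchanged. `r -> Inf` returns the background parameters; `r -> 0`
#' returns the posterior statistics.
#'
#' @param background Trained universal [activity_hmm()].
#' @param seqs Class training sequences.
#' @param relevance Relevance factor `r` (default 16, standard
#'   universal-background practice).
#' @param label Class label for the adapted model.
#' @return An adapted `activity_hmm`.
#' @export
adapt_universal <- function(background, seqs, relevance = 16, label = NULL) {
  X_list <- as_matrix_list(seqs)
  if (length(X_list) == 0) {
    warning("no class data; returning background copy")
    background$label <- label
    return(background)
  }
  S <- background$n_states
  flat <- flatten_emissions(background)
  M <- length(flat$logw)
  K <- ncol(X_list[[1]])
  Nw <- numeric(M)
  mu_num <- matrix(0, M, K)
  for (g in length_groups(X_list)) {
    N <- length(g$idx); T_ <- g$T
    X <- do.call(rbind, X_list[g$idx])
    ed <- emission_logdens(background, X, flat)
    Bl <- array(0, c(T_, N, S))
    for (s in seq_len(S)) Bl[, , s] <- matrix(ed$state[, s], T_, N)
    fb <- batch_forward_backward(background, Bl)
    # rows of X are sequence-major; column-major read of the T x N slice
    # gives exactly that order
    Gam <- matrix(0, N * T_, S)
    for (s in seq_len(S)) Gam[, s] <- as.numeric(fb$gamma[, , s])
    resp <- Gam[, flat$state, drop = FALSE] *
      exp(ed$comp - ed$state[, flat$state, drop = FALSE])
    resp[!is.finite(resp)] <- 0
    Nw <- Nw + colSums(resp)
    mu_num <- mu_num + crossprod(resp, X)
  }
  em <- background$emissions
  for (s in seq_len(S)) {
    cols <- which(flat$state == s)
    n_sc <- Nw[cols]
    alpha <- n_sc / (n_sc + relevance)
    mu_bg <- em[[s]]$means
    xbar <- mu_bg
    pos <- n_sc > 1e-10
    xbar[pos, ] <- mu_num[cols[pos], , drop = FALSE] / n_sc[pos]
    em[[s]]$means <- alpha * xbar + (1 - alpha) * mu_bg
    w_ml <- n_sc / max(sum(n_sc), 1e-10)
    w <- alpha * w_ml + (1 - alpha) * em[[s]]$weights
    em[[s]]$weights <- w / sum(w)
  }
  out <- activity_hmm(background$A, background$pi_, em, background$topology,
                      label = label, feature_set = background$feature_set)
  attr(out, "relevance") <- relevance
  out
}

#' Bundle per-class recognizers
#'
#' @param models Named list of per-class `activity_hmm` models.
#' @param mode `"class_specific"` or `"universal_adapted"`.
#' @param background The background model for universal mode.
#' @param selection Optional metadata (chosen states/components).
#' @return A `recognizer_bundle`.
#' @export
recognizer_bundle <- function(models, mode = c("class_specific", "universal_adapted"),
                              background = NULL, selection = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(models) >= 1, !is.null(names(models)))
  structure(list(mode = mode, models = models, background = background,
                 selection = selection),
            class = "recognizer_bundle")
}

#' Classify feature sequences by maximum normalized likelihood
#'
#' Scores each sequence under every class model with the forward
#' algorithm, normalizes by frame count so clip length does not bias the
#' decision, and returns the argmax label. Ties break to the earliest
#' class in bundle order.
#'
#' @param bundle A [recognizer_bundle()].
#' @param seqs A [feature_seq()] or list of them.
#' @return A data frame with `clip_id`, `predicted`, and one score column
#'   per class (per-frame log-likelihoods).
#' @export
classify <- function(bundle, seqs) {
  if (inherits(seqs, "feature_seq") || is.matrix(seqs)) seqs <- list(seqs)
  lens <- vapply(as_matrix_list(seqs), nrow, 0L)
  scores <- vapply(bundle$models, function(m) hmm_loglik(m, seqs) / lens,
                   numeric(length(seqs)))
  scores <- matrix(scores, nrow = length(seqs),
                   dimnames = list(NULL, names(bundle$models)))
  dead <- apply(scores, 1L, function(r) !any(is.finite(r)))
  if (any(dead)) {
    stop("non-finite likelihood under all models for sequence(s) ",
         paste(which(dead), collapse = ", "))
  }
  pred <- names(bundle$models)[apply(scores, 1L, which.max)]
  ids <- vapply(seqs, function(s)
    if (inherits(s, "feature_seq")) s$clip_id else "seq", "")
  out <- data.frame(clip_id = ids, predicted = pred, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Grid search over model sizes by validation accuracy
#'
#' Trains one recognizer bundle per `(n_states, n_components)` candidate
#' and keeps the one with maximum validation accuracy; ties resolve to
#' the smallest model (states first, then components).
#'
#' @param train_seqs Named-label training sequences (list of
#'   [feature_seq()] with labels).
#' @param val_seqs Labeled validation sequences.
#' @param state_grid,component_grid Candidate values.
#' @param mode `"class_specific"` or `"universal_adapted"`.
#' @param seed Integer seed.
#' @param ... Passed to the trainers (e.g. `max_iter`).
#' @return List with `n_states`, `n_components`, `accuracy`, `table`
#'   (all candidates), and `bundle` (the winning recognizer).
#' @export
select_model <- function(train_seqs, val_seqs,
                         state_grid = c(3, 4, 5, 6, 7),
                         component_grid = c(2, 4, 8, 16, 32, 64, 128),
                         mode = c("class_specific", "universal_adapted"),
                         seed = 1L, ...) {
  mode <- match.arg(mode)
  if (length(val_seqs) == 0) stop("empty validation set")
  grid <- expand.grid(n_states = sort(state_grid),
                      n_components = sort(component_grid))
  grid <- grid[order(grid$n_states, grid$n_components), , drop = FALSE]
  truth <- vapply(val_seqs, `[[`, "", "label")
  best <- NULL; best_acc <- -Inf
  accs <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    bundle <- train_recognizer(train_seqs, mode = mode,
                               n_states = grid$n_states[i],
                               n_components = grid$n_components[i],
                               seed = seed, ...)
    acc <- mean(classify(bundle, val_seqs)$predicted == truth)
    accs[i] <- acc
    if (acc > best_acc + 1e-12) {
      best_acc <- acc
      best <- list(n_states = grid$n_states[i],
                   n_components = grid$n_components[i],
                   accuracy = acc, bundle = bundle)
    }
  }
  grid$accuracy <- accs
  best$table <- grid
  best
}

#' Train a full recognizer bundle
#'
#' Class-specific mode trains one left-right HMM per class; universal
#' mode trains one ergodic background model on everything and MAP-adapts
#' it to each class.
#'
#' @param train_seqs Labeled training sequences.
#' @param mode `"class_specific"` or `"universal_adapted"`.
#' @param n_states States per model.
#' @param n_components Components per state (class-specific) or total
#'   components (universal).
#' @param seed Integer seed.
#' @param relevance MAP relevance factor for universal adaptation.
#' @param ... Passed to the trainers (`max_iter`, `tol`).
#' @return A [recognizer_bundle()].
#' @export
train_recognizer <- function(train_seqs, mode = c("class_specific", "universal_adapted"),
                             n_states = 3L, n_components = 2L, seed = 1L,
                             relevance = 16, ...) {
  mode <- match.arg(mode)
  labels <- vapply(train_seqs, `[[`, "", "label")
  classes <- sort(unique(labels))
  if (mode == "class_specific") {
    models <- lapply(classes, function(cl) {
      train_class_hmm(train_seqs[labels == cl], n_states = n_states,
                      n_components = n_components, seed = seed,
                      label = cl, ...)
    })
    names(models) <- classes
    recognizer_bundle(models, "class_specific",
                      selection = list(n_states = n_states,
                                       n_components = n_components))
  } else {
    bg <- train_universal_hmm(train_seqs, n_states = n_states,
                              total_components = n_components, seed = seed, ...)
    models <- lapply(classes, function(cl) {
      adapt_universal(bg, train_seqs[labels == cl], relevance = relevance,
                      label = cl)
    })
    names(models) <- classes
    recognizer_bundle(models, "universal_adapted", background = bg,
                      selection = list(n_states = n_states,
                                       n_components = n_components))
  }
}
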