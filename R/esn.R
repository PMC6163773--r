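#' Initialize an untrained reservoir transform
#'
#' The recurrent matrix is drawn from a zero-mean Gaussian and rescaled so
#' its spectral radius (largest absolute eigenvalue) equals `SR` exactly;
#' input weights are uniform on `[-input_scaling, +input_scaling]`.
#' `L = 0` yields the degenerate direct-readout model in which the ridge
#' readout maps input frames straight to targets with no reservoir.
#'
#' @param K Input (and output) dimensionality.
#' @param L Reservoir size (number of neurons); `0` for direct readout.
#' @param SR Target spectral radius of the recurrent matrix.
#' @param input_scaling Half-width of the uniform input-weight distribution.
#' @param seed Integer seed; same seed reproduces the matrices bit-exactly.
#' @param regularization Ridge term used when the readout is learned.
#' @param washout Number of initial states excluded from regression and
#'   from emitted output.
#' @return A `reservoir_transform` with `Win` (`L x K`), `Wres` (`L x L`),
#'   `Wout = NULL` (untrained), and the hyperparameters.
#' @export
init_reservoir <- function(K, L, SR = 0.9, input_scaling = 0.5, seed = 1L,
                           regularization = 1e-6, washout = 10L) {
  stopifnot(K >= 1, L >= 0, SR > 0)
  local_seed(seed)
  if (L > 0) {
    Win <- matrix(stats::runif(L * K, -input_scaling, input_scaling), L, K)
    Wres <- matrix(stats::rnorm(L * L), L, L)
    rho <- max(Mod(eigen(Wres, only.values = TRUE)$values))
    Wres <- Wres * (SR / rho)
  } else {
    Win <- matrix(0, 0, K)
    Wres <- matrix(0, 0, 0)
  }
  structure(
    list(Win = Win, Wres = Wres, Wout = NULL,
         K = as.integer(K), L = as.integer(L), SR = SR,
         input_scaling = input_scaling, regularization = regularization,
         washout = as.integer(washout), seed = as.integer(seed)),
    class = "reservoir_transform"
  )
}

#' @export
print.reservoir_transform <- function(x, ...) {
  cat(sprintf("<reservoir_transform: K=%d L=%d SR=%.2f scale=%.2f %s>\n",
              x$K, x$L, x$SR, x$input_scaling,
              if (is.null(x$Wout)) "untrained" else "trained"))
  invisible(x)
}

#' Run the reservoir over an input sequence
#'
#' State recursion `x(k) = tanh(Win u(k) + Wres x(k-1))` from `x(0) = 0`.
#' For `L = 0` the "states" are the inputs themselves (direct readout).
#'
#' @param rt A [init_reservoir()] result.
#' @param inputs `T x K` matrix or a [feature_seq()].
#' @return `T x L` state matrix (or `T x K` when `L = 0`), with attribute
#'   `washout` copied from `rt`.
#' @export
run_reservoir <- function(rt, inputs) {
  U <- if (inherits(inputs, "feature_seq")) inputs$values else as.matrix(inputs)
  if (ncol(U) != rt$K) {
    stop(sprintf("input dimensionality %d does not match reservoir K=%d",
                 ncol(U), rt$K))
  }
  if (rt$L == 0L) {
    X <- U
  } else {
    T_ <- nrow(U)
    drive <- tcrossprod(U, rt$Win)            # T x L: Win u(k) terms
    X <- matrix(0, T_, rt$L)
    x <- numeric(rt$L)
    for (k in seq_len(T_)) {
      x <- tanh(drive[k, ] + as.numeric(rt$Wres %*% x))
      X[k, ] <- x
    }
  }
  attr(X, "washout") <- rt$washout
  X
}

#' Learn the linear readout by ridge regression
#'
#' Solves `(X'X + eps I) Wout = X'D` with a Cholesky solve of the normal
#' equations (no explicit inverse). With `eps = 0` the plain least-squares
#' solution is returned; a rank-deficient `X` then raises an error
#' suggesting a positive `eps`.
#'
#' @param X State matrix (washout rows already removed).
#' @param D Target matrix, rows aligned with `X`.
#' @param regularization Ridge term `eps >= 0`.
#' @return `L x K` readout weight matrix.
#' @export
learn_readout <- function(X, D, regularization = 1e-6) {
  X <- as.matrix(X); D <- as.matrix(D)
  stopifnot(nrow(X) == nrow(D))
  G <- crossprod(X) + regularization * diag(ncol(X))
  Wout <- tryCatch(
    solve(G, crossprod(X, D)),
    error = function(e) {
      stop("normal equations are singular (rank-deficient states); ",
           "use regularization > 0", call. = FALSE)
    }
  )
  Wout
}

#' Transform a donor-class sequence into the limited-class feature space
#'
#' Applies the trained MIMO map: runs the reservoir over the donor frames
#' and reads out `y(k) = Wout' x(k)`. The first `washout` frames are
#' dropped; the output carries the limited-class label and is flagged
#' synthetic with provenance.
#'
#' @param rt A trained reservoir transform (after [learn_transfer()]).
#' @param donor_seq A [feature_seq()] from the donor class (or a matrix).
#' @param label Label to assign (the limited class).
#' @return A synthetic [feature_seq()] of `K` columns.
#' @export
apply_transfer <- function(rt, donor_seq, label = NULL) {
  if (is.null(rt$Wout)) stop("reservoir transform is untrained; call learn_transfer first")
  X <- run_reservoir(rt, donor_seq)
  keep <- setdiff(seq_len(nrow(X)), seq_len(min(rt$washout, nrow(X))))
  Y <- X[keep, , drop = FALSE] %*% rt$Wout
  src <- if (inherits(donor_seq, "feature_seq")) donor_seq$clip_id else "matrix"
  fset <- if (inherits(donor_seq, "feature_seq")) donor_seq$feature_set else "unknown"
  feature_seq(Y, fset,
              clip_id = paste0("synth_", src), label = label,
              synthetic = TRUE,
              provenance = list(source_clip = src, reservoir_seed = rt$seed,
                                L = rt$L, SR = rt$SR))
}

#' Default hyperparameter grids for transfer learning
#'
#' The exhaustive-search grids for spectral radius, reservoir size and
#' input scaling; `"small"` is a reduced grid sized for tests and
#' desk-scale experiments.
#'
#' @param which `"full"` or `"small"`.
#' @return Named list of numeric vectors `SR`, `L`, `input_scaling`,
#'   `regularization`.
#' @export
esn_grid <- function(which = c("full", "small")) {
  which <- match.arg(which)
  if (which == "full") {
    list(SR = c(0.8, 0.9, 0.95, 0.99),
         L = c(0, 500, 1000, 5000, 10000),
         input_scaling = c(0.1, 0.5, 0.7, 0.95, 0.99),
         regularization = c(1e-6, 1e-2))
  } else {
    list(SR = 0.9, L = c(0, 50), input_scaling = c(0.1, 0.5),
         regularization = 1e-4)
  }
}

# Symmetric PSD square root (and inverse root) via eigendecomposition.
psd_root <- function(S, inverse = FALSE, ridge = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, ridge)
  p <- if (inverse) -0.5 else 0.5
  e$vectors %*% (lam^p * t(e$vectors))
}

# Gaussian optimal-transport affine map from the donor frame distribution
# onto the limited frame distribution: T(u) = mu_l + M (u - mu_u) with
# M = Cu^{-1/2} (Cu^{1/2} Cl Cu^{1/2})^{1/2} Cu^{-1/2}. Frames within a
# clip are strongly correlated, so the effective sample size behind Cl is
# roughly the clip count; Cl is therefore shrunk toward Cu with
# lambda = n_clips / (n_clips + 8), degrading gracefully to a pure mean
# shift when the limited class holds almost no clips.
transport_map <- function(U, D, ridge = 1e-6, n_limited_clips = Inf,
                          shrink_prior = 8) {
  mu_u <- colMeans(U); mu_l <- colMeans(D)
  Cu <- stats::cov(U) + ridge * diag(ncol(U))
  Cl <- stats::cov(D) + ridge * diag(ncol(D))
  lambda <- if (is.finite(n_limited_clips) && shrink_prior > 0)
    n_limited_clips / (n_limited_clips + shrink_prior) else 1
  Cl <- lambda * Cl + (1 - lambda) * Cu
  Cu_h <- psd_root(Cu); Cu_ih <- psd_root(Cu, inverse = TRUE)
  M <- Cu_ih %*% psd_root(Cu_h %*% Cl %*% Cu_h) %*% Cu_ih
  list(M = M, mu_u = mu_u, mu_l = mu_l,
       apply = function(X) sweep(sweep(X, 2L, mu_u) %*% M, 2L, mu_l, `+`))
}

# Build supervised (donor -> limited) frame-paired training material.
#   transport: targets are the donor frames pushed through the Gaussian
#     optimal-transport map onto the limited frame distribution; the
#     reservoir sees real donor trajectories in temporal order.
#   index: donor clips paired with limited clips drawn with replacement,
#     each pair truncated to the shorter length, frames matched by index.
pair_sequences <- function(donor, limited, seed,
                           strategy = c("transport", "index"),
                           shrink_prior = 8) {
  strategy <- match.arg(strategy)
  if (strategy == "transport") {
    U <- do.call(rbind, lapply(donor, `[[`, "values"))
    D <- do.call(rbind, lapply(limited, `[[`, "values"))
    tmap <- transport_map(U, D, n_limited_clips = length(limited),
                          shrink_prior = shrink_prior)
    return(lapply(donor, function(s) {
      list(u = s$values, d = tmap$apply(s$values))
    }))
  }
  local_seed(seed)
  pick <- sample.int(length(limited), length(donor), replace = TRUE)
  lapply(seq_along(donor), function(i) {
    u <- donor[[i]]$values
    d <- limited[[pick[i]]]$values
    n <- min(nrow(u), nrow(d))
    list(u = u[seq_len(n), , drop = FALSE], d = d[seq_len(n), , drop = FALSE])
  })
}

#' Learn the donor-to-limited feature-space transformation
#'
#' Builds supervised frame pairs between donor and limited sequences, runs
#' the reservoir over the donor side, and fits the ridge readout toward
#' the limited side. With the default `"transport"` strategy the targets
#' are the donor frames pushed through a Gaussian optimal-transport
#' alignment onto the limited frame distribution (there is no one-to-one
#' correspondence between clips of two classes, so the alignment supplies
#' the supervision); `"index"` instead pairs donor clips with randomly
#' drawn limited clips truncated to the shorter length, matching frames by
#' index. Hyperparameters are chosen by exhaustive search over the grids,
#' minimizing per-frame reconstruction mean squared error on a held-out
#' 20% of the pairs.
#'
#' @param donor List of donor-class [feature_seq()] objects (training folds).
#' @param limited List of limited-class [feature_seq()] objects.
#' @param grid Hyperparameter grid, as from [esn_grid()].
#' @param washout Initial frames discarded per sequence.
#' @param seed Integer seed controlling pairing, reservoir draws and the
#'   validation split.
#' @param pairing_strategy `"transport"` or `"index"`; see above.
#' @param shrink_prior Strength (in clips) of the shrinkage of the
#'   limited-class covariance toward the donor's inside the transport
#'   alignment; frames within a clip are correlated, so the effective
#'   sample behind that covariance is roughly the clip count. `0`
#'   disables shrinkage.
#' @return A trained `reservoir_transform` with attributes `selection`
#'   (data frame of all grid points and their validation errors) and
#'   `val_mse` (the winner's error).
#' @export
learn_transfer <- function(donor, limited, grid = esn_grid("small"),
                           washout = 10L, seed = 1L,
                           pairing_strategy = c("transport", "index"),
                           shrink_prior = 8) {
  pairing_strategy <- match.arg(pairing_strategy)
  if (length(donor) == 0 || length(limited) == 0) {
    stop("need at least one donor and one limited sequence")
  }
  Kd <- ncol(donor[[1]]$values); Kl <- ncol(limited[[1]]$values)
  if (Kd != Kl) stop("donor and limited feature dimensionality differ")

  pairs <- pair_sequences(donor, limited, seed = seed,
                          strategy = pairing_strategy,
                          shrink_prior = shrink_prior)
  local_seed(seed + 1L)
  n_val <- max(1L, floor(0.2 * length(pairs)))
  val_idx <- if (length(pairs) > 1L) sample.int(length(pairs), n_val) else integer(0)
  tr_pairs <- if (length(val_idx)) pairs[-val_idx] else pairs
  va_pairs <- if (length(val_idx)) pairs[val_idx] else pairs

  combos <- expand.grid(L = grid$L, SR = grid$SR,
                        input_scaling = grid$input_scaling,
                        regularization = grid$regularization)
  # ties in validation error resolve to the smallest model first
  combos <- combos[order(combos$L, combos$SR, combos$input_scaling,
                         combos$regularization), , drop = FALSE]

  eval_combo <- function(L, SR, IS, eps) {
    rt <- init_reservoir(Kd, L, SR = SR, input_scaling = IS, seed = seed,
                         regularization = eps, washout = washout)
    collect <- function(ps) {
      Xs <- lapply(ps, function(p) {
        X <- run_reservoir(rt, p$u)
        keep <- setdiff(seq_len(nrow(X)), seq_len(min(washout, nrow(X))))
        list(X = X[keep, , drop = FALSE], D = p$d[keep, , drop = FALSE])
      })
      list(X = do.call(rbind, lapply(Xs, `[[`, "X")),
           D = do.call(rbind, lapply(Xs, `[[`, "D")))
    }
    tr <- collect(tr_pairs)
    rt$Wout <- learn_readout(tr$X, tr$D, regularization = eps)
    va <- collect(va_pairs)
    mse <- mean((va$X %*% rt$Wout - va$D)^2)
    list(rt = rt, mse = mse)
  }

  best <- NULL; best_mse <- Inf
  errs <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    fit <- eval_combo(combos$L[i], combos$SR[i], combos$input_scaling[i],
                      combos$regularization[i])
    errs[i] <- fit$mse
    if (fit$mse < best_mse - 1e-12) {
      best <- fit$rt; best_mse <- fit$mse
    }
  }
  combos$val_mse <- errs
  attr(best, "selection") <- combos
  attr(best, "val_mse") <- best_mse
  best
}
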