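#' Diagonal-covariance Gaussian mixture density
#'
#' Container for one class's frame-level density estimate: mixture weights,
#' component means and diagonal variances.
#'
#' @param weights Length-`C` simplex vector.
#' @param means `C x K` matrix of component means.
#' @param variances `C x K` matrix of diagonal variances (all `>=` floor).
#' @param feature_set Feature-set tag of the frames the model describes.
#' @return A `gmm_density` object.
#' @export
gmm_density <- function(weights, means, variances, feature_set = "unknown") {
  means <- as.matrix(means); variances <- as.matrix(variances)
  stopifnot(length(weights) == nrow(means),
            all(dim(means) == dim(variances)),
            all(variances > 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("mixture weights must sum to 1")
  structure(
    list(weights = as.numeric(weights), means = means, variances = variances,
         n_components = nrow(means), feature_set = feature_set),
    class = "gmm_density"
  )
}

#' @export
print.gmm_density <- function(x, ...) {
  cat(sprintf("<gmm_density: %d components x %d dims [%s]>\n",
              x$n_components, ncol(x$means), x$feature_set))
  invisible(x)
}

# Per-frame per-component Gaussian log-densities: n x C.
gmm_component_logdens <- function(gmm, x) {
  x <- as.matrix(x)
  inv_v <- 1 / gmm$variances                                    # C x K
  const <- -0.5 * (ncol(x) * log(2 * pi) + rowSums(log(gmm$variances)) +
                     rowSums(gmm$means^2 * inv_v))
  ll <- tcrossprod(x, gmm$means * inv_v) - 0.5 * tcrossprod(x^2, inv_v)
  sweep(ll, 2L, const, `+`)
}

logsumexp_rows <- function(m) {
  mx <- m[, 1L]
  if (ncol(m) > 1L) for (j in 2:ncol(m)) mx <- pmax(mx, m[, j])
  mx + log(rowSums(exp(m - mx)))
}

#' Log-density of frames under a mixture
#'
#' Computed fully in log space so distant points do not underflow.
#'
#' @param gmm A [gmm_density()].
#' @param x `n x K` frame matrix.
#' @return Length-`n` vector of `log p(x)`.
#' @export
gmm_logdens <- function(gmm, x) {
  lp <- sweep(gmm_component_logdens(gmm, x), 2L, log(gmm$weights), `+`)
  logsumexp_rows(lp)
}

#' Draw frames from a mixture
#'
#' @param gmm A [gmm_density()].
#' @param n Number of draws.
#' @return `n x K` matrix.
#' @export
gmm_sample <- function(gmm, n) {
  comp <- sample.int(gmm$n_components, n, replace = TRUE, prob = gmm$weights)
  K <- ncol(gmm$means)
  gmm$means[comp, , drop = FALSE] +
    matrix(stats::rnorm(n * K), n, K) * sqrt(gmm$variances[comp, , drop = FALSE])
}

#' Fit a diagonal-covariance GMM by k-means-initialized EM
#'
#' Component means are initialized by k-means; EM then runs to a
#' log-likelihood tolerance with a variance floor. Deterministic given
#' `seed`. The 16-component default matches the density size used for
#' class-proximity computation.
#'
#' @param x `n x K` matrix of pooled frames of one class, or a list of
#'   [feature_seq()] objects to pool.
#' @param n_components Number of mixture components.
#' @param seed Integer seed controlling k-means and EM.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute per-frame log-likelihood change at which EM stops.
#' @param var_floor Lower bound applied to every variance.
#' @param feature_set Tag stored on the model (taken from sequences if a
#'   list is given).
#' @return A [gmm_density()] with attributes `loglik` (final total
#'   log-likelihood) and `n_frames`.
#' @export
fit_gmm <- function(x, n_components = 16L, seed = 1L, max_iter = 100L,
                    tol = 1e-4, var_floor = 1e-6, feature_set = "unknown") {
  if (is.list(x) && !is.matrix(x)) {
    feature_set <- unique(vapply(x, `[[`, "", "feature_set"))[1]
    x <- do.call(rbind, lapply(x, `[[`, "values"))
  }
  x <- as.matrix(x)
  n <- nrow(x); K <- ncol(x)
  if (n < 10L * n_components) {
    stop(sprintf("only %d frames for %d components; use at most %d components",
                 n, n_components, max(1L, n %/% 10L)))
  }
  local_seed(seed)
  km <- suppressWarnings(
    stats::kmeans(x, centers = n_components, iter.max = 50L, nstart = 1L)
  )
  means <- km$centers
  sizes <- pmax(km$size, 1L)
  w <- sizes / sum(sizes)
  v <- matrix(0, n_components, K)
  for (c_ in seq_len(n_components)) {
    xc <- x[km$cluster == c_, , drop = FALSE]
    v[c_, ] <- if (nrow(xc) > 1L) colMeans(sweep(xc, 2L, means[c_, ])^2) else
      colMeans(sweep(x, 2L, colMeans(x))^2)
  }
  v <- pmax(v, var_floor)

  gmm <- gmm_density(w, means, v, feature_set)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- sweep(gmm_component_logdens(gmm, x), 2L, log(gmm$weights), `+`)
    lse <- logsumexp_rows(lp)
    ll <- sum(lse)
    resp <- exp(lp - lse)                       # n x C
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    w <- nk / n
    means <- crossprod(resp, x) / nk
    v <- pmax(crossprod(resp, x^2) / nk - means^2, var_floor)
    gmm <- gmm_density(w / sum(w), means, v, feature_set)
    if (abs(ll - ll_old) / n < tol) break
    ll_old <- ll
  }
  attr(gmm, "loglik") <- sum(gmm_logdens(gmm, x))
  attr(gmm, "n_frames") <- n
  gmm
}
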