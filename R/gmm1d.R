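#' Fit a one-dimensional Gaussian mixture by EM
#'
#' Plain EM for a K-component univariate normal mixture with multiple seeded
#' k-means-style restarts. The best restart (highest log-likelihood) is kept.
#' Components are reported sorted by mean. Convergence is declared when the
#' relative log-likelihood change falls below `tol`; component sds are floored
#' at `sd_floor` to avoid singular solutions.
#'
#' @param x Numeric vector of observations (finite).
#' @param K Number of components (>= 1).
#' @param seed Integer seed controlling the restarts.
#' @param n_init Number of restarts (default 5).
#' @param max_iter Maximum EM iterations per restart (default 500).
#' @param tol Relative log-likelihood convergence tolerance (default 1e-8).
#' @param sd_floor Lower bound on component sds (default 1e-3).
#' @return A list of class `"gmm1d"`: `K`, `weights`, `means`, `sds` (sorted
#'   by mean), `loglik`, `loglik_trace` (per-iteration log-likelihood of the
#'   winning restart), `bic`, `n`.
#' @export
fit_gmm1d <- function(x, K, seed = 1L, n_init = 5, max_iter = 500,
                      tol = 1e-8, sd_floor = 1e-3) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values", call. = FALSE)
  if (stats::sd(x) < .Machine$double.eps^0.5) {
    stop("degenerate input: values are (numerically) constant", call. = FALSE)
  }
  K <- as.integer(K)
  stopifnot(K >= 1)

  if (K == 1L) {
    mu <- mean(x); s <- max(stats::sd(x) * sqrt((n - 1) / n), sd_floor)
    ll <- sum(stats::dnorm(x, mu, s, log = TRUE))
    out <- list(K = 1L, weights = 1, means = mu, sds = s,
                loglik = ll, loglik_trace = ll,
                bic = -2 * ll + 2 * log(n), n = n)
    class(out) <- "gmm1d"
    return(out)
  }

  seeds <- derive_seeds(seed, n_init)
  best <- NULL
  for (init in seq_len(n_init)) {
    cen <- with_seed(seeds[init], {
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = K, nstart = 1,
                                       iter.max = 25)),
        error = function(e) NULL)
      if (is.null(km)) sample(x, K) else as.numeric(km$centers)
    })
    fit <- em_gmm1d(x, sort(cen), max_iter = max_iter, tol = tol,
                    sd_floor = sd_floor)
    if (is.null(fit)) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed for all restarts", call. = FALSE)
  ord <- order(best$means)
  npar <- 3 * K - 1
  out <- list(K = K, weights = best$weights[ord], means = best$means[ord],
              sds = best$sds[ord], loglik = best$loglik,
              loglik_trace = best$trace,
              bic = -2 * best$loglik + npar * log(n), n = n)
  class(out) <- "gmm1d"
  out
}

# single EM run from given centres; returns NULL on failure
em_gmm1d <- function(x, centres, max_iter, tol, sd_floor) {
  n <- length(x)
  K <- length(centres)
  w <- rep(1 / K, K)
  mu <- centres
  s <- rep(max(stats::sd(x) / K, sd_floor), K)
  trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(K),
                   function(k) w[k] * stats::dnorm(x, mu[k], s[k]),
                   numeric(n))
    rowsum_ <- rowSums(dens)
    if (any(rowsum_ <= 0) || any(!is.finite(rowsum_))) return(NULL)
    ll <- sum(log(rowsum_))
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + .Machine$double.eps)) break
    ll_old <- ll
    r <- dens / rowsum_
    nk <- colSums(r)
    if (any(nk < .Machine$double.eps)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    s <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    s <- pmax(s, sd_floor)
  }
  list(weights = w, means = mu, sds = s, loglik = ll, trace = trace)
}

#' Select the number of mixture components by BIC
#'
#' Fits [fit_gmm1d()] for each K in `k_range` and returns the fit with the
#' smallest BIC.
#'
#' @inheritParams fit_gmm1d
#' @param k_range Length-2 integer vector `(min, max)` of component counts.
#' @return The winning `"gmm1d"` fit, with an extra element `bic_by_k`.
#' @export
select_gmm1d <- function(x, k_range, seed = 1L, n_init = 5, max_iter = 500,
                         tol = 1e-8, sd_floor = 1e-3) {
  x <- x[is.finite(x)]
  if (length(x) >= 2 && stats::sd(x) < .Machine$double.eps^0.5) {
    stop("degenerate input: values are (numerically) constant", call. = FALSE)
  }
  ks <- seq.int(k_range[1], k_range[2])
  fits <- lapply(ks, function(K) {
    tryCatch(fit_gmm1d(x, K, seed = seed, n_init = n_init,
                       max_iter = max_iter, tol = tol, sd_floor = sd_floor),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("EM failed at every K in k_range", call. = FALSE)
  bics <- vapply(fits[ok], function(f) f$bic, numeric(1))
  best <- fits[ok][[which.min(bics)]]
  best$bic_by_k <- stats::setNames(bics, ks[ok])
  best
}

#' Posterior component membership probabilities under a 1-D mixture
#'
#' @param model A `"gmm1d"` fit.
#' @param x Numeric vector of evaluation points.
#' @return Matrix, `length(x)` rows by `model$K` columns, rows summing to 1.
#' @export
posterior_gmm1d <- function(model, x) {
  K <- model$K
  dens <- vapply(seq_len(K),
                 function(k) model$weights[k] *
                   stats::dnorm(x, model$means[k], model$sds[k]),
                 numeric(length(x)))
  dens <- matrix(dens, ncol = K)
  dens / pmax(rowSums(dens), .Machine$double.xmin)
}
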