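#' Cluster genes by multidimensional response profiles
#'
#' Multivariate Gaussian-mixture model-based clustering of per-gene profile
#' vectors (e.g. the SLRs of a gene across two heat-shock contrasts, or its
#' group means). Full covariance components are used; the number of clusters
#' is chosen by BIC over `k_range`, scanned coarsely on a geometric grid and
#' then refined around the best coarse value. Genes are assigned by maximum
#' posterior. Cluster ids are relabelled 1..K by descending size.
#'
#' @param profiles Numeric matrix, genes x dimensions (>= 2 dimensions unless
#'   `allow_1d = TRUE`); rownames are gene ids. No missing values.
#' @param k_range Length-2 vector of cluster counts to consider (default
#'   `c(2, 100)`, matching reported cluster ids running into the nineties on
#'   genome-scale profiles; at least `10 * k_range[2]` genes are required).
#' @param seed Integer seed.
#' @param allow_1d Permit a single-column profile matrix.
#' @return A list of class `"cluster_assignment"`: `cluster` (named integer
#'   vector), `K`, `sizes`, `centroids` (K x dim matrix), `bic`,
#'   `loglik`, `model` (the underlying mclust fit).
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_profiles <- function(profiles, k_range = c(2, 100), seed = 1L,
                             allow_1d = FALSE) {
  profiles <- as.matrix(profiles)
  if (anyNA(profiles) || !all(is.finite(profiles))) {
    stop("profiles contain missing or non-finite values", call. = FALSE)
  }
  if (ncol(profiles) < 2 && !allow_1d) {
    stop("profiles must have >= 2 dimensions (or set allow_1d = TRUE)",
         call. = FALSE)
  }
  if (nrow(profiles) < 10 * k_range[2]) {
    stop("need at least 10 genes per candidate cluster", call. = FALSE)
  }
  if (all(apply(profiles, 2, stats::sd) < .Machine$double.eps^0.5)) {
    stop("degenerate fit: all profiles are identical", call. = FALSE)
  }

  ks <- seq.int(k_range[1], k_range[2])
  # coarse geometric grid, then refine +/-2 around the coarse winner
  coarse <- unique(round(exp(seq(log(k_range[1]), log(k_range[2]),
                                 length.out = min(8, length(ks))))))
  model_name <- if (ncol(profiles) == 1) "V" else "VVV"
  fit_g <- function(gs) {
    with_seed(seed, {
      suppressWarnings(Mclust(profiles, G = gs, modelNames = model_name,
                              verbose = FALSE))
    })
  }
  fit <- fit_g(coarse)
  if (is.null(fit)) stop("mixture fit failed for every K", call. = FALSE)
  refine <- intersect(seq.int(fit$G - 2L, fit$G + 2L), ks)
  fit2 <- fit_g(refine)
  if (!is.null(fit2) && fit2$bic >= fit$bic) fit <- fit2

  raw <- fit$classification
  sizes <- sort(table(raw), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- as.integer(relabel[as.character(raw)])
  names(cl) <- rownames(profiles)
  centroids <- t(fit$parameters$mean)
  if (ncol(profiles) == 1) centroids <- matrix(fit$parameters$mean, ncol = 1)
  centroids <- centroids[as.integer(names(sizes)), , drop = FALSE]
  rownames(centroids) <- seq_along(sizes)
  out <- list(cluster = cl, K = fit$G,
              sizes = as.integer(sizes),
              centroids = centroids,
              bic = fit$bic, loglik = fit$loglik,
              model = fit)
  class(out) <- "cluster_assignment"
  out
}
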