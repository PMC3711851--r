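#' Fit a Gaussian mixture to a log2 signal distribution
#'
#' Models a dataset's log2 signal distribution as a Gaussian mixture whose
#' lowest-mean component represents array noise (hybridization background),
#' with the remaining components modelling low and high expressed signals.
#' The number of components is selected by BIC over `k_range`; each K is
#' fitted with seeded k-means-style restarts.
#'
#' @param values Numeric vector of log2 signals (>= 50 finite values).
#' @param k_range Length-2 vector `(min, max)` of component counts; min >= 2
#'   (a noise component must be distinguishable from signal).
#' @param seed Integer seed.
#' @param n_init Restarts per K (default 5).
#' @return A `"noise_model"` object: the winning `"gmm1d"` fit with element
#'   `threshold` set to `NA` until [noise_threshold()] is applied.
#' @seealso [noise_threshold()], [call_expressed()]
#' @export
fit_signal_mixture <- function(values, k_range = c(2, 5), seed = 1L,
                               n_init = 5, ...) {
  v <- values[is.finite(values)]
  if (length(v) < 50) {
    stop("need at least 50 finite signal values", call. = FALSE)
  }
  if (k_range[1] < 2) {
    stop_param("k_range", "minimum component count must be >= 2")
  }
  fit <- select_gmm1d(v, k_range = k_range, seed = seed, n_init = n_init, ...)
  fit$threshold <- NA_real_
  class(fit) <- c("noise_model", class(fit))
  fit
}

#' Noise threshold from a fitted signal mixture
#'
#' The expression threshold is the smallest signal value at or above the
#' noise-component mean where the posterior probability of the lowest-mean
#' component drops below 0.5 against the union of the remaining components
#' (the posterior crossover). Found by a bracketed root search to 1e-6.
#'
#' For two equally weighted components with equal sds the crossover is the
#' midpoint of the two means.
#'
#' @param model A `"noise_model"` (or `"gmm1d"`) fit with K >= 2.
#' @return The model with `threshold` set (invisibly also returned as the
#'   attribute-free numeric when `value_only = TRUE`).
#' @param value_only If `TRUE` return just the numeric threshold.
#' @export
noise_threshold <- function(model, value_only = FALSE) {
  if (model$K < 2) {
    stop("noise threshold requires a mixture with K >= 2 components",
         call. = FALSE)
  }
  f <- function(x) posterior_gmm1d(model, x)[, 1] - 0.5
  lo <- model$means[1]
  hi <- max(model$means) + 10 * max(model$sds)
  if (f(lo) <= 0) {
    thr <- lo           # noise never dominates at its own mean
  } else {
    # coarse scan for the first sign change, then bisection via uniroot
    grid <- seq(lo, hi, length.out = 512)
    fg <- f(grid)
    idx <- which(fg <= 0)
    if (length(idx) == 0) {
      stop("posterior of the noise component never drops below 0.5",
           call. = FALSE)
    }
    i <- idx[1]
    thr <- stats::uniroot(f, lower = grid[i - 1], upper = grid[i],
                          tol = 1e-9)$root
  }
  if (value_only) return(thr)
  model$threshold <- thr
  model
}

#' Per-group noise thresholds for an expression matrix
#'
#' Fits [fit_signal_mixture()] to each experimental group's pooled replicate
#' signals and derives each group's noise threshold.
#'
#' @param mat Genes x samples log2 matrix (colnames = sample ids).
#' @param design Design data frame with `sample_id` and `group` columns.
#' @param k_range,seed,n_init Passed to [fit_signal_mixture()].
#' @return Named list of `"noise_model"` objects, one per group, each with
#'   `threshold` set.
#' @export
fit_group_thresholds <- function(mat, design, k_range = c(2, 5), seed = 1L,
                                 n_init = 5, ...) {
  stopifnot(all(design$sample_id %in% colnames(mat)))
  groups <- unique(design$group)
  seeds <- derive_seeds(seed, length(groups))
  out <- lapply(seq_along(groups), function(i) {
    cols <- design$sample_id[design$group == groups[i]]
    noise_threshold(fit_signal_mixture(as.vector(mat[, cols, drop = FALSE]),
                                       k_range = k_range, seed = seeds[i],
                                       n_init = n_init, ...))
  })
  names(out) <- groups
  out
}

#' Call genes expressed above the noise threshold
#'
#' A gene is above noise in a group when the mean of that group's replicate
#' signals exceeds the group's threshold; it is expressed anywhere when this
#' holds in at least one experimental group. The complement of `above_noise`
#' corresponds to the "nl" (below noise level) annotation used in expression
#' report tables.
#'
#' @param mat Genes x samples log2 matrix.
#' @param design Design data frame with `sample_id` and `group` columns.
#' @param thresholds Named numeric vector of per-group thresholds, or the
#'   list returned by [fit_group_thresholds()].
#' @return A list: `above_noise` (genes x groups logical matrix),
#'   `expressed_anywhere` (named logical vector), `group_means` (genes x
#'   groups numeric matrix), `thresholds` (named numeric vector).
#' @export
call_expressed <- function(mat, design, thresholds) {
  if (is.list(thresholds)) {
    thresholds <- vapply(thresholds, function(m) m$threshold, numeric(1))
  }
  groups <- unique(design$group)
  missing <- setdiff(groups, names(thresholds))
  if (length(missing) > 0) {
    stop("no threshold supplied for group(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  gm <- vapply(groups, function(g) {
    cols <- design$sample_id[design$group == g]
    rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  gm <- matrix(gm, ncol = length(groups),
               dimnames = list(rownames(mat), groups))
  above <- sweep(gm, 2, thresholds[groups], ">")
  list(above_noise = above,
       expressed_anywhere = apply(above, 1, any),
       group_means = gm,
       thresholds = thresholds[groups])
}
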