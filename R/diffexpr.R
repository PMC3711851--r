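#' Per-gene signal log ratio for a heat-shock contrast
#'
#' The SLR is the difference of replicate-mean log2 signals, heat-shocked
#' minus control. Genes below the noise threshold in both groups are marked
#' `not_evaluated` (reported as "-"); genes below noise in exactly one group
#' keep their SLR but carry the corresponding `nl` flag. Full precision is
#' kept internally; use [round_half_away()] (2 decimals) when writing report
#' files.
#'
#' @param mat Genes x samples log2 matrix.
#' @param design Design data frame with `sample_id` and `group`.
#' @param calls Result of [call_expressed()] for the same matrix/design.
#' @param contrast Character vector `(control group, heat-shock group)`.
#' @return A `contrast_table` data frame: `gene`, `mean_c`, `mean_hs`, `slr`,
#'   `nl_c`, `nl_hs`, `de_class` (initially `"null"` or `"not_evaluated"`),
#'   `posterior_up`, `posterior_down`.
#' @export
compute_slr <- function(mat, design, calls, contrast) {
  stopifnot(length(contrast) == 2)
  groups <- colnames(calls$above_noise)
  unknown <- setdiff(contrast, groups)
  if (length(unknown) > 0) {
    stop("unknown group(s) in contrast: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ctrl <- contrast[1]; hs <- contrast[2]
  mean_c <- calls$group_means[, ctrl]
  mean_hs <- calls$group_means[, hs]
  nl_c <- !calls$above_noise[, ctrl]
  nl_hs <- !calls$above_noise[, hs]
  not_eval <- nl_c & nl_hs
  out <- data.frame(
    gene = rownames(mat),
    mean_c = mean_c, mean_hs = mean_hs,
    slr = ifelse(not_eval, NA_real_, mean_hs - mean_c),
    nl_c = nl_c, nl_hs = nl_hs,
    de_class = ifelse(not_eval, "not_evaluated", "null"),
    posterior_up = NA_real_, posterior_down = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("contrast_table", class(out))
  out
}

#' Classify genes as induced / repressed / unchanged from the SLR distribution
#'
#' Fits a Gaussian mixture to the evaluated SLR values (BIC over `k_range`),
#' maps each component to a direction by its mean against a dead-band of
#' `+/- dead_band` log2 units (the component with mean nearest zero is always
#' part of the null class), and assigns each gene to the class with the
#' highest summed posterior, ties broken toward null. The significant SLR
#' ranges reported are the min/max observed SLR among genes in each
#' directional class.
#'
#' @param table A `contrast_table` from [compute_slr()].
#' @param k_range Length-2 vector of component counts tried (default
#'   `c(1, 4)`; including K = 1 lets effect-free data select a pure null
#'   solution).
#' @param seed Integer seed.
#' @param dead_band Half-width (log2) of the null dead-band (default 0.1).
#' @param n_init Restarts per K.
#' @return A list: `table` (the input with `de_class`, `posterior_up`,
#'   `posterior_down` filled in) and `mixture` (an `"slr_mixture"`: the
#'   `"gmm1d"` fit plus `class_map`, `range_up`, `range_down`, and per-class
#'   `counts`).
#' @export
classify_slr <- function(table, k_range = c(1, 4), seed = 1L,
                         dead_band = 0.1, n_init = 5, ...) {
  eval_idx <- table$de_class != "not_evaluated"
  slr <- table$slr[eval_idx]
  if (sum(is.finite(slr)) < 100) {
    stop("need at least 100 evaluated SLR values", call. = FALSE)
  }
  if (stats::sd(slr) < .Machine$double.eps^0.5) {
    stop("degenerate fit: all SLR values are identical", call. = FALSE)
  }
  fit <- select_gmm1d(slr, k_range = k_range, seed = seed, n_init = n_init,
                      ...)

  class_map <- ifelse(fit$means > dead_band, "up",
                      ifelse(fit$means < -dead_band, "down", "null"))
  class_map[which.min(abs(fit$means))] <- "null"

  if (fit$K == 1L || all(class_map == "null")) {
    cls <- rep("null", length(slr))
    post_up <- rep(0, length(slr))
    post_down <- rep(0, length(slr))
  } else {
    post <- posterior_gmm1d(fit, slr)
    sum_class <- function(cl) {
      idx <- which(class_map == cl)
      if (length(idx) == 0) rep(0, length(slr))
      else rowSums(post[, idx, drop = FALSE])
    }
    post_up <- sum_class("up")
    post_down <- sum_class("down")
    post_null <- sum_class("null")
    # ties toward null: null wins at equality
    cls <- rep("null", length(slr))
    cls[post_up > post_null & post_up > post_down] <- "up"
    cls[post_down > post_null & post_down >= post_up] <- "down"
  }

  table$de_class[eval_idx] <- cls
  table$posterior_up[eval_idx] <- post_up
  table$posterior_down[eval_idx] <- post_down

  rng <- function(cl) {
    v <- slr[cls == cl]
    if (length(v) == 0) c(NA_real_, NA_real_) else range(v)
  }
  mixture <- fit
  mixture$class_map <- class_map
  mixture$range_up <- rng("up")      # (smallest significant, max) induced SLR
  mixture$range_down <- rng("down")  # (min, largest significant) repressed SLR
  mixture$counts <- c(up = sum(cls == "up"), down = sum(cls == "down"),
                      null = sum(cls == "null"),
                      not_evaluated = sum(!eval_idx))
  class(mixture) <- c("slr_mixture", class(fit))
  list(table = table, mixture = mixture)
}

#' Summarise an SLR mixture in the layout of published contrast tables
#'
#' @param mixture An `"slr_mixture"` from [classify_slr()].
#' @return Data frame with one row per directional class: class, SLR range
#'   (significant bound to extreme), gene count, percent of evaluated genes.
#' @export
slr_summary <- function(mixture) {
  n_eval <- sum(mixture$counts[c("up", "down", "null")])
  data.frame(
    class = c("induction", "repression"),
    slr_from = round_half_away(c(mixture$range_up[1], mixture$range_down[1])),
    slr_to = round_half_away(c(mixture$range_up[2], mixture$range_down[2])),
    n_genes = as.integer(mixture$counts[c("up", "down")]),
    pct_of_evaluated = round_half_away(
      100 * mixture$counts[c("up", "down")] / n_eval),
    row.names = NULL
  )
}
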