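#' Quantile normalization of probe intensities across arrays
#'
#' Each array's sorted values are replaced by the across-array mean of order
#' statistics, so all columns share an identical multiset of values
#' afterwards; ties within a column receive the mean of their quantile
#' targets. Delegates to [limma::normalizeQuantiles()] with tie averaging.
#'
#' @param mat Numeric matrix, probes x arrays (>= 2 arrays).
#' @return Normalized matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 arrays", call. = FALSE)
  if (anyNA(mat)) stop("intensity matrix contains missing values",
                       call. = FALSE)
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Percentile background subtraction
#'
#' Subtracts each array's `pct`-th percentile (linear-interpolation
#' definition, [stats::quantile()] type 7) from its values, flooring at 0.
#'
#' @param x Numeric vector (one array) or matrix (probes x arrays, applied
#'   per column); values must be >= 0.
#' @param pct Percentile to subtract, default 5.
#' @return Background-subtracted values, same shape as `x`.
#' @export
subtract_background <- function(x, pct = 5) {
  if (length(x) == 0) stop("empty intensity array", call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (is.matrix(x)) {
    return(apply(x, 2, subtract_background, pct = pct))
  }
  pmax(x - stats::quantile(x, pct / 100, names = FALSE, type = 7), 0)
}

# reshape a long signals data frame into per-channel probe x replicate
# matrices, preprocessed (quantile normalization across all arrays, then
# per-array percentile background subtraction)
preprocess_chip <- function(signals, normalize = TRUE, background_pct = 5) {
  stopifnot(all(c("probe_id", "channel", "replicate", "intensity")
                %in% names(signals)))
  arrays <- unique(signals[, c("channel", "replicate")])
  arrays <- arrays[order(arrays$channel, arrays$replicate), ]
  probe_ids <- unique(signals$probe_id)
  mat <- matrix(NA_real_, nrow = length(probe_ids), ncol = nrow(arrays),
                dimnames = list(probe_ids,
                                paste(arrays$channel, arrays$replicate,
                                      sep = ".")))
  for (j in seq_len(nrow(arrays))) {
    sel <- signals$channel == arrays$channel[j] &
      signals$replicate == arrays$replicate[j]
    sub <- signals[sel, ]
    if (anyDuplicated(sub$probe_id)) {
      stop("duplicate probe ", sub$probe_id[duplicated(sub$probe_id)][1],
           " within one array", call. = FALSE)
    }
    mat[sub$probe_id, j] <- sub$intensity
  }
  if (anyNA(mat)) {
    stop("probe universe differs between channels/replicates", call. = FALSE)
  }
  # normalize replicate arrays within each channel: AB1 and AB0 replicates
  # are identically distributed by design, while forcing the IP channel onto
  # the mock's distribution would strip out genuine enrichment mass
  if (normalize) {
    for (ch in unique(arrays$channel)) {
      cols <- which(arrays$channel == ch)
      if (length(cols) >= 2) {
        mat[, cols] <- quantile_normalize(mat[, cols, drop = FALSE])
      }
    }
  }
  if (!is.null(background_pct)) mat <- subtract_background(mat, background_pct)
  list(mat = mat,
       ab1_cols = which(arrays$channel == "AB1"),
       ab0_cols = which(arrays$channel == "AB0"))
}

#' Promoter binding score from per-probe AB1 - AB0 differences
#'
#' Per probe, the difference of replicate-mean AB1 and AB0 intensities; the
#' promoter score is the mean of these per-probe differences over all probes
#' annotated to the promoter (arbitrary linear units).
#'
#' @param diffs Numeric vector of per-probe differences (in map order).
#' @return The promoter score.
#' @export
promoter_score <- function(diffs) mean(diffs)

#' Signal-enhancement test for a promoter region
#'
#' One-sided Wilcoxon signed-rank test of the per-probe AB1 - AB0 differences
#' against zero (alternative: positive shift). Zero differences are dropped.
#' For up to 25 non-zero probes without tied absolute values the exact null
#' distribution of the rank sum is used; with ties or more probes, a normal
#' approximation with tie correction and continuity correction.
#'
#' @param diffs Numeric vector of per-probe differences (>= 1 probe).
#' @return List: `p` (the one-sided p value) and `degenerate` (`TRUE` when
#'   all differences are zero, in which case `p = 1`).
#' @export
test_enhancement <- function(diffs) {
  if (length(diffs) < 1) stop("need at least one probe", call. = FALSE)
  d <- diffs[diffs != 0]
  n <- length(d)
  if (n == 0) {
    warning("all probe differences are zero; enhancement p set to 1")
    return(list(p = 1, degenerate = TRUE))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    p <- stats::psignrank(v - 1, n, lower.tail = FALSE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    p <- stats::pnorm((v - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  }
  list(p = min(max(p, 0), 1), degenerate = FALSE)
}

# rolling means of window w along a vector (stats::filter based)
rolling_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 1))[w:length(x)]
}

#' Non-uniformity permutation test for a promoter region
#'
#' Tests whether the AB1 - AB0 differences are positionally concentrated: the
#' statistic is the maximum over all contiguous windows of `window` probes of
#' the window-mean difference, and the null distribution comes from `B`
#' random permutations of the differences across positions within the region.
#' `p = (1 + #\{S_perm >= S_obs\}) / (B + 1)`.
#'
#' @param diffs Per-probe differences in positional order.
#' @param window Window width in probes (default 5).
#' @param B Number of permutations (default 999, >= 1).
#' @param seed Integer seed for the permutations.
#' @return List: `p`, `statistic` (observed S), `short_region` (`TRUE`, with
#'   `p = 1`, when the region has fewer than `window` probes).
#' @export
test_nonuniformity <- function(diffs, window = 5, B = 999, seed = 1L) {
  if (B < 1) stop_param("B", "must be >= 1")
  n <- length(diffs)
  if (n < window) {
    return(list(p = 1, statistic = NA_real_, short_region = TRUE))
  }
  s_obs <- max(rolling_mean(diffs, window))
  if (max(diffs) - min(diffs) < .Machine$double.eps^0.5 * max(1, abs(s_obs))) {
    return(list(p = 1, statistic = s_obs, short_region = FALSE))
  }
  s_perm <- with_seed(seed, {
    # B x n matrix of permuted differences; window sums via row-wise
    # cumulative sums, max window mean per row
    M <- matrix(0, nrow = B, ncol = n)
    for (b in seq_len(B)) M[b, ] <- diffs[sample.int(n)]
    for (j in 2:n) M[, j] <- M[, j] + M[, j - 1]
    ws <- M[, window:n, drop = FALSE] -
      cbind(0, M[, seq_len(n - window), drop = FALSE])
    do.call(pmax, as.data.frame(ws)) / window
  })
  p <- (1 + sum(s_perm >= s_obs - 1e-12)) / (B + 1)
  list(p = p, statistic = s_obs, short_region = FALSE)
}

#' Benjamini-Hochberg FDR and bound calls for promoter results
#'
#' Adjusts the combined per-promoter p values by the Benjamini-Hochberg
#' step-up over all promoters and flags a promoter bound when its score is at
#' least `score_min` AND its adjusted value (q) is below `q_max`.
#'
#' @param results Data frame with at least `score` and `p_comb` columns.
#' @param score_min Minimum AB1 - AB0 promoter score (default 15).
#' @param q_max FDR threshold (default 0.05).
#' @return The data frame with `q` and `bound` columns added.
#' @export
call_bound <- function(results, score_min = 15, q_max = 0.05) {
  stopifnot(all(c("score", "p_comb") %in% names(results)))
  results$q <- stats::p.adjust(results$p_comb, method = "BH")
  results$bound <- results$score >= score_min & results$q < q_max
  results
}

#' Full promoter binding caller
#'
#' Runs the complete tiling-ChIP pipeline for every promoter in the map:
#' quantile normalization across arrays, percentile background subtraction,
#' per-probe AB1 - AB0 differencing (replicates averaged per channel),
#' promoter-mean scoring, signal-enhancement (signed-rank) and non-uniformity
#' (permutation) tests, intersection-union combination
#' `p_comb = max(p_enh, p_nonunif)`, BH FDR, and bound calls.
#'
#' @param signals Long data frame `probe_id`, `channel`, `replicate`,
#'   `intensity` (linear scale).
#' @param map BED-like data frame `chrom`, `start`, `end`, `probe_id`,
#'   `promoter_id`, `strand`.
#' @param score_min,q_max Bound-call thresholds (defaults 15 and 0.05).
#' @param window,B Non-uniformity test parameters.
#' @param seed Integer seed (one independent permutation stream per
#'   promoter).
#' @param normalize Quantile-normalize across arrays first (default TRUE).
#' @param background_pct Percentile for background subtraction (default 5;
#'   `NULL` to skip).
#' @return Data frame, one row per promoter: `promoter_id`, `n_probes`,
#'   `score`, `p_enh`, `p_nonunif`, `p_comb`, `q`, `bound`, `short_region`.
#' @export
call_binding <- function(signals, map, score_min = 15, q_max = 0.05,
                         window = 5, B = 999, seed = 1L,
                         normalize = TRUE, background_pct = 5) {
  prep <- preprocess_chip(signals, normalize = normalize,
                          background_pct = background_pct)
  ab1 <- rowMeans(prep$mat[, prep$ab1_cols, drop = FALSE])
  ab0 <- rowMeans(prep$mat[, prep$ab0_cols, drop = FALSE])
  dprobe <- ab1 - ab0

  promoters <- unique(map$promoter_id)
  seeds <- derive_seeds(seed, length(promoters))
  rows <- vector("list", length(promoters))
  for (i in seq_along(promoters)) {
    pm <- map[map$promoter_id == promoters[i], , drop = FALSE]
    pm <- pm[order(pm$start), , drop = FALSE]
    missing <- setdiff(pm$probe_id, names(dprobe))
    if (length(missing) > 0) {
      stop("no signal for probe(s) ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    d <- dprobe[pm$probe_id]
    enh <- test_enhancement(d)
    nun <- test_nonuniformity(d, window = window, B = B, seed = seeds[i])
    rows[[i]] <- data.frame(
      promoter_id = promoters[i], n_probes = length(d),
      score = promoter_score(d),
      p_enh = enh$p, p_nonunif = nun$p,
      p_comb = max(enh$p, nun$p),
      short_region = isTRUE(nun$short_region),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  res <- call_bound(res, score_min = score_min, q_max = q_max)
  res[, c("promoter_id", "n_probes", "score", "p_enh", "p_nonunif",
          "p_comb", "q", "bound", "short_region")]
}
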