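#' Percentages for a binding/expression crosstab from its counts
#'
#' Given the number of bound, induced and repressed genes and the overlap
#' counts, computes the four percentage cells (bound-and-induced as % of all
#' induced and % of all bound; bound-and-repressed as % of all repressed and
#' % of all bound), rounded half-away-from-zero to 2 decimals.
#'
#' @param n_bound,n_induced,n_repressed Class totals.
#' @param n_bound_induced,n_bound_repressed Overlap counts.
#' @return A list with the counts and `pct_of_induced`, `pct_of_bound_up`,
#'   `pct_of_repressed`, `pct_of_bound_down`.
#' @export
crosstab_percentages <- function(n_bound, n_induced, n_repressed,
                                 n_bound_induced, n_bound_repressed) {
  stopifnot(n_bound_induced <= min(n_bound, n_induced),
            n_bound_repressed <= min(n_bound, n_repressed))
  pct <- function(num, den) {
    if (den == 0) 0 else round_half_away(100 * num / den, 2)
  }
  list(
    n_bound = n_bound, n_induced = n_induced, n_repressed = n_repressed,
    n_bound_induced = n_bound_induced, n_bound_repressed = n_bound_repressed,
    pct_of_induced = pct(n_bound_induced, n_induced),
    pct_of_bound_up = pct(n_bound_induced, n_bound),
    pct_of_repressed = pct(n_bound_repressed, n_repressed),
    pct_of_bound_down = pct(n_bound_repressed, n_bound)
  )
}

#' Crosstab of bound genes against differential-expression classes
#'
#' Intersects a bound gene set with the induced and repressed classes of a
#' contrast table and reports counts plus the four percentages.
#'
#' @param bound Character vector of bound gene ids.
#' @param contrast A `contrast_table` with `de_class` filled in (from
#'   [classify_slr()]).
#' @return As [crosstab_percentages()].
#' @export
crosstab <- function(bound, contrast) {
  induced <- contrast$gene[contrast$de_class == "up"]
  repressed <- contrast$gene[contrast$de_class == "down"]
  crosstab_percentages(
    n_bound = length(unique(bound)),
    n_induced = length(induced),
    n_repressed = length(repressed),
    n_bound_induced = length(intersect(bound, induced)),
    n_bound_repressed = length(intersect(bound, repressed))
  )
}

#' Pairwise and three-way overlaps of named gene sets
#'
#' @param sets Named list of >= 2 character vectors.
#' @return Data frame of intersection counts for every pair and, when three
#'   or more sets are given, every triple: columns `sets` (names joined by
#'   " & ") and `n`.
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be named", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  combos <- c(utils::combn(names(sets), 2, simplify = FALSE),
              if (length(sets) >= 3) {
                utils::combn(names(sets), 3, simplify = FALSE)
              })
  data.frame(
    sets = vapply(combos, paste, character(1), collapse = " & "),
    n = vapply(combos, function(nm) {
      length(Reduce(intersect, sets[nm]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# exact two-sided permutation p for Spearman rho on n <= 10 pairs:
# enumerate permutations of the y-ranks in chunks over the first element
spearman_perm_p <- function(rx, ry) {
  n <- length(rx)
  rho_obs <- stats::cor(rx, ry)
  perms_of <- function(v) {
    m <- matrix(v[1], 1, 1)
    for (k in seq_along(v)[-1]) {
      m <- do.call(rbind, lapply(seq_len(k), function(pos) {
        cbind(m[, seq_len(pos - 1), drop = FALSE], v[k],
              m[, seq_len(k - 1) >= pos, drop = FALSE])
      }))
    }
    m
  }
  sx <- sum((rx - mean(rx))^2)
  sy <- sum((ry - mean(ry))^2)
  cnt <- 0; tot <- 0
  for (i in seq_len(n)) {
    rest <- perms_of(ry[-i])
    block <- cbind(ry[i], rest)
    rho_b <- (block %*% (rx - mean(rx)) - 0) / sqrt(sx * sy)
    # centre: sum(block_j * rxc) already centred since sum(rxc)=0
    cnt <- cnt + sum(abs(rho_b) >= abs(rho_obs) - 1e-12)
    tot <- tot + nrow(block)
  }
  cnt / tot
}

#' Spearman correlation between promoter binding and expression change
#'
#' Joins a contrast table with promoter binding results by gene id (a gene
#' with several promoters takes its maximum score), applies the inclusion
#' filters -- gene evaluated, SLR non-zero with the requested sign, promoter
#' score positive (AB1 > AB0) -- and computes the average-rank Spearman
#' correlation between score and SLR. The p value is two-sided: an exact
#' permutation tail for n <= 10, a t approximation for n > 10.
#'
#' @param contrast A `contrast_table` with `de_class` filled in.
#' @param binding Promoter binding results from [call_binding()]
#'   (`promoter_id` interpreted as the gene accession).
#' @param direction `"up"` (SLR > 0) or `"down"` (SLR < 0).
#' @return List: `n`, `rho`, `p`. With fewer than 3 usable pairs `rho` and
#'   `p` are `NA` and `insufficient` is `TRUE`.
#' @export
spearman_binding_expression <- function(contrast, binding,
                                        direction = c("up", "down")) {
  direction <- match.arg(direction)
  score <- tapply(binding$score, binding$promoter_id, max)
  idx <- contrast$de_class != "not_evaluated" &
    !is.na(contrast$slr) & contrast$slr != 0 &
    (if (direction == "up") contrast$slr > 0 else contrast$slr < 0) &
    contrast$gene %in% names(score)
  g <- contrast$gene[idx]
  x <- as.numeric(score[g])
  y <- contrast$slr[idx]
  keep <- x > 0                       # AB1 > AB0 only
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(list(n = n, rho = NA_real_, p = NA_real_, insufficient = TRUE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 10) {
    p <- spearman_perm_p(rx, ry)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(n = n, rho = rho, p = min(p, 1), insufficient = FALSE)
}
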