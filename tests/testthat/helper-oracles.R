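# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / enumeration, never through the package's own
# code paths.

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
hyper_upper_enum <- function(k, n, K_term, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K_term)   # genes 1..K_term carry the term
  mean(hits >= k)
}

# Benjamini-Hochberg step-up by its definition: q_i = min_{j: p_(j) >= p_(i)}
# min(1, p_(j) * m / j)
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, p[o] * m / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# dense-grid posterior-crossover oracle for the noise threshold of a
# two-component mixture
threshold_grid_oracle <- function(w, mu, s, step = 1e-5) {
  grid <- seq(mu[1], max(mu) + 10 * max(s), by = step)
  post1 <- w[1] * dnorm(grid, mu[1], s[1]) /
    (w[1] * dnorm(grid, mu[1], s[1]) + w[2] * dnorm(grid, mu[2], s[2]))
  grid[which(post1 < 0.5)[1]]
}

# all permutations of a vector, iterative insertion (independent of the
# package's internal enumerator)
all_perms <- function(v) {
  out <- matrix(v[1], 1, 1)
  for (k in seq_along(v)[-1]) {
    n0 <- nrow(out)
    blocks <- lapply(seq_len(k), function(pos) {
      left <- out[, seq_len(pos - 1), drop = FALSE]
      right <- out[, setdiff(seq_len(k - 1), seq_len(pos - 1)),
                   drop = FALSE]
      cbind(left, v[k], right)
    })
    out <- do.call(rbind, blocks)
  }
  out
}

# adjusted Rand index between two labelings (closed-form from the
# contingency table)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- ai * bj / n2
  (nij - exp_) / ((ai + bj) / 2 - exp_)
}

# a gmm1d-shaped model built by hand (no EM) for threshold tests
manual_gmm2 <- function(w, mu, s) {
  m <- list(K = 2L, weights = w, means = mu, sds = s)
  class(m) <- "gmm1d"
  m
}

# contrast table built directly from an SLR vector (for classification tests
# that plant the SLR distribution itself)
slr_table <- function(slr) {
  tab <- data.frame(
    gene = sprintf("g%05d", seq_along(slr)),
    mean_c = 0, mean_hs = slr, slr = slr,
    nl_c = FALSE, nl_hs = FALSE,
    de_class = "null", posterior_up = NA_real_, posterior_down = NA_real_,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("contrast_table", class(tab))
  tab
}
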