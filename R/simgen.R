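#' Parameters for the synthetic expression-matrix generator
#'
#' Describes a desk-scale emulation of a log2 microarray expression dataset:
#' per-gene baselines drawn from a three-component (noise / low / high)
#' Gaussian mixture, replicate noise around the baseline, and planted
#' log2-shift effects in heat-shock groups for a fraction of the expressed
#' (non-noise) genes.
#'
#' Defaults: mixture weights (0.35, 0.40, 0.25), means (4.5, 7.0, 10.0) and
#' sds (0.6, 1.0, 1.2) log2 units, replicate sd 0.25, so that simulated
#' signals span roughly 4-13 log2, the range typical of normalized arrays.
#'
#' @param n_genes Number of genes.
#' @param groups Data frame with columns `cell_type` and `condition`, one row
#'   per experimental group. Conditions other than `"C"` are treated as
#'   heat-shock groups and receive the planted effects.
#' @param n_reps Replicates per group (>= 2).
#' @param mixture List with numeric vectors `weights`, `means`, `sds` of equal
#'   length; weights must sum to 1. The lowest-mean component is the noise
#'   component; genes drawn from it are never differentially expressed.
#' @param rep_sd Replicate noise sd (log2 units).
#' @param frac_up,frac_down Fractions of expressed genes shifted up/down in
#'   heat-shock groups; their sum must be <= 1.
#' @param effect_up,effect_down Length-2 vectors `(mean, sd)` of the log2
#'   shift magnitude for up- and down-shifted genes.
#' @param floor Lower bound applied to every simulated signal (log2 units).
#' @param seed Integer seed.
#' @return A validated parameter list of class `"sim_expr_params"`.
#' @export
sim_expr_params <- function(n_genes = 15000,
                            groups = data.frame(
                              cell_type = c("SC", "SC"),
                              condition = c("C", "HS")
                            ),
                            n_reps = 3,
                            mixture = list(
                              weights = c(0.35, 0.40, 0.25),
                              means = c(4.5, 7.0, 10.0),
                              sds = c(0.6, 1.0, 1.2)
                            ),
                            rep_sd = 0.25,
                            frac_up = 0.03, frac_down = 0.03,
                            effect_up = c(1.5, 0.4),
                            effect_down = c(1.5, 0.4),
                            floor = 3.0,
                            seed = 1L) {
  check_flag(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be >= 1")
  check_flag(is.data.frame(groups) &&
               all(c("cell_type", "condition") %in% names(groups)),
             "groups", "needs columns cell_type, condition")
  check_flag(n_reps >= 2, "n_reps", "must be >= 2")
  check_flag(length(mixture$weights) == length(mixture$means) &&
               length(mixture$means) == length(mixture$sds),
             "mixture", "weights/means/sds lengths differ")
  check_flag(abs(sum(mixture$weights) - 1) < 1e-9, "mixture",
             "weights must sum to 1")
  check_flag(all(mixture$sds > 0), "mixture", "all sds must be > 0")
  check_flag(frac_up >= 0 && frac_down >= 0 && frac_up + frac_down <= 1,
             "frac_up", "frac_up + frac_down must lie in [0, 1]")
  check_flag(length(effect_up) == 2 && effect_up[2] >= 0,
             "effect_up", "must be (mean, sd) with sd >= 0")
  check_flag(length(effect_down) == 2 && effect_down[2] >= 0,
             "effect_down", "must be (mean, sd) with sd >= 0")
  check_flag(rep_sd > 0, "rep_sd", "must be > 0")
  p <- list(n_genes = as.integer(n_genes), groups = groups,
            n_reps = as.integer(n_reps), mixture = mixture, rep_sd = rep_sd,
            frac_up = frac_up, frac_down = frac_down,
            effect_up = effect_up, effect_down = effect_down,
            floor = floor, seed = as.integer(seed))
  class(p) <- "sim_expr_params"
  p
}

#' Generate a synthetic expression matrix with known truth
#'
#' Draws per-gene baselines from the configured noise/low/high mixture, adds
#' planted log2 shifts to heat-shock groups for a random subset of expressed
#' genes, and adds replicate noise. Random variates are consumed gene by gene
#' from a single seeded stream, so enlarging `n_genes` leaves earlier genes'
#' values unchanged.
#'
#' @param params A [sim_expr_params()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{matrix}{numeric matrix, genes x samples, log2 signals floored at
#'       `params$floor`; rownames are gene ids, colnames are sample ids.}
#'     \item{design}{data frame `sample_id`, `cell_type`, `condition`,
#'       `replicate`, `group` (cell_type.condition).}
#'     \item{truth}{data frame per gene: `gene`, `component` (mixture
#'       component index), `expressed` (not drawn from the noise component),
#'       `de_class` (`"up"`, `"down"`, `"null"`), `effect` (log2 shift, 0 for
#'       null genes).}
#'   }
#' @export
gen_expression <- function(params) {
  stopifnot(inherits(params, "sim_expr_params"))
  p <- params
  n <- p$n_genes
  grp <- p$groups
  n_groups <- nrow(grp)
  group_id <- paste(grp$cell_type, grp$condition, sep = ".")
  is_hs <- grp$condition != "C"
  n_cols <- n_groups * p$n_reps

  # fixed variate budget per gene, consumed gene-major:
  # component u, baseline z, de u, effect z, then replicate noise
  m <- 4 + n_cols
  # one uniform stream, consumed gene-major; normal variates via qnorm so a
  # gene's draws occupy a contiguous block and earlier genes are prefix-stable
  U <- with_seed(p$seed, matrix(stats::runif(n * m), nrow = n, byrow = TRUE))
  draws <- list(u = U, z = stats::qnorm(U))

  w <- p$mixture$weights
  ord <- order(p$mixture$means)
  mw <- w[ord]; mm <- p$mixture$means[ord]; ms <- p$mixture$sds[ord]
  comp <- findInterval(draws$u[, 1], cumsum(mw), left.open = TRUE) + 1L
  baseline <- mm[comp] + ms[comp] * draws$z[, 2]
  expressed <- comp > 1L

  de_class <- rep("null", n)
  u_de <- draws$u[, 3]
  de_class[expressed & u_de < p$frac_up] <- "up"
  de_class[expressed & u_de >= p$frac_up &
             u_de < p$frac_up + p$frac_down] <- "down"
  effect <- numeric(n)
  effect[de_class == "up"] <-
    p$effect_up[1] + p$effect_up[2] * draws$z[de_class == "up", 4]
  effect[de_class == "down"] <-
    -(p$effect_down[1] + p$effect_down[2] * draws$z[de_class == "down", 4])

  genes <- sprintf("g%05d", seq_len(n))
  sample_id <- character(n_cols)
  mat <- matrix(0, nrow = n, ncol = n_cols,
                dimnames = list(genes, NULL))
  col <- 0L
  for (g in seq_len(n_groups)) {
    mu <- baseline + if (is_hs[g]) effect else 0
    for (r in seq_len(p$n_reps)) {
      col <- col + 1L
      sample_id[col] <- sprintf("%s.r%d", group_id[g], r)
      mat[, col] <- mu + p$rep_sd * draws$z[, 4 + col]
    }
  }
  mat <- pmax(mat, p$floor)
  colnames(mat) <- sample_id

  design <- data.frame(
    sample_id = sample_id,
    cell_type = rep(grp$cell_type, each = p$n_reps),
    condition = rep(grp$condition, each = p$n_reps),
    replicate = rep(seq_len(p$n_reps), times = n_groups),
    group = rep(group_id, each = p$n_reps),
    stringsAsFactors = FALSE
  )
  truth <- data.frame(gene = genes, component = comp, expressed = expressed,
                      de_class = de_class, effect = effect,
                      stringsAsFactors = FALSE)
  list(matrix = mat, design = design, truth = truth)
}

#' Parameters for the synthetic promoter tiling-ChIP generator
#'
#' Emulates probe-level AB1 (antibody) / AB0 (mock) intensities on promoter
#' tiling regions: lognormal background on both channels, plus a Gaussian
#' positional enrichment bump added to AB1 at a planted subset of promoters.
#'
#' The enrichment kernel is mean-normalized over the region, so `amplitude`
#' is the expected promoter score (promoter-mean AB1 - AB0) in arbitrary
#' linear units while the positional profile stays a Gaussian bump.
#'
#' Defaults were chosen once as a realistic desk-scale emulation: 18-24
#' probes per tiled promoter region (tiling arrays cover promoters with many
#' overlapping probes), triplicate immunoprecipitations per channel, a
#' lognormal background around 40 arbitrary units with ~8% coefficient of
#' variation (normalized tiling arrays are tight), 10% of promoters bound
#' with amplitudes Uniform(20, 120) arbitrary units so promoter scores span
#' the 10-160 range typical of published promoter-binding values, and a
#' positional spread of 3.5 probes reflecting sonication-fragment smearing
#' of the immunoprecipitated signal across neighbouring probes.
#'
#' @param n_promoters Number of promoter regions.
#' @param probes_per_promoter Length-2 integer vector `(min, max)`; min >= 3.
#' @param n_reps Replicates per channel.
#' @param background Length-2 vector `(log-mean, log-sd)` of the lognormal
#'   probe background (linear intensity scale).
#' @param frac_bound Fraction of promoters with planted enrichment, in [0, 1].
#' @param amplitude Length-2 vector `(min, max)` of the uniform peak-height
#'   range (linear units); min > 0.
#' @param peak_sd Positional spread of the enrichment kernel, in probes.
#' @param seed Integer seed.
#' @return A validated parameter list of class `"sim_chip_params"`.
#' @export
sim_chip_params <- function(n_promoters = 500,
                            probes_per_promoter = c(18L, 24L),
                            n_reps = 3,
                            background = c(log(40), 0.08),
                            frac_bound = 0.1,
                            amplitude = c(20, 120),
                            peak_sd = 3.5,
                            seed = 1L) {
  check_flag(n_promoters >= 1, "n_promoters", "must be >= 1")
  check_flag(length(probes_per_promoter) == 2 &&
               probes_per_promoter[1] >= 3 &&
               probes_per_promoter[2] >= probes_per_promoter[1],
             "probes_per_promoter", "min must be >= 3 and <= max")
  check_flag(n_reps >= 1, "n_reps", "must be >= 1")
  check_flag(length(background) == 2 && background[2] > 0,
             "background", "must be (log-mean, log-sd) with log-sd > 0")
  check_flag(frac_bound >= 0 && frac_bound <= 1, "frac_bound",
             "must lie in [0, 1]")
  check_flag(length(amplitude) == 2 && amplitude[1] > 0 &&
               amplitude[2] >= amplitude[1],
             "amplitude", "min must be > 0 and <= max")
  check_flag(peak_sd > 0, "peak_sd", "must be > 0")
  p <- list(n_promoters = as.integer(n_promoters),
            probes_per_promoter = as.integer(probes_per_promoter),
            n_reps = as.integer(n_reps), background = background,
            frac_bound = frac_bound, amplitude = amplitude,
            peak_sd = peak_sd, seed = as.integer(seed))
  class(p) <- "sim_chip_params"
  p
}

#' Generate synthetic probe-level ChIP signals with known truth
#'
#' AB0 replicate intensities are pure lognormal background; AB1 adds, at
#' bound promoters, `amplitude * k_i` where the positional weights
#' `k_i = exp(-(i - peak)^2 / (2 * peak_sd^2))`, rescaled to mean 1 over the
#' region's probes, so the planted amplitude equals the expected promoter
#' score. Probe coordinates are emitted 0-based half-open on a synthetic
#' chromosome (`chrS`), 25 bp probes spaced 35 bp apart. Variates are consumed
#' promoter by promoter from one seeded stream, so enlarging `n_promoters`
#' leaves earlier promoters unchanged.
#'
#' @param params A [sim_chip_params()] object.
#' @param bound Optional logical vector (length `n_promoters`) overriding the
#'   random bound/unbound assignment, e.g. to couple binding to a planted
#'   expression effect.
#' @param amplitude Optional numeric vector of peak heights for bound
#'   promoters (recycled against `bound`); overrides the uniform draw.
#' @param promoter_ids Optional character vector of promoter (gene accession)
#'   ids; defaults to `p00001...`.
#' @return A list with elements:
#'   \describe{
#'     \item{signals}{data frame `probe_id`, `channel` (`"AB1"`/`"AB0"`),
#'       `replicate`, `intensity` (linear, >= 0).}
#'     \item{map}{BED-like data frame `chrom`, `start`, `end`, `probe_id`,
#'       `promoter_id`, `strand` (0-based half-open).}
#'     \item{truth}{data frame per promoter: `promoter_id`, `bound`,
#'       `amplitude` (0 when unbound), `peak_index` (NA when unbound),
#'       `n_probes`.}
#'   }
#' @export
gen_chip <- function(params, bound = NULL, amplitude = NULL,
                     promoter_ids = NULL) {
  stopifnot(inherits(params, "sim_chip_params"))
  p <- params
  n <- p$n_promoters
  if (is.null(promoter_ids)) promoter_ids <- sprintf("p%05d", seq_len(n))
  check_flag(length(promoter_ids) == n, "promoter_ids", "length mismatch")
  if (!is.null(bound)) {
    check_flag(is.logical(bound) && length(bound) == n, "bound",
               "must be logical of length n_promoters")
  }
  pmin_ <- p$probes_per_promoter[1]; pmax_ <- p$probes_per_promoter[2]
  # fixed variate budget per promoter: n_probes u, bound u, amplitude u,
  # peak u, then intensities for max probes x reps x 2 channels
  m_int <- pmax_ * p$n_reps * 2
  m <- 4 + m_int
  U <- with_seed(p$seed, matrix(stats::runif(n * m), nrow = n, byrow = TRUE))
  draws <- list(u = U, z = stats::qnorm(U))

  n_probes <- pmin_ + floor(draws$u[, 1] * (pmax_ - pmin_ + 1))
  n_probes <- pmin(n_probes, pmax_)
  is_bound <- if (is.null(bound)) draws$u[, 2] < p$frac_bound else bound
  amp <- p$amplitude[1] + draws$u[, 3] * diff(p$amplitude)
  if (!is.null(amplitude)) amp <- rep_len(amplitude, n)
  amp[!is_bound] <- 0
  # peak placed in the central half of the region (binding near the TSS,
  # which tiling regions are centred on)
  lo <- pmax(1, ceiling(n_probes * 0.25))
  hi <- pmax(lo, floor(n_probes * 0.75))
  peak_index <- lo + floor(draws$u[, 4] * (hi - lo + 1))
  peak_index <- pmin(peak_index, hi)
  peak_index[!is_bound] <- NA_integer_

  sig_list <- vector("list", n)
  map_list <- vector("list", n)
  pos <- 0L
  chan_names <- c("AB1", "AB0")
  for (i in seq_len(n)) {
    k <- n_probes[i]
    probe_id <- sprintf("%s_probe%02d", promoter_ids[i], seq_len(k))
    start <- pos + (seq_len(k) - 1L) * 35L
    map_list[[i]] <- data.frame(
      chrom = "chrS", start = start, end = start + 25L,
      probe_id = probe_id, promoter_id = promoter_ids[i], strand = "+",
      stringsAsFactors = FALSE
    )
    pos <- pos + k * 35L + 500L
    bump <- if (is_bound[i]) {
      kern <- exp(-((seq_len(k) - peak_index[i])^2) / (2 * p$peak_sd^2))
      amp[i] * kern / mean(kern)
    } else rep(0, k)
    z <- draws$z[i, 4 + seq_len(k * p$n_reps * 2)]
    bg <- exp(p$background[1] + p$background[2] * z)
    # layout: channel-major, then replicate, then probe
    dim(bg) <- c(k, p$n_reps, 2)
    bg[, , 1] <- bg[, , 1] + bump     # AB1 gets the enrichment bump
    sig_list[[i]] <- data.frame(
      probe_id = rep(probe_id, times = p$n_reps * 2),
      channel = rep(chan_names, each = k * p$n_reps),
      replicate = rep(rep(seq_len(p$n_reps), each = k), times = 2),
      intensity = c(bg),
      stringsAsFactors = FALSE
    )
  }
  truth <- data.frame(promoter_id = promoter_ids, bound = is_bound,
                      amplitude = amp, peak_index = peak_index,
                      n_probes = n_probes, stringsAsFactors = FALSE)
  list(signals = do.call(rbind, sig_list),
       map = do.call(rbind, map_list),
       truth = truth)
}

#' Generate a synthetic gene-to-term annotation with one planted term
#'
#' Builds an acyclic term DAG of depth <= 3 (a root, mid-level terms, and
#' leaves) over a gene universe, assigns random gene sets to leaves, and
#' plants one designated leaf term whose gene set overlaps a designated query
#' set at a chosen fraction.
#'
#' @param n_genes Universe size.
#' @param n_terms Number of leaf terms (>= 2).
#' @param planted_term_overlap Fraction in [0, 1] of the planted term's genes
#'   that are shared with the returned query set.
#' @param term_size Genes drawn per leaf term.
#' @param seed Integer seed.
#' @return A list with elements:
#'   \describe{
#'     \item{annotation}{a term annotation as used by
#'       [conditional_enrichment()]: list with `term_genes` (named list of
#'       direct gene sets), `parents` (named list term -> parent ids),
#'       `universe` (character vector).}
#'     \item{query}{character vector, the designated query gene set.}
#'     \item{planted_term}{id of the planted leaf term.}
#'   }
#' @export
gen_annotation <- function(n_genes = 2000, n_terms = 20,
                           planted_term_overlap = 1.0,
                           term_size = 40, seed = 1L) {
  check_flag(n_terms >= 2, "n_terms", "must be >= 2")
  check_flag(planted_term_overlap >= 0 && planted_term_overlap <= 1,
             "planted_term_overlap", "must lie in [0, 1]")
  genes <- sprintf("g%05d", seq_len(n_genes))
  with_seed(seed, {
    leaf_ids <- sprintf("T%03d", seq_len(n_terms))
    n_mid <- max(1L, n_terms %/% 5L)
    mid_ids <- sprintf("M%02d", seq_len(n_mid))
    root <- "ROOT"
    parents <- c(
      stats::setNames(as.list(sample(mid_ids, n_terms, replace = TRUE)),
                      leaf_ids),
      stats::setNames(rep(list(root), n_mid), mid_ids),
      stats::setNames(list(character(0)), root)
    )
    term_genes <- lapply(leaf_ids, function(t) {
      sample(genes, min(term_size, n_genes))
    })
    names(term_genes) <- leaf_ids
    term_genes[mid_ids] <- list(character(0))
    term_genes[[root]] <- character(0)

    planted <- leaf_ids[1]
    tg <- term_genes[[planted]]
    n_in <- round(planted_term_overlap * length(tg))
    inside <- if (n_in > 0) sample(tg, n_in) else character(0)
    outside_pool <- setdiff(genes, tg)
    n_out <- length(tg) - n_in
    outside <- if (n_out > 0) sample(outside_pool, n_out) else character(0)
    query <- c(inside, outside)

    list(
      annotation = list(term_genes = term_genes, parents = parents,
                        universe = genes),
      query = query,
      planted_term = planted
    )
  })
}

#' Generate a linked expression + binding study with known truth
#'
#' Convenience wrapper for end-to-end runs: generates an expression matrix
#' (control vs heat shock) with [gen_expression()], then a promoter tiling
#' ChIP dataset whose promoters are a subset of the genes, with the planted
#' bound promoters drawn from the up-shifted genes and peak amplitudes
#' increasing monotonically in the planted expression effect (larger
#' induction, stronger binding). This plants a positive binding-expression
#' association for the up-regulated class, the situation a factor acting as
#' a transcriptional activator produces.
#'
#' @param expr_params A [sim_expr_params()] object.
#' @param chip_params A [sim_chip_params()] object (its `frac_bound` sets how
#'   many of the `n_promoters` are bound).
#' @param seed Integer seed for the promoter/gene coupling.
#' @return A list: `expr` (from [gen_expression()]), `chip` (from
#'   [gen_chip()], promoter ids are gene ids), `bound_genes` (character).
#' @export
gen_linked_study <- function(expr_params = sim_expr_params(),
                             chip_params = sim_chip_params(),
                             seed = 1L) {
  expr <- gen_expression(expr_params)
  n_prom <- chip_params$n_promoters
  n_bound <- round(chip_params$frac_bound * n_prom)
  with_seed(seed, {
    up_genes <- expr$truth$gene[expr$truth$de_class == "up"]
    if (length(up_genes) < n_bound) {
      stop("not enough planted up-shifted genes to host bound promoters",
           call. = FALSE)
    }
    bound_genes <- sample(up_genes, n_bound)
    other <- sample(expr$truth$gene[expr$truth$de_class == "null"],
                    n_prom - n_bound)
    promoter_ids <- sample(c(bound_genes, other))
    bound <- promoter_ids %in% bound_genes
    # amplitude increases monotonically in the planted effect
    eff <- expr$truth$effect[match(promoter_ids, expr$truth$gene)]
    amp <- rep(0, n_prom)
    r <- rank(eff[bound], ties.method = "first")
    amp[bound] <- chip_params$amplitude[1] +
      diff(chip_params$amplitude) * (r - 1) / max(1, length(r) - 1)
    chip <- gen_chip(chip_params, bound = bound, amplitude = amp,
                     promoter_ids = promoter_ids)
    list(expr = expr, chip = chip, bound_genes = bound_genes)
  })
}
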