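#' Write / read an expression matrix with its design sheet
#'
#' Plain UTF-8 TSV with '.' decimals: the matrix has genes in rows (first
#' column `gene`) and one column per sample; the design sheet has columns
#' `sample_id`, `cell_type`, `condition`, `replicate` (a `group` column is
#' derived on read as `cell_type.condition`).
#'
#' @param mat Genes x samples numeric matrix.
#' @param design Design data frame.
#' @param matrix_path,design_path File paths.
#' @name expression_io
NULL

#' @rdname expression_io
#' @export
write_expression <- function(mat, design, matrix_path, design_path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    design[, c("sample_id", "cell_type", "condition", "replicate")],
    design_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, design_path))
}

#' @rdname expression_io
#' @export
read_expression <- function(matrix_path, design_path) {
  df <- utils::read.delim(matrix_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") {
    stop("expression matrix must have `gene` as its first column",
         call. = FALSE)
  }
  if (anyDuplicated(df$gene)) {
    stop("duplicated gene id: ", df$gene[duplicated(df$gene)][1],
         call. = FALSE)
  }
  design <- utils::read.delim(design_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_type", "condition", "replicate")
  if (!all(need %in% names(design))) {
    stop("design sheet must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  samples <- names(df)[-1]
  if (!setequal(samples, design$sample_id)) {
    bad <- c(setdiff(design$sample_id, samples), setdiff(samples,
                                                         design$sample_id))
    stop("sample mismatch between matrix header and design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    stop("non-numeric expression values found", call. = FALSE)
  }
  rownames(mat) <- df$gene
  design$group <- paste(design$cell_type, design$condition, sep = ".")
  list(matrix = mat[, design$sample_id, drop = FALSE], design = design)
}

#' Write / read probe-level ChIP signals
#'
#' Long TSV with columns `probe_id`, `channel` (AB1/AB0), `replicate`,
#' `intensity`.
#'
#' @param signals Long signals data frame.
#' @param path File path.
#' @name chip_io
NULL

#' @rdname chip_io
#' @export
write_chip_signals <- function(signals, path) {
  utils::write.table(signals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname chip_io
#' @export
read_chip_signals <- function(path) {
  sig <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("probe_id", "channel", "replicate", "intensity")
  if (!all(need %in% names(sig))) {
    stop("signals file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(sig$intensity) || anyNA(sig$intensity)) {
    stop("non-numeric intensity values found", call. = FALSE)
  }
  sig
}

#' Write / read a BED-like promoter probe map
#'
#' Columns `chrom`, `start`, `end`, `probe_id`, `promoter_id`, `strand`;
#' coordinates 0-based half-open. On read, probes are grouped by promoter and
#' sorted by start (with a warning when input order needed fixing); a probe
#' assigned to two promoters or an empty interval is an error.
#'
#' @param map Promoter map data frame.
#' @param path File path.
#' @name promoter_map_io
NULL

#' @rdname promoter_map_io
#' @export
write_promoter_map <- function(map, path) {
  utils::write.table(
    map[, c("chrom", "start", "end", "probe_id", "promoter_id", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname promoter_map_io
#' @export
read_promoter_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "probe_id", "promoter_id", "strand")
  if (!all(need %in% names(map))) {
    stop("promoter map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(map$start >= map$end)) {
    bad <- map$probe_id[map$start >= map$end][1]
    stop("empty or inverted interval (start >= end) at probe ", bad,
         call. = FALSE)
  }
  if (anyDuplicated(map$probe_id)) {
    stop("probe assigned more than once: ",
         map$probe_id[duplicated(map$probe_id)][1], call. = FALSE)
  }
  ord <- order(match(map$promoter_id, unique(map$promoter_id)), map$start)
  if (!identical(ord, seq_len(nrow(map)))) {
    warning("probes were not sorted by start within promoters; sorting")
    map <- map[ord, , drop = FALSE]
    rownames(map) <- NULL
  }
  map
}

#' Run the full analysis pipeline on files
#'
#' Chains the stages -- per-group noise thresholds, expression calls, SLR and
#' mixture classification for each configured contrast, promoter binding
#' calls, and the binding/expression integration -- and writes every result
#' as TSV under `out_dir`, together with a machine-readable JSON manifest of
#' parameters, seeds and input checksums.
#'
#' @param config List with elements: `expression` (path to matrix TSV),
#'   `design` (design TSV), `chip_signals` (signals TSV), `promoter_map`
#'   (map TSV), `contrasts` (list of `(control, heat-shock)` group pairs),
#'   `out_dir`, and optional parameters `k_range_noise`, `k_range_slr`,
#'   `score_min`, `q_max`, `window`, `B`, `seed`.
#' @return The output directory, invisibly; side effect: result TSVs and
#'   `manifest.json` under `out_dir`.
#' @export
run_pipeline <- function(config) {
  need <- c("expression", "design", "chip_signals", "promoter_map",
            "contrasts", "out_dir")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0) {
    stop("pipeline config is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  paths <- unlist(config[c("expression", "design", "chip_signals",
                           "promoter_map")])
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    stop("input path(s) not found: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(
    list(k_range_noise = c(2, 5), k_range_slr = c(1, 4), score_min = 15,
         q_max = 0.05, window = 5, B = 999, seed = 1L),
    config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf(...))

  expr <- read_expression(cfg$expression, cfg$design)
  log_stage("read expression: %d genes, %d samples",
            nrow(expr$matrix), ncol(expr$matrix))

  models <- fit_group_thresholds(expr$matrix, expr$design,
                                 k_range = cfg$k_range_noise,
                                 seed = cfg$seed)
  thr <- vapply(models, function(m) m$threshold, numeric(1))
  utils::write.table(
    data.frame(group = names(thr), K = vapply(models, `[[`, 0L, "K"),
               threshold = thr, row.names = NULL),
    file.path(cfg$out_dir, "noise_thresholds.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  calls <- call_expressed(expr$matrix, expr$design, thr)
  log_stage("noise thresholds fitted for %d groups; %d genes expressed",
            length(thr), sum(calls$expressed_anywhere))

  contrast_tables <- list()
  for (ct in cfg$contrasts) {
    tag <- paste(ct[2], "vs", ct[1], sep = "_")
    tab <- compute_slr(expr$matrix, expr$design, calls, ct)
    cls <- classify_slr(tab, k_range = cfg$k_range_slr, seed = cfg$seed)
    contrast_tables[[tag]] <- cls
    rep_tab <- cls$table
    rep_tab$mean_c <- round_half_away(rep_tab$mean_c)
    rep_tab$mean_hs <- round_half_away(rep_tab$mean_hs)
    rep_tab$slr <- ifelse(is.na(rep_tab$slr), NA,
                          round_half_away(rep_tab$slr))
    utils::write.table(rep_tab, file.path(cfg$out_dir,
                                          paste0("slr_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "-")
    utils::write.table(slr_summary(cls$mixture),
                       file.path(cfg$out_dir,
                                 paste0("slr_summary_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("contrast %s: %d up, %d down of %d evaluated", tag,
              cls$mixture$counts["up"], cls$mixture$counts["down"],
              sum(cls$mixture$counts[c("up", "down", "null")]))
  }

  signals <- read_chip_signals(cfg$chip_signals)
  map <- read_promoter_map(cfg$promoter_map)
  binding <- call_binding(signals, map, score_min = cfg$score_min,
                          q_max = cfg$q_max, window = cfg$window,
                          B = cfg$B, seed = cfg$seed)
  utils::write.table(binding, file.path(cfg$out_dir, "binding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("binding: %d of %d promoters bound", sum(binding$bound),
            nrow(binding))

  bound_genes <- binding$promoter_id[binding$bound]
  integ <- lapply(names(contrast_tables), function(tag) {
    tab <- contrast_tables[[tag]]$table
    xt <- crosstab(bound_genes, tab)
    sp_up <- spearman_binding_expression(tab, binding, "up")
    sp_down <- spearman_binding_expression(tab, binding, "down")
    data.frame(contrast = tag, as.data.frame(xt),
               rho_up = sp_up$rho, p_up = sp_up$p, n_up = sp_up$n,
               rho_down = sp_down$rho, p_down = sp_down$p,
               n_down = sp_down$n)
  })
  utils::write.table(do.call(rbind, integ),
                     file.path(cfg$out_dir, "integration.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("integration written for %d contrast(s)", length(integ))

  manifest <- list(
    package_version = as.character(utils::packageVersion("heatshockr")),
    parameters = cfg[c("k_range_noise", "k_range_slr", "score_min",
                       "q_max", "window", "B", "seed")],
    contrasts = cfg$contrasts,
    inputs = lapply(as.list(paths), function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
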