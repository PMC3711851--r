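#' Hypergeometric upper-tail over-representation probability
#'
#' `P(X >= k)` where `X` counts query genes falling in a term's gene set when
#' `n` genes are drawn without replacement from a universe of `N` genes of
#' which `K_term` carry the term.
#'
#' @param k Observed overlap (query and term).
#' @param n Query size.
#' @param K_term Term gene count in the universe.
#' @param N Universe size.
#' @return The exact upper-tail probability.
#' @export
hypergeom_upper <- function(k, n, K_term, N) {
  if (any(c(k, n, K_term, N) < 0) || n > N || K_term > N ||
      k > min(n, K_term)) {
    stop("impossible hypergeometric counts", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K_term, N - K_term, n, lower.tail = FALSE)
}

# effective gene set of every term: union over the term and its descendants
effective_gene_sets <- function(annotation, order_children_first) {
  eff <- annotation$term_genes
  children <- term_children(annotation)
  for (t in order_children_first) {
    kids <- children[[t]]
    if (length(kids) > 0) {
      eff[[t]] <- unique(c(eff[[t]], unlist(eff[kids], use.names = FALSE)))
    }
  }
  eff
}

term_children <- function(annotation) {
  kids <- lapply(annotation$parents, function(p) character(0))
  for (child in names(annotation$parents)) {
    for (par in annotation$parents[[child]]) {
      kids[[par]] <- c(kids[[par]], child)
    }
  }
  kids
}

# children-before-parents order; errors on a cyclic structure
topo_children_first <- function(annotation) {
  terms <- names(annotation$parents)
  edges <- do.call(rbind, lapply(terms, function(child) {
    pars <- annotation$parents[[child]]
    if (length(pars) == 0) NULL else cbind(child, pars)
  }))
  if (is.null(edges)) return(terms)
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- g + igraph::vertices(setdiff(terms, igraph::V(g)$name))
  if (!igraph::is_dag(g)) {
    stop("term structure is cyclic, not a DAG", call. = FALSE)
  }
  # edges point child -> parent, so a topological sort already puts
  # children before their parents
  igraph::topo_sort(g, mode = "out")$name
}

#' Conditional hypergeometric over-representation test on a term DAG
#'
#' Terms are tested children before parents. When a term is tested, genes
#' belonging to any of its already-significant descendants (conditional
#' p below `child_cutoff`) are removed from the term's effective gene set,
#' from the query, and from the universe copy used for that test, so a parent
#' is only credited with enrichment its significant children do not already
#' explain.
#'
#' @param query Character vector of query genes (must lie in the universe).
#' @param annotation Term annotation: a list with `term_genes` (named list of
#'   direct gene sets), `parents` (named list mapping each term to its parent
#'   ids; empty for roots), `universe` (character vector).
#' @param child_cutoff Conditional-p threshold below which a descendant is
#'   considered to explain its genes (default 0.05).
#' @param bh Also report Benjamini-Hochberg adjusted conditional p values.
#' @return Data frame with one row per term with raw overlap >= 1: `term`,
#'   `k`, `n`, `K_term`, `N`, `p_raw`, `p_conditional`, `significant`, and
#'   `q` when `bh = TRUE`; sorted by `p_conditional`.
#' @export
conditional_enrichment <- function(query, annotation, child_cutoff = 0.05,
                                   bh = FALSE) {
  universe <- unique(annotation$universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe", call. = FALSE)
  }
  ord <- topo_children_first(annotation)
  eff <- effective_gene_sets(annotation, ord)
  desc <- descendants(annotation, ord)

  rows <- list()
  significant <- character(0)
  for (t in ord) {
    genes_t <- eff[[t]]
    k_raw <- length(intersect(query, genes_t))
    # genes explained by already-significant descendants
    sig_desc <- intersect(desc[[t]], significant)
    drop <- if (length(sig_desc) > 0) {
      unique(unlist(eff[sig_desc], use.names = FALSE))
    } else character(0)
    g_cond <- setdiff(genes_t, drop)
    u_cond <- setdiff(universe, drop)
    q_cond <- setdiff(query, drop)
    k <- length(intersect(q_cond, g_cond))
    p_raw <- hypergeom_upper(k_raw, length(query), length(genes_t),
                             length(universe))
    p_cond <- hypergeom_upper(k, length(q_cond), length(g_cond),
                              length(u_cond))
    if (p_cond < child_cutoff) significant <- c(significant, t)
    if (k_raw >= 1) {
      rows[[t]] <- data.frame(
        term = t, k = k, n = length(q_cond), K_term = length(g_cond),
        N = length(u_cond), p_raw = p_raw, p_conditional = p_cond,
        significant = p_cond < child_cutoff, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K_term = integer(0), N = integer(0),
                      p_raw = numeric(0), p_conditional = numeric(0),
                      significant = logical(0))
  }
  out <- out[order(out$p_conditional, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (bh) out$q <- stats::p.adjust(out$p_conditional, method = "BH")
  out
}

# all descendants of each term, computed bottom-up
descendants <- function(annotation, order_children_first) {
  children <- term_children(annotation)
  desc <- lapply(annotation$parents, function(p) character(0))
  for (t in order_children_first) {
    kids <- children[[t]]
    if (length(kids) > 0) {
      desc[[t]] <- unique(c(kids, unlist(desc[kids], use.names = FALSE)))
    }
  }
  desc
}
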