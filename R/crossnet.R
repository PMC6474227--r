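#' Correlation p-value from the t transform
#' @noRd
.cor_pvalue <- function(r, n) {
  r <- pmin(pmax(r, -1), 1)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
  p[abs(r) >= 1 - 1e-15] <- 0
  p
}

#' Correlate eigengene sets across organisms
#'
#' Scores every host-module x symbiont-module pair by the Pearson
#' correlation of their eigengenes over a shared sample subset (by default
#' the caller passes the inoculated samples, where fungal expression
#' exists). Two-sided p-values come from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n - 2 df; an edge is
#' significant when the raw p-value falls below `edge_alpha`.
#' BH-adjusted p-values are reported alongside.
#'
#' @param ME_host,ME_symbiont module x sample eigengene matrices.
#' @param sample_subset sample ids to use (default: all shared samples).
#' @param edge_alpha raw-p significance threshold (default 0.001).
#' @return data.frame: `module_host`, `module_symbiont`, `r`, `p`, `q`,
#'   `n`, `significant`.
#' @export
correlate_module_sets <- function(ME_host, ME_symbiont, sample_subset = NULL,
                                  edge_alpha = 0.001) {
  shared <- intersect(colnames(ME_host), colnames(ME_symbiont))
  if (!is.null(sample_subset)) shared <- intersect(shared, sample_subset)
  if (length(shared) < 4)
    stop("need at least 4 shared samples", call. = FALSE)
  H <- ME_host[, shared, drop = FALSE]
  S <- ME_symbiont[, shared, drop = FALSE]
  r <- stats::cor(t(H), t(S))
  n <- length(shared)
  tab <- expand.grid(module_host = rownames(H),
                     module_symbiont = rownames(S),
                     stringsAsFactors = FALSE)
  tab$r <- r[cbind(tab$module_host, tab$module_symbiont)]
  tab$p <- .cor_pvalue(tab$r, n)
  tab$q <- stats::p.adjust(tab$p, "BH")
  tab$n <- n
  tab$significant <- tab$p < edge_alpha
  tab
}

#' Build the bipartite cross-kingdom module network
#'
#' Nodes are modules of both organisms; edges are the significant
#' module-module correlations, weighted by r. Modules without any
#' significant edge are kept as flagged isolated nodes.
#'
#' @param edges edge table from [correlate_module_sets()].
#' @return an [igraph::graph] with vertex attributes `organism` and
#'   `isolated`, and edge attributes `weight` (r) and `p`.
#' @export
build_bipartite_network <- function(edges) {
  hosts <- unique(edges$module_host)
  syms <- unique(edges$module_symbiont)
  nodes <- data.frame(
    name = c(paste0("host:", hosts), paste0("symbiont:", syms)),
    organism = c(rep("host", length(hosts)), rep("symbiont", length(syms))),
    stringsAsFactors = FALSE)
  sig <- edges[edges$significant, , drop = FALSE]
  el <- if (nrow(sig) == 0) {
    data.frame(from = character(0), to = character(0),
               weight = numeric(0), p = numeric(0))
  } else {
    data.frame(from = paste0("host:", sig$module_host),
               to = paste0("symbiont:", sig$module_symbiont),
               weight = sig$r, p = sig$p, stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  igraph::V(g)$isolated <- igraph::degree(g) == 0
  igraph::V(g)$type <- igraph::V(g)$organism == "symbiont"
  g
}

#' Gene significance toward a partner-module eigengene (or trait)
#'
#' Pearson correlation of every gene with a single reference profile —
#' either a partner-organism module eigengene or a quantitative trait —
#' over a sample subset, using pairwise-complete observations.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param reference named numeric vector (eigengene or trait values by
#'   sample id) or a 1 x samples matrix.
#' @param sample_subset sample ids to use (default: all shared).
#' @return named numeric vector of correlations; zero-variance genes give
#'   NA.
#' @export
gene_significance <- function(expr, reference, sample_subset = NULL) {
  if (is.matrix(reference)) reference <- stats::setNames(reference[1, ], colnames(reference))
  shared <- intersect(colnames(expr), names(reference))
  if (!is.null(sample_subset)) shared <- intersect(shared, sample_subset)
  shared <- shared[!is.na(reference[shared])]
  if (length(shared) < 4)
    stop("need at least 4 shared samples", call. = FALSE)
  gs <- suppressWarnings(
    stats::cor(t(expr[, shared, drop = FALSE]), reference[shared],
               use = "pairwise.complete.obs"))[, 1]
  stats::setNames(gs, rownames(expr))
}

#' Key-gene selection rule
#'
#' Within one module, a gene is a key gene when its |GS| reaches the
#' module's `quantile` (default 0.90) quantile of |GS| (linear-interpolation
#' estimator; ties at the boundary included) AND its module membership
#' exceeds `kme_min` (default 0.8).
#'
#' @param gs named numeric: gene significance of the module's members.
#' @param kme named numeric: membership of the same genes in their own
#'   module.
#' @param quantile quantile of |GS| a key gene must reach.
#' @param kme_min strict lower bound on kME.
#' @return logical vector, named by gene.
#' @export
select_key_genes <- function(gs, kme, quantile = 0.90, kme_min = 0.8) {
  stopifnot(identical(names(gs), names(kme)))
  ok <- !is.na(gs) & !is.na(kme)
  out <- stats::setNames(rep(FALSE, length(gs)), names(gs))
  if (!any(ok)) return(out)
  qthr <- stats::quantile(abs(gs[ok]), probs = quantile, names = FALSE)
  out[ok] <- abs(gs[ok]) >= qthr & kme[ok] > kme_min
  out
}

#' Extract key genes of the cross-kingdom network
#'
#' For every significantly correlated (host module, symbiont module) pair,
#' computes each organism's gene significance toward the partner eigengene
#' over the shared sample subset, and selects, within each module, the
#' genes in the top `quantile` of |GS| that also have kME above `kme_min`
#' in their own module.
#'
#' @param expr_host,expr_symbiont log2-CPM matrices.
#' @param partition_host,partition_symbiont `module_partition` objects.
#' @param edges edge table from [correlate_module_sets()].
#' @param quantile,kme_min key-gene thresholds (defaults 0.90 and 0.8).
#' @param sample_subset sample ids for the GS correlations.
#' @return data.frame: `gene_id`, `organism`, `module`, `partner_module`,
#'   `GS`, `kME`, `passes`.
#' @export
key_genes <- function(expr_host, expr_symbiont,
                      partition_host, partition_symbiont, edges,
                      quantile = 0.90, kme_min = 0.8,
                      sample_subset = NULL) {
  sig <- edges[edges$significant, , drop = FALSE]
  res <- list()
  one_side <- function(expr, part, own_mod, partner_me, organism, partner_name) {
    members <- names(part$labels)[part$labels == as.integer(sub("^ME", "", own_mod))]
    if (length(members) < 2) {
      warning("module ", own_mod, " has < 2 members; skipped", call. = FALSE)
      return(NULL)
    }
    gs <- gene_significance(expr[members, , drop = FALSE], partner_me,
                            sample_subset)
    kme <- part$kME[members, own_mod]
    passes <- select_key_genes(gs, stats::setNames(kme, members),
                               quantile, kme_min)
    data.frame(gene_id = members, organism = organism, module = own_mod,
               partner_module = partner_name, GS = unname(gs),
               kME = unname(kme), passes = unname(passes),
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(sig))) {
    mh <- sig$module_host[i]; ms <- sig$module_symbiont[i]
    res[[length(res) + 1]] <- one_side(
      expr_host, partition_host, mh,
      stats::setNames(partition_symbiont$ME[ms, ],
                      colnames(partition_symbiont$ME)),
      "host", ms)
    res[[length(res) + 1]] <- one_side(
      expr_symbiont, partition_symbiont, ms,
      stats::setNames(partition_host$ME[mh, ], colnames(partition_host$ME)),
      "symbiont", mh)
  }
  if (!length(res))
    return(data.frame(gene_id = character(0), organism = character(0),
                      module = character(0), partner_module = character(0),
                      GS = numeric(0), kME = numeric(0),
                      passes = logical(0)))
  do.call(rbind, res)
}

#' Random-relabelling permutation null for the cross network
#'
#' Repeatedly reassigns genes to modules uniformly at random while
#' preserving every module's size (including the unassigned pool),
#' recomputes both organisms' eigengenes, and counts significant
#' cross-kingdom edges at `edge_alpha`. The empirical p-value of the
#' observed network is `(1 + #{null >= observed}) / (n_perm + 1)`.
#'
#' @param expr_host,expr_symbiont log2-CPM matrices.
#' @param labels_host,labels_symbiont module label vectors (0 = unassigned).
#' @param n_perm number of permutations (>= 1).
#' @param edge_alpha raw-p edge threshold (default 0.001).
#' @param sample_subset sample ids for the cross correlations.
#' @param seed integer seed for the permutation stream.
#' @return list: `observed` (edge count), `null_counts` (length `n_perm`),
#'   `p_value`.
#' @export
permutation_null <- function(expr_host, expr_symbiont,
                             labels_host, labels_symbiont,
                             n_perm = 100, edge_alpha = 0.001,
                             sample_subset = NULL, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  count_edges <- function(lh, ls) {
    meh <- module_eigengenes(expr_host, lh)$ME
    mes <- module_eigengenes(expr_symbiont, ls)$ME
    sum(correlate_module_sets(meh, mes, sample_subset, edge_alpha)$significant)
  }
  observed <- count_edges(labels_host, labels_symbiont)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(b) {
    lh <- stats::setNames(sample(labels_host), names(labels_host))
    ls <- stats::setNames(sample(labels_symbiont), names(labels_symbiont))
    count_edges(lh, ls)
  }, numeric(1))
  list(observed = observed, null_counts = null_counts,
       p_value = (1 + sum(null_counts >= observed)) / (n_perm + 1))
}
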