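#' Soft-thresholded co-expression adjacency
#'
#' Pearson-correlation adjacency raised to a soft power: unsigned
#' `|cor|^power` or signed `((1 + cor) / 2)^power`. Zero-variance genes are
#' dropped with a warning before correlation.
#'
#' @param expr log2-CPM matrix (genes x samples), >= 3 samples.
#' @param power soft-thresholding power (default 12).
#' @param mode `"unsigned"` (default) or `"signed"`.
#' @return symmetric gene x gene matrix in \[0,1\] with unit diagonal;
#'   attributes `power` and `mode`.
#' @export
adjacency <- function(expr, power = 12, mode = c("unsigned", "signed")) {
  mode <- match.arg(mode)
  if (ncol(expr) < 3)
    stop("adjacency needs at least 3 samples", call. = FALSE)
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance gene(s)", call. = FALSE)
    expr <- expr[v > 0, , drop = FALSE]
  }
  r <- stats::cor(t(expr))
  if (anyNA(r))
    stop("NaN correlations for gene(s): ",
         paste(rownames(r)[apply(is.na(r), 1, any)], collapse = ", "),
         call. = FALSE)
  a <- if (mode == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  structure(a, power = power, mode = mode)
}

#' Topological overlap matrix
#'
#' Smooths an adjacency by shared-neighbour structure: for i != j,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over u distinct from i and j and `k_i` the
#' connectivity of node i; the diagonal is 1. `1 - TOM` is the clustering
#' dissimilarity.
#'
#' @param adj adjacency matrix from [adjacency()].
#' @return TOM matrix, same dimensions and dimnames.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(adj), tol = 1e-8))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- unclass(adj)
  diag(a) <- 0
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Average-linkage gene clustering
#'
#' Agglomerative average-linkage (UPGMA) clustering of a symmetric
#' dissimilarity matrix, typically `1 - TOM`.
#'
#' @param dissim square symmetric matrix with zero diagonal.
#' @return an [stats::hclust] tree.
#' @export
cluster_genes <- function(dissim) {
  if (!isSymmetric(unname(dissim), tol = 1e-8))
    stop("dissimilarity must be symmetric", call. = FALSE)
  if (any(abs(diag(dissim)) > 1e-12))
    stop("dissimilarity must have a zero diagonal", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  # dynamic_cut scores branches on the dissimilarity itself, so carry it
  hc$dissim <- dissim
  hc$dissim_max <- max(dissim)
  hc
}

#' Dynamic branch cut of a dendrogram
#'
#' Identifies modules as dendrogram branches whose internal similarity
#' stands far above the network background. Every branch (internal node)
#' of at least `min_size` leaves is scored by the ratio
#' `q = median within-branch similarity / median off-diagonal
#' similarity`, where similarity is `1 - dissimilarity` (for a
#' topological-overlap dissimilarity, the TOM itself) and the global
#' median off-diagonal similarity estimates the background level of
#' unrelated gene pairs; medians on both sides keep the score immune to
#' the heavy upper tail that soft thresholding gives chance
#' correlations. A branch
#' qualifies when `q > 2 / gap_frac` (8 at the default `gap_frac =
#' 0.25`). Qualifying branches are resolved bottom-up: an enclosing
#' branch replaces the qualifying branches nested inside it when its own
#' quality retains at least a fraction `1 - gap_frac` of the best nested
#' quality — so a module keeps its peripheral members, while a loose
#' super-branch that dilutes a tight module does not swallow it. Genes
#' in no selected branch are unassigned (label 0); selected modules are
#' renumbered 1..K by decreasing size.
#'
#' Scoring branches against the global background rather than against
#' their parent merge heights is what makes the cut stable on
#' soft-thresholded trees, where all between-module merges compress into
#' a thin shelf of heights just under the maximum and height gaps carry
#' little signal.
#'
#' @param dendro an [stats::hclust] tree from [cluster_genes()] (which
#'   carries the dissimilarity matrix), or any hclust tree if `dissim`
#'   is supplied.
#' @param min_size minimum module size (default 50).
#' @param gap_frac stringency in (0, 1); smaller values demand branches
#'   that stand out more strongly from the background (default 0.25).
#' @param dissim optional dissimilarity matrix matching the tree's
#'   leaves; defaults to the matrix stored by [cluster_genes()].
#' @return integer vector of module labels, named by gene (leaf label).
#' @export
dynamic_cut <- function(dendro, min_size = 50, gap_frac = 0.25,
                        dissim = NULL) {
  n <- length(dendro$order)
  labs <- if (is.null(dendro$labels)) as.character(seq_len(n)) else dendro$labels
  if (min_size > n) {
    warning("min_size exceeds the number of genes; all genes unassigned",
            call. = FALSE)
    return(stats::setNames(integer(n), labs))
  }
  if (is.null(dissim)) dissim <- dendro$dissim
  if (is.null(dissim))
    stop("a dissimilarity matrix is required (cluster the genes with ",
         "cluster_genes(), or pass dissim=)", call. = FALSE)
  S <- 1 - unclass(dissim)
  diag(S) <- 0
  floor_s <- stats::median(S[upper.tri(S)])
  q_min <- 2 / gap_frac
  dominance <- 1 - gap_frac
  m <- dendro$merge
  leafsets <- vector("list", n - 1)
  qual <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    lv <- integer(0)
    for (ch in m[i, ]) lv <- c(lv, if (ch < 0) -ch else leafsets[[ch]])
    leafsets[[i]] <- lv
    k <- length(lv)
    if (k >= min_size) {
      sub <- S[lv, lv]
      within <- stats::median(sub[upper.tri(sub)])
      qual[i] <- if (floor_s <= 0) {
        if (within > 0) Inf else 0
      } else within / floor_s
    }
  }
  # bottom-up resolution: children rows always precede their parent row
  sel <- vector("list", n - 1)              # selected nodes in subtree
  bestq <- rep(-Inf, n - 1)                 # best selected quality below
  for (i in seq_len(n - 1)) {
    ch <- m[i, ][m[i, ] > 0]
    sub_sel <- unlist(lapply(ch, function(x) sel[[x]]))
    sub_q <- if (length(ch)) max(bestq[ch]) else -Inf
    if (length(leafsets[[i]]) >= min_size && qual[i] > q_min &&
        qual[i] >= dominance * sub_q) {
      sel[[i]] <- i
      bestq[i] <- max(qual[i], sub_q)
    } else {
      sel[i] <- list(sub_sel)               # list() keeps NULLs from deleting
      bestq[i] <- sub_q
    }
  }
  chosen <- sel[[n - 1]]
  labels <- integer(n)
  if (length(chosen)) {
    sizes <- vapply(chosen, function(i) length(leafsets[[i]]), integer(1))
    chosen <- chosen[order(-sizes, chosen)]
    for (i in seq_along(chosen))
      labels[leafsets[[chosen[i]]]] <- i
  }
  stats::setNames(labels, labs)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardized expression submatrix, scaled to unit variance across
#' samples and sign-anchored so that the mean correlation with the module's
#' member genes is positive. Reported alongside is the proportion of
#' within-module variance the eigengene explains.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param labels integer module labels named by gene (0 = unassigned).
#' @return list: `ME` (module x sample matrix, rows `ME1`, `ME2`, ...) and
#'   `var_explained` (named numeric).
#' @export
module_eigengenes <- function(expr, labels) {
  labels <- labels[rownames(expr)]
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) stop("no modules to summarise", call. = FALSE)
  n <- ncol(expr)
  ME <- matrix(NA_real_, length(mods), n,
               dimnames = list(paste0("ME", mods), colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    X <- expr[labels == mods[i], , drop = FALSE]
    Z <- t(scale(t(X)))                        # standardize each gene
    if (nrow(Z) == 1) {
      me <- Z[1, ]
      ve[i] <- 1
    } else {
      S <- crossprod(Z)                        # sample x sample
      eg <- eigen(S, symmetric = TRUE)
      me <- eg$vectors[, 1]
      ve[i] <- eg$values[1] / sum(pmax(eg$values, 0))
    }
    me <- me / stats::sd(me)                   # unit variance over samples
    if (mean(stats::cor(me, t(X))) < 0) me <- -me
    ME[i, ] <- me
  }
  list(ME = ME, var_explained = ve)
}

#' Gene module membership (kME)
#'
#' Pearson correlation of every gene's expression profile with every
#' module eigengene.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param ME module x sample eigengene matrix.
#' @return gene x module matrix of correlations; zero-variance genes yield
#'   NA rows with a warning.
#' @export
module_membership <- function(expr, ME) {
  v <- apply(expr, 1, stats::var)
  kme <- suppressWarnings(stats::cor(t(expr), t(ME)))
  if (any(v == 0))
    warning("zero-variance gene(s) have undefined membership: ",
            paste(rownames(expr)[v == 0], collapse = ", "), call. = FALSE)
  kme
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters module eigengenes by the dissimilarity
#' `1 - cor(ME_a, ME_b)` with average linkage, merges every group of
#' modules whose eigengenes cluster below `merge_cut`, recomputes
#' eigengenes, and repeats until no pair falls below the cut. Unassigned
#' genes (label 0) never merge.
#'
#' @param expr log2-CPM matrix.
#' @param labels module labels (0 = unassigned).
#' @param merge_cut eigengene-dissimilarity threshold (default 0.1).
#' @param min_size recorded minimum module size (modules only grow here).
#' @return a `module_partition`: list with `labels` (renumbered by
#'   decreasing size), `ME`, `var_explained`, `kME`, `min_size`,
#'   `merge_cut`.
#' @export
merge_modules <- function(expr, labels, merge_cut = 0.1, min_size = 50L) {
  labels <- labels[rownames(expr)]
  repeat {
    mods <- sort(unique(labels[labels > 0]))
    if (length(mods) < 2) break
    eg <- module_eigengenes(expr, labels)
    d <- 1 - stats::cor(t(eg$ME))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    cl <- stats::cutree(hc, h = merge_cut)
    if (max(cl) == length(mods)) break
    remap <- stats::setNames(cl, mods)
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  # renumber by decreasing size
  mods <- sort(unique(labels[labels > 0]))
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
    remap <- stats::setNames(seq_along(mods), mods[order(-sizes, mods)])
    labels[labels > 0] <- remap[as.character(labels[labels > 0])]
  }
  eg <- if (length(mods)) module_eigengenes(expr, labels) else
    list(ME = matrix(NA_real_, 0, ncol(expr),
                     dimnames = list(NULL, colnames(expr))),
         var_explained = numeric(0))
  kme <- if (length(mods)) module_membership(expr, eg$ME) else NULL
  structure(list(labels = labels, ME = eg$ME,
                 var_explained = eg$var_explained, kME = kme,
                 min_size = min_size, merge_cut = merge_cut),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf("module_partition: %d modules over %d genes (%d unassigned)\n",
              k, length(x$labels), sum(x$labels == 0)))
  invisible(x)
}

#' Build co-expression modules end to end
#'
#' Runs adjacency, topological overlap, average-linkage clustering, dynamic
#' branch cutting and eigengene-based merging in sequence — the standard
#' step-by-step weighted co-expression network construction.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param power soft-thresholding power (default 12).
#' @param min_size minimum module size (default 50).
#' @param merge_cut eigengene merge threshold (default 0.1).
#' @param mode adjacency mode (default `"unsigned"`).
#' @param gap_frac dynamic-cut gap fraction (default 0.25).
#' @return a `module_partition` (see [merge_modules()]).
#' @export
build_modules <- function(expr, power = 12, min_size = 50, merge_cut = 0.1,
                          mode = "unsigned", gap_frac = 0.25) {
  adj <- adjacency(expr, power = power, mode = mode)
  expr <- expr[rownames(adj), , drop = FALSE]    # zero-variance genes dropped
  tom <- topological_overlap(adj)
  dendro <- cluster_genes(1 - tom)
  labels <- dynamic_cut(dendro, min_size = min_size, gap_frac = gap_frac)
  if (!any(labels > 0)) {
    warning("no modules found; all genes unassigned", call. = FALSE)
    return(structure(list(labels = labels,
                          ME = matrix(NA_real_, 0, ncol(expr),
                                      dimnames = list(NULL, colnames(expr))),
                          var_explained = numeric(0), kME = NULL,
                          min_size = min_size, merge_cut = merge_cut),
                     class = "module_partition"))
  }
  merge_modules(expr, labels, merge_cut = merge_cut, min_size = min_size)
}
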