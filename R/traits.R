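#' Correlate module eigengenes with quantitative traits
#'
#' Pairwise-complete Pearson correlation of every module eigengene with
#' every trait over a sample subset, with two-sided t-based p-values and
#' BH-adjusted q-values. Host-module correlations typically use all
#' samples; symbiont-module correlations the inoculated samples only.
#'
#' @param ME module x sample eigengene matrix.
#' @param traits data.frame with `sample_id` plus one numeric column per
#'   trait, or a sample x trait matrix with sample-id rownames.
#' @param sample_subset sample ids to use (default: all shared).
#' @return data.frame: `module`, `trait`, `r`, `p`, `q`, `n`.
#' @export
correlate_modules_traits <- function(ME, traits, sample_subset = NULL) {
  tm <- .trait_matrix(traits)
  shared <- intersect(colnames(ME), rownames(tm))
  if (!is.null(sample_subset)) shared <- intersect(shared, sample_subset)
  if (length(shared) < 4)
    stop("need at least 4 shared samples", call. = FALSE)
  tm <- tm[shared, , drop = FALSE]
  E <- t(ME[, shared, drop = FALSE])
  out <- expand.grid(module = rownames(ME), trait = colnames(tm),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    x <- E[, out$module[i]]
    y <- tm[, out$trait[i]]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    out$n[i] <- n
    if (n < 4) next
    if (stats::sd(y[ok]) == 0) {
      warning("trait ", out$trait[i], " is constant over the subset",
              call. = FALSE)
      next
    }
    r <- stats::cor(x[ok], y[ok])
    out$r[i] <- r
    out$p[i] <- .cor_pvalue(r, n)
  }
  out$q <- stats::p.adjust(out$p, "BH")
  out[, c("module", "trait", "r", "p", "q", "n")]
}

#' @noRd
.trait_matrix <- function(traits) {
  if (is.data.frame(traits) && "sample_id" %in% names(traits)) {
    tm <- as.matrix(traits[, setdiff(names(traits), "sample_id"),
                           drop = FALSE])
    rownames(tm) <- traits$sample_id
    tm
  } else {
    as.matrix(traits)
  }
}

#' Key genes for a quantitative trait
#'
#' Applies the cross-network key-gene rule with the trait playing the role
#' of the partner eigengene: within every module whose eigengene is
#' significantly correlated with the trait, genes in the top `quantile` of
#' |gene-trait correlation| with own-module kME above `kme_min` are key
#' genes. Gene significance is computed through the same code path as for
#' partner modules ([gene_significance()]).
#'
#' @param expr log2-CPM matrix.
#' @param partition a `module_partition`.
#' @param traits trait table (see [correlate_modules_traits()]).
#' @param trait name of the trait column to analyse.
#' @param alpha module-trait correlation significance threshold (default
#'   0.001, matching the cross-network edge threshold).
#' @param quantile,kme_min key-gene thresholds (defaults 0.90 and 0.8).
#' @param sample_subset sample ids to use.
#' @return data.frame in the [key_genes()] layout, `partner_module` set to
#'   the trait name.
#' @export
key_genes_for_trait <- function(expr, partition, traits, trait,
                                alpha = 0.001, quantile = 0.90,
                                kme_min = 0.8, sample_subset = NULL) {
  tm <- .trait_matrix(traits)
  if (!trait %in% colnames(tm))
    stop("unknown trait: ", trait, call. = FALSE)
  mt <- correlate_modules_traits(partition$ME, traits, sample_subset)
  mt <- mt[mt$trait == trait & !is.na(mt$p) & mt$p < alpha, , drop = FALSE]
  tvec <- stats::setNames(tm[, trait], rownames(tm))
  res <- list()
  for (m in mt$module) {
    members <- names(partition$labels)[
      partition$labels == as.integer(sub("^ME", "", m))]
    if (length(members) < 2) {
      warning("module ", m, " has < 2 members; skipped", call. = FALSE)
      next
    }
    gs <- gene_significance(expr[members, , drop = FALSE], tvec,
                            sample_subset)
    kme <- stats::setNames(partition$kME[members, m], members)
    passes <- select_key_genes(gs, kme, quantile, kme_min)
    res[[length(res) + 1]] <- data.frame(
      gene_id = members, organism = attr(expr, "organism") %||% NA_character_,
      module = m, partner_module = trait, GS = unname(gs),
      kME = unname(kme), passes = unname(passes), stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(gene_id = character(0), organism = character(0),
                      module = character(0), partner_module = character(0),
                      GS = numeric(0), kME = numeric(0),
                      passes = logical(0)))
  do.call(rbind, res)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
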