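#' Count matrix container
#'
#' Light container for a non-negative integer gene x sample count matrix
#' with an organism tag and per-sample library sizes.
#'
#' @param counts integer matrix, genes as rows (rownames = gene ids),
#'   samples as columns (colnames = sample ids).
#' @param organism character tag, e.g. `"host"` or `"symbiont"`.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, organism = "host") {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicated gene id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "), call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (is.double(counts) && max(counts) < .Machine$integer.max)
    storage.mode(counts) <- "integer"
  structure(list(counts = counts, organism = organism,
                 lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d genes x %d samples, median library %s\n",
              x$organism, nrow(x$counts), ncol(x$counts),
              format(stats::median(x$lib_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @noRd
.as_counts <- function(x) {
  if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
}

#' log2 counts-per-million normalisation
#'
#' Computes `log2((count + prior) / (library_size + 2 * prior) * 1e6)`,
#' the prior keeping zero counts finite. Library sizes are the column sums
#' of the full (unfiltered) matrix when a `count_matrix` is supplied.
#'
#' @param counts a [count_matrix()] or plain matrix.
#' @param prior prior count added to each observation (default 0.5).
#' @param lib_sizes optional per-sample library sizes; defaults to the
#'   stored or computed column sums.
#' @return numeric matrix of log2-CPM values, same dimnames as the input,
#'   with the organism tag (if any) kept in `attr(, "organism")`.
#' @export
log2_cpm <- function(counts, prior = 0.5, lib_sizes = NULL) {
  m <- .as_counts(counts)
  if (is.null(lib_sizes))
    lib_sizes <- if (inherits(counts, "count_matrix")) counts$lib_sizes
      else colSums(m)
  if (any(lib_sizes == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib_sizes == 0], collapse = ", "), call. = FALSE)
  out <- log2(sweep(m + prior, 2, lib_sizes + 2 * prior, "/") * 1e6)
  dimnames(out) <- dimnames(m)
  if (inherits(counts, "count_matrix"))
    attr(out, "organism") <- counts$organism
  out
}

#' Filter genes on minimum expression
#'
#' Keeps genes with CPM >= `min_cpm` in at least `min_samples` samples.
#' Samples named in `exclude_samples` (typically the mock-inoculated
#' samples when filtering the symbiont matrix, where the fungus is absent)
#' are dropped from the matrix entirely: they take part neither in the
#' filter nor in any downstream analysis of that organism.
#'
#' @param counts a [count_matrix()].
#' @param min_cpm,min_samples filter thresholds (>= 0).
#' @param exclude_samples character vector of sample ids to drop.
#' @return filtered [count_matrix()] (library sizes recomputed on the
#'   retained samples, reflecting sequencing depth of the kept columns).
#' @export
filter_genes <- function(counts, min_cpm = 1, min_samples = 3,
                         exclude_samples = NULL) {
  stopifnot(inherits(counts, "count_matrix"), min_cpm >= 0, min_samples >= 0)
  m <- counts$counts
  if (!is.null(exclude_samples))
    m <- m[, !colnames(m) %in% exclude_samples, drop = FALSE]
  lib <- colSums(m)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(m)[lib == 0], collapse = ", "), call. = FALSE)
  cpm <- sweep(m, 2, lib, "/") * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  if (!any(keep))
    warning("all genes removed by the expression filter", call. = FALSE)
  count_matrix(m[keep, , drop = FALSE], organism = counts$organism)
}

#' Classify per-gene transcriptional responses
#'
#' Fits, for every gene, a two-factor linear model of log2-CPM on cultivar,
#' fungal treatment and their interaction, F-tests each term, adjusts
#' p-values per term with Benjamini-Hochberg across genes, and assigns each
#' gene one response class with the priority: significant interaction ->
#' `interaction` (genotype x genotype response); else significant treatment
#' -> `mycorrhiza_conserved` or `isolate_conserved`, decided by which
#' single-df contrast (mock vs pooled AMF; isolateA vs isolateB) carries the
#' smaller p-value; else significant cultivar -> `cultivar_only`; else
#' `none`. When the design holds no mock samples (symbiont analysis) a
#' significant treatment term always yields `isolate_conserved`.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param design sample design data.frame; only rows matching `colnames(expr)`
#'   are used, in expression-matrix order.
#' @param alpha per-term BH-FDR level (default 0.05).
#' @return data.frame (one row per gene): p and BH q per term, the two
#'   treatment contrast p-values and log2 fold changes, and `class`.
#' @export
classify_responses <- function(expr, design, alpha = 0.05) {
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id))
    stop("expression samples missing from the design", call. = FALSE)
  cu <- droplevels(factor(design$cultivar))
  tr <- droplevels(factor(design$fungal_treatment))
  if (nlevels(cu) < 2 || nlevels(tr) < 2)
    stop("classification needs >= 2 cultivars and >= 2 fungal levels",
         call. = FALSE)
  tab <- table(cu, tr)
  if (any(tab < 2))
    warning("factor cell(s) with < 2 samples; tests proceed with reduced df",
            call. = FALSE)
  n <- ncol(expr)
  Y <- t(expr)                                   # samples x genes
  rss <- function(X) {
    qr_ <- qr(X)
    if (qr_$rank < ncol(X)) stop("singular design", call. = FALSE)
    colSums(qr.resid(qr_, Y)^2)
  }
  X0 <- matrix(1, n, 1)
  X1 <- stats::model.matrix(~cu)
  X2 <- stats::model.matrix(~cu + tr)
  X3 <- stats::model.matrix(~cu * tr)
  rss0 <- rss(X0); rss1 <- rss(X1); rss2 <- rss(X2); rss3 <- rss(X3)
  df_cu <- nlevels(cu) - 1
  df_tr <- nlevels(tr) - 1
  df_int <- df_cu * df_tr
  df_res <- n - ncol(X3)
  if (df_res < 1) stop("no residual degrees of freedom", call. = FALSE)
  mse <- rss3 / df_res
  eps <- 1e-12
  fp <- function(ss, df) {
    p <- stats::pf((ss / df) / mse, df, df_res, lower.tail = FALSE)
    # zero-residual (noise-free) genes: effect present -> 0, absent -> 1
    p[mse < eps] <- ifelse(ss[mse < eps] / df > eps, 0, 1)
    p
  }
  p_cu <- fp(rss0 - rss1, df_cu)
  p_tr <- fp(rss1 - rss2, df_tr)
  p_int <- fp(rss2 - rss3, df_int)
  q_cu <- stats::p.adjust(p_cu, "BH")
  q_tr <- stats::p.adjust(p_tr, "BH")
  q_int <- stats::p.adjust(p_int, "BH")

  # single-df treatment contrasts on cell means (equal cultivar weights)
  cell <- interaction(cu, tr, drop = FALSE)
  cm_n <- as.vector(table(cell))
  cell_means <- apply(Y, 2, function(y) tapply(y, cell, mean))
  cell_means[is.na(cell_means)] <- 0          # empty cells carry zero weight
  contrast_p <- function(w) {
    if (all(w == 0)) return(list(p = rep(NA_real_, ncol(Y)), est = rep(NA_real_, ncol(Y))))
    est <- as.vector(t(w) %*% cell_means)
    se <- sqrt(mse * sum(w[w != 0]^2 / cm_n[w != 0]))
    p <- 2 * stats::pt(abs(est / se), df_res, lower.tail = FALSE)
    p[se < eps] <- ifelse(abs(est[se < eps]) > eps, 0, 1)
    list(p = p, est = est)
  }
  lv_tr <- levels(tr); lv_cu <- levels(cu)
  cell_tr <- rep(lv_tr, each = nlevels(cu))
  has_mock <- "mock" %in% lv_tr
  amf_lv <- lv_tr[lv_tr != "mock"]
  w_mock <- numeric(length(cell_tr))
  if (has_mock && length(amf_lv) >= 1) {
    w_mock[cell_tr %in% amf_lv] <- 1 / (nlevels(cu) * length(amf_lv))
    w_mock[cell_tr == "mock"] <- -1 / nlevels(cu)
  }
  w_iso <- numeric(length(cell_tr))
  if (length(amf_lv) >= 2) {
    w_iso[cell_tr == amf_lv[1]] <- 1 / nlevels(cu)
    w_iso[cell_tr == amf_lv[2]] <- -1 / nlevels(cu)
  }
  c_mock <- contrast_p(w_mock)
  c_iso <- contrast_p(w_iso)

  cls <- rep("none", ncol(Y))
  sig_tr <- q_tr < alpha
  cls[q_cu < alpha] <- "cultivar_only"
  mock_dominant <- if (has_mock)
    !is.na(c_mock$p) & (is.na(c_iso$p) | c_mock$p <= c_iso$p)
  else rep(FALSE, ncol(Y))
  cls[sig_tr & mock_dominant] <- "mycorrhiza_conserved"
  cls[sig_tr & !mock_dominant] <- "isolate_conserved"
  cls[q_int < alpha] <- "interaction"

  data.frame(gene_id = colnames(Y),
             p_cultivar = p_cu, q_cultivar = q_cu,
             p_treatment = p_tr, q_treatment = q_tr,
             p_interaction = p_int, q_interaction = q_int,
             p_mock_vs_amf = c_mock$p, lfc_mock_vs_amf = c_mock$est,
             p_isolates = c_iso$p, lfc_isolates = c_iso$est,
             class = cls, row.names = NULL, stringsAsFactors = FALSE)
}

#' Select genes by per-cultivar fold change
#'
#' Computes the log2 fold change (difference of mean log2-CPM) between two
#' sample groups, overall and separately within each cultivar, and returns
#' the genes whose largest per-cultivar |log2FC| exceeds the threshold —
#' the selection behind the isolate-contrast heatmaps, where a gene
#' responding +3 in one cultivar and -3 in another qualifies even though
#' its overall fold change cancels. Optionally intersects with a response
#' class from [classify_responses()].
#'
#' @param expr log2-CPM matrix.
#' @param design sample design.
#' @param groupA,groupB character vectors of sample ids (non-empty).
#' @param min_abs_log2fc threshold on |log2FC| (host default 2; use 4 for
#'   the symbiont, matching the stricter fungal gene-set cut).
#' @param classification optional data.frame from [classify_responses()].
#' @param classes response classes to intersect with (default
#'   `"interaction"`) when `classification` is given.
#' @return list: `genes` (character), `fold_changes` (gene x cultivar
#'   matrix, plus an `overall` column), `selected` logical vector.
#' @export
select_by_fold_change <- function(expr, design, groupA, groupB,
                                  min_abs_log2fc = 2,
                                  classification = NULL,
                                  classes = "interaction") {
  if (!length(groupA) || !length(groupB))
    stop("both sample groups must be non-empty", call. = FALSE)
  if (!all(c(groupA, groupB) %in% colnames(expr)))
    stop("group sample(s) missing from the expression matrix", call. = FALSE)
  design <- design[match(colnames(expr), design$sample_id), , drop = FALSE]
  cultivars <- unique(design$cultivar[design$sample_id %in% c(groupA, groupB)])
  fc <- sapply(cultivars, function(cv) {
    a <- intersect(groupA, design$sample_id[design$cultivar == cv])
    b <- intersect(groupB, design$sample_id[design$cultivar == cv])
    if (!length(a) || !length(b)) return(rep(NA_real_, nrow(expr)))
    rowMeans(expr[, a, drop = FALSE]) - rowMeans(expr[, b, drop = FALSE])
  })
  if (is.null(dim(fc))) fc <- matrix(fc, ncol = length(cultivars))
  colnames(fc) <- cultivars
  overall <- rowMeans(expr[, groupA, drop = FALSE]) -
    rowMeans(expr[, groupB, drop = FALSE])
  fcm <- cbind(fc, overall = overall)
  rownames(fcm) <- rownames(expr)
  max_abs <- apply(abs(fc), 1, max, na.rm = TRUE)
  sel <- max_abs > min_abs_log2fc
  if (!is.null(classification)) {
    ok <- classification$gene_id[classification$class %in% classes]
    sel <- sel & rownames(expr) %in% ok
  }
  list(genes = rownames(expr)[sel], fold_changes = fcm, selected = sel)
}
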