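#' Read a count matrix
#'
#' Reads a gene x sample count matrix from tab-separated text (header row
#' of sample ids, first column of gene ids) or Matrix Market coordinate
#' format with companion one-id-per-line gene and sample index files.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"mtx"`.
#' @param organism organism tag for the resulting [count_matrix()].
#' @param genes_file,samples_file index files for `mtx` input; default to
#'   `<path minus .mtx>_genes.txt` / `_samples.txt`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"),
                              organism = "host",
                              genes_file = NULL, samples_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    gene_ids <- as.character(df[[1]])
    if (anyDuplicated(gene_ids))
      stop("duplicated gene id(s): ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
           call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(is.na(suppressWarnings(
        matrix(as.numeric(m), nrow(m)))) & !is.na(m), arr.ind = TRUE)
      stop(sprintf("non-numeric count at row %d, column %d",
                   bad[1, 1], bad[1, 2] + 1), call. = FALSE)
    }
    if (any(m < 0)) {
      bad <- which(m < 0, arr.ind = TRUE)
      stop(sprintf("negative count at row %d, column %d",
                   bad[1, 1], bad[1, 2] + 1), call. = FALSE)
    }
    rownames(m) <- gene_ids
    count_matrix(m, organism = organism)
  } else {
    if (!requireNamespace("Matrix", quietly = TRUE))
      stop("the Matrix package is required for mtx input", call. = FALSE)
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, "_genes.txt")
    samples_file <- samples_file %||% paste0(stem, "_samples.txt")
    m <- as.matrix(Matrix::readMM(path))
    gene_ids <- readLines(genes_file)
    sample_ids <- readLines(samples_file)
    if (length(gene_ids) != nrow(m) || length(sample_ids) != ncol(m))
      stop("index files do not match the matrix dimensions", call. = FALSE)
    if (anyDuplicated(gene_ids))
      stop("duplicated gene id(s): ",
           paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
           call. = FALSE)
    dimnames(m) <- list(gene_ids, sample_ids)
    count_matrix(m, organism = organism)
  }
}

#' Write a count matrix as TSV
#'
#' @param cm a [count_matrix()] or plain matrix.
#' @param path output file; first column `gene_id`, one column per sample.
#' @export
write_count_matrix <- function(cm, path) {
  m <- .as_counts(cm)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @noRd
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a sample design table
#' @param path TSV with columns sample_id, cultivar, fungal_treatment,
#'   block, replicate.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- read_tsv(path)
  need <- c("sample_id", "cultivar", "fungal_treatment", "block", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("design file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}

#' Read a sample x trait table
#' @param path TSV with a sample_id column plus numeric trait columns.
#' @return data.frame.
#' @export
read_traits <- function(path) {
  d <- read_tsv(path)
  if (!"sample_id" %in% names(d))
    stop("trait file must carry a sample_id column", call. = FALSE)
  d
}

#' Write simulator output to a directory
#'
#' Writes `host_counts.tsv`, `fungus_counts.tsv`, `metadata.tsv`,
#' `traits.tsv` and `truth.json` in the simulator's interchange layout.
#'
#' @param sim output of [simulate_dual_experiment()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(sim$host, file.path(dir, "host_counts.tsv"))
  write_count_matrix(sim$symbiont, file.path(dir, "fungus_counts.tsv"))
  write_tsv(sim$design, file.path(dir, "metadata.tsv"))
  write_tsv(sim$traits, file.path(dir, "traits.tsv"))
  truth <- sim$truth
  truth$factors <- NULL                       # large; kept in memory only
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are rejected; known keys override the defaults of
#' [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}
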