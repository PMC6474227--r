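#' Pipeline configuration
#'
#' Collects every numeric parameter of the full analysis with its default:
#' soft power 12, minimum module size 50, eigengene merge cut 0.1, cross
#' edge threshold p < 0.001, key-gene |GS| quantile 0.90 and kME > 0.8,
#' per-term BH-FDR 0.05 for response classification, fold-change cuts of 2
#' (host) and 4 (symbiont), and a CPM prior of 0.5.
#'
#' @param host_counts,symbiont_counts,metadata,traits optional input file
#'   paths; when `host_counts` is `NULL` the synthetic generator supplies
#'   the data.
#' @param sim a [sim_config()] used when simulating.
#' @param power,min_size,merge_cut,mode,gap_frac module construction
#'   parameters (see [build_modules()]).
#' @param edge_alpha,quantile,kme_min cross-network parameters.
#' @param de_alpha response-classification FDR level.
#' @param fc_host,fc_symbiont per-organism |log2FC| gene-set thresholds.
#' @param prior log2-CPM prior count.
#' @param min_cpm,min_samples expression filter.
#' @param n_perm permutations for the relabelling null.
#' @param seed integer master seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(host_counts = NULL, symbiont_counts = NULL,
                            metadata = NULL, traits = NULL,
                            sim = sim_config(),
                            power = 12, min_size = 50, merge_cut = 0.1,
                            mode = "unsigned", gap_frac = 0.25,
                            edge_alpha = 0.001, quantile = 0.9,
                            kme_min = 0.8, de_alpha = 0.05,
                            fc_host = 2, fc_symbiont = 4, prior = 0.5,
                            min_cpm = 1, min_samples = 3, n_perm = 100,
                            seed = 1L) {
  if (is.list(sim) && !inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)
  cfg <- list(host_counts = host_counts, symbiont_counts = symbiont_counts,
              metadata = metadata, traits = traits, sim = sim,
              power = power, min_size = min_size, merge_cut = merge_cut,
              mode = mode, gap_frac = gap_frac, edge_alpha = edge_alpha,
              quantile = quantile, kme_min = kme_min, de_alpha = de_alpha,
              fc_host = fc_host, fc_symbiont = fc_symbiont, prior = prior,
              min_cpm = min_cpm, min_samples = min_samples, n_perm = n_perm,
              seed = as.integer(seed))
  stopifnot(cfg$power > 0, cfg$min_size >= 1,
            cfg$merge_cut >= 0, cfg$merge_cut <= 1,
            cfg$edge_alpha > 0, cfg$edge_alpha < 1,
            cfg$quantile >= 0, cfg$quantile <= 1,
            cfg$kme_min >= -1, cfg$kme_min <= 1,
            cfg$de_alpha > 0, cfg$de_alpha < 1,
            cfg$prior >= 0, cfg$n_perm >= 1)
  if (!cfg$mode %in% c("unsigned", "signed"))
    stop("mode must be 'unsigned' or 'signed'", call. = FALSE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @noRd
.config_fingerprint <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full dual-transcriptome pipeline
#'
#' Executes, in order: data acquisition (synthetic generation or file
#' input), expression filtering and log2-CPM normalisation (mock samples
#' are removed from the symbiont data, where the fungus is absent),
#' per-gene response classification for both organisms, fold-change gene
#' sets for the isolate contrast, module construction (host modules from
#' the pool of mycorrhiza-responsive genes, symbiont modules from all
#' retained genes), the cross-kingdom module correlation network with key
#' genes and a random-relabelling permutation null, and module--trait
#' association. All tables are written as TSV plus a GraphML network and a
#' JSON manifest; a rerun with the same configuration and seed reproduces
#' every table byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return invisibly, a list with every intermediate result.
#' @export
run_all <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(force(expr),
             error = function(e) stop("stage '", name, "' failed: ",
                                      conditionMessage(e), call. = FALSE))
  }

  # ---- data ----
  if (is.null(config$host_counts)) {
    sim <- stage("simulate",
                 simulate_dual_experiment(config$sim, seed = config$seed))
    stage("simulate", write_simulation(sim, out_dir))
    design <- sim$design; host_cm <- sim$host; sym_cm <- sim$symbiont
    traits <- sim$traits
  } else {
    design <- stage("input", read_design(config$metadata))
    host_cm <- stage("input", read_count_matrix(config$host_counts,
                                                organism = "host"))
    sym_cm <- stage("input", read_count_matrix(config$symbiont_counts,
                                               organism = "symbiont"))
    traits <- if (!is.null(config$traits)) read_traits(config$traits) else NULL
  }
  mock_ids <- design$sample_id[design$fungal_treatment == "mock"]
  inoc_ids <- setdiff(design$sample_id, mock_ids)
  if (!length(inoc_ids))
    stop("stage 'preprocess' failed: no inoculated samples in the design",
         call. = FALSE)

  # ---- preprocess ----
  host_f <- stage("preprocess",
                  filter_genes(host_cm, config$min_cpm, config$min_samples))
  sym_f <- stage("preprocess",
                 filter_genes(sym_cm, config$min_cpm, config$min_samples,
                              exclude_samples = mock_ids))
  message(sprintf("  host: %d/%d genes kept; symbiont: %d/%d genes kept (%d mock samples dropped)",
                  nrow(host_f$counts), nrow(host_cm$counts),
                  nrow(sym_f$counts), nrow(sym_cm$counts), length(mock_ids)))
  host_expr <- log2_cpm(host_f, prior = config$prior)
  sym_expr <- log2_cpm(sym_f, prior = config$prior)

  # ---- classify ----
  host_de <- stage("classify", classify_responses(host_expr, design,
                                                  alpha = config$de_alpha))
  sym_de <- stage("classify", classify_responses(sym_expr, design,
                                                 alpha = config$de_alpha))
  write_tsv(host_de, file.path(out_dir, "de_classes_host.tsv"))
  write_tsv(sym_de, file.path(out_dir, "de_classes_symbiont.tsv"))
  message(sprintf("  host classes: %s",
                  paste(names(table(host_de$class)), table(host_de$class),
                        sep = "=", collapse = ", ")))

  # ---- fold-change gene sets (isolate contrast) ----
  iso <- sort(unique(design$fungal_treatment[design$sample_id %in% inoc_ids]))
  fc_host <- fc_sym <- NULL
  if (length(iso) >= 2) {
    gA <- design$sample_id[design$fungal_treatment == iso[1]]
    gB <- design$sample_id[design$fungal_treatment == iso[2]]
    fc_host <- stage("foldchange",
                     select_by_fold_change(host_expr, design, gA, gB,
                                           config$fc_host, host_de))
    fc_sym <- stage("foldchange",
                    select_by_fold_change(sym_expr, design, gA, gB,
                                          config$fc_symbiont, sym_de))
    for (nm in c("host", "symbiont")) {
      fc <- if (nm == "host") fc_host else fc_sym
      df <- data.frame(gene_id = rownames(fc$fold_changes),
                       fc$fold_changes, selected = fc$selected,
                       check.names = FALSE)
      write_tsv(df, file.path(out_dir, paste0("foldchange_matrix_", nm, ".tsv")))
    }
  }

  # ---- modules ----
  # host modules come from the genes responsive to the fungal treatment
  # (conserved or interaction); symbiont modules from all retained genes
  pool <- host_de$gene_id[host_de$class %in%
    c("mycorrhiza_conserved", "isolate_conserved", "interaction")]
  if (length(pool) < config$min_size)
    stop("stage 'modules' failed: mycorrhiza-responsive gene pool smaller ",
         "than one module", call. = FALSE)
  host_part <- stage("modules",
                     build_modules(host_expr[pool, , drop = FALSE],
                                   power = config$power,
                                   min_size = config$min_size,
                                   merge_cut = config$merge_cut,
                                   mode = config$mode,
                                   gap_frac = config$gap_frac))
  sym_part <- stage("modules",
                    build_modules(sym_expr, power = config$power,
                                  min_size = config$min_size,
                                  merge_cut = config$merge_cut,
                                  mode = config$mode,
                                  gap_frac = config$gap_frac))
  message(sprintf("  %d host and %d symbiont modules",
                  nrow(host_part$ME), nrow(sym_part$ME)))
  for (nm in c("host", "symbiont")) {
    p <- if (nm == "host") host_part else sym_part
    write_tsv(data.frame(gene_id = names(p$labels), module_label = p$labels),
              file.path(out_dir, paste0("modules_", nm, ".tsv")))
    write_tsv(data.frame(module = rownames(p$ME), p$ME, check.names = FALSE),
              file.path(out_dir, paste0("eigengenes_", nm, ".tsv")))
    write_tsv(data.frame(gene_id = rownames(p$kME), p$kME,
                         check.names = FALSE),
              file.path(out_dir, paste0("kme_", nm, ".tsv")))
  }

  # ---- cross network ----
  edges <- stage("crossnet",
                 correlate_module_sets(host_part$ME, sym_part$ME,
                                       sample_subset = inoc_ids,
                                       edge_alpha = config$edge_alpha))
  write_tsv(edges, file.path(out_dir, "cross_edges.tsv"))
  net <- stage("crossnet", build_bipartite_network(edges))
  igraph::write_graph(net, file.path(out_dir, "network.graphml"),
                      format = "graphml")
  kg <- stage("crossnet",
              key_genes(host_expr[pool, , drop = FALSE], sym_expr,
                        host_part, sym_part, edges,
                        quantile = config$quantile,
                        kme_min = config$kme_min,
                        sample_subset = inoc_ids))
  write_tsv(kg, file.path(out_dir, "key_genes.tsv"))
  message(sprintf("  %d significant edges; %d host / %d symbiont key genes",
                  sum(edges$significant),
                  sum(kg$passes[kg$organism == "host"]),
                  sum(kg$passes[kg$organism == "symbiont"])))
  perm <- stage("permutation",
                permutation_null(host_expr[pool, , drop = FALSE], sym_expr,
                                 host_part$labels, sym_part$labels,
                                 n_perm = config$n_perm,
                                 edge_alpha = config$edge_alpha,
                                 sample_subset = inoc_ids,
                                 seed = config$seed + 1L))
  write_tsv(data.frame(permutation = seq_along(perm$null_counts),
                       n_significant_edges = perm$null_counts),
            file.path(out_dir, "permutation_null.tsv"))
  message(sprintf("  observed %d edges; null median %g; empirical p = %.4g",
                  perm$observed, stats::median(perm$null_counts),
                  perm$p_value))

  # ---- traits ----
  mt <- trait_kg <- NULL
  if (!is.null(traits)) {
    mt_host <- stage("traits",
                     correlate_modules_traits(host_part$ME, traits))
    mt_sym <- stage("traits",
                    correlate_modules_traits(sym_part$ME, traits,
                                             sample_subset = inoc_ids))
    mt_host$organism <- "host"; mt_sym$organism <- "symbiont"
    mt <- rbind(mt_host, mt_sym)
    write_tsv(mt, file.path(out_dir, "module_trait.tsv"))
    sig_tr <- unique(mt$trait[!is.na(mt$p) & mt$p < config$edge_alpha])
    tkl <- list()
    for (tr in sig_tr) {
      tkl[[length(tkl) + 1]] <- key_genes_for_trait(
        host_expr[pool, , drop = FALSE], host_part, traits, tr,
        alpha = config$edge_alpha, quantile = config$quantile,
        kme_min = config$kme_min)
      tkl[[length(tkl) + 1]] <- key_genes_for_trait(
        sym_expr, sym_part, traits, tr, alpha = config$edge_alpha,
        quantile = config$quantile, kme_min = config$kme_min,
        sample_subset = inoc_ids)
    }
    trait_kg <- if (length(tkl)) do.call(rbind, tkl) else NULL
    if (!is.null(trait_kg))
      write_tsv(trait_kg, file.path(out_dir, "trait_key_genes.tsv"))
  }

  # ---- manifest ----
  outputs <- sort(list.files(out_dir))
  outputs <- outputs[outputs != "manifest.json"]
  manifest <- list(
    package = "dualcoexp",
    package_version = as.character(utils::packageVersion("dualcoexp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_md5 = .config_fingerprint(config),
    schema_version = "1.0",
    n_samples = nrow(design),
    outputs = outputs,
    output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$output_md5) <- outputs
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(design = design, host_expr = host_expr,
                 symbiont_expr = sym_expr, host_de = host_de,
                 symbiont_de = sym_de, fc_host = fc_host,
                 fc_symbiont = fc_sym, host_modules = host_part,
                 symbiont_modules = sym_part, edges = edges, network = net,
                 key_genes = kg, permutation = perm, module_trait = mt,
                 trait_key_genes = trait_kg, manifest = manifest))
}
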