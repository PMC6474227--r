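# Shared fixtures, built in code.

# small standard design: 5 cultivars x (2 isolates + mock) x 3 reps
std_design <- function(seed = 1L) generate_design(5, 3, 3, 3, seed = seed)

# expression matrix with two planted correlation blocks plus noise genes
block_expr <- function(n_block = 60, n_noise = 0, n_samples = 45,
                       within = 0.6, seed = 1L) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  mk <- function(f, n) t(sapply(seq_len(n), function(i)
    sqrt(within) * f + sqrt(1 - within) * rnorm(n_samples)))
  x <- rbind(mk(f1, n_block), mk(f2, n_block),
             if (n_noise > 0) matrix(rnorm(n_noise * n_samples), n_noise))
  dimnames(x) <- list(paste0("g", seq_len(nrow(x))),
                      paste0("s", seq_len(n_samples)))
  x
}

# recovery-benchmark configuration: planted modules only, null background
recovery_config <- function(n_genes = 1500L) {
  sim_config(gxg_fraction = 0, cultivar_fraction = 0, conserved_fraction = 0,
             n_genes = c(host = n_genes, symbiont = n_genes))
}

# build both organisms' modules from one simulated dataset; memoised across
# acceptance blocks (module recovery and cross-network reuse the same runs)
.recovery_cache <- new.env(parent = emptyenv())
recovery_run <- function(seed, n_genes = 1500L) {
  key <- paste0("s", seed, "_n", n_genes)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  sim <- simulate_dual_experiment(recovery_config(n_genes), seed = seed)
  mock <- sim$design$sample_id[sim$design$fungal_treatment == "mock"]
  inoc <- setdiff(sim$design$sample_id, mock)
  expr_h <- log2_cpm(sim$host)
  expr_s <- log2_cpm(filter_genes(sim$symbiont, 1, 3, exclude_samples = mock))
  part_h <- suppressWarnings(build_modules(expr_h))
  part_s <- suppressWarnings(build_modules(expr_s))
  out <- list(sim = sim, inoc = inoc, expr_h = expr_h, expr_s = expr_s,
              part_h = part_h, part_s = part_s)
  .recovery_cache[[key]] <- out
  out
}

# majority-vote map from found module labels to planted truth labels
map_to_truth <- function(part, truth) {
  found <- sort(unique(part$labels[part$labels > 0]))
  vapply(found, function(fm) {
    tg <- truth[names(part$labels)[part$labels == fm]]
    tg <- tg[tg > 0]
    if (!length(tg)) return(NA_integer_)
    as.integer(names(which.max(table(tg))))
  }, integer(1))
}

# adjusted Rand index on method-assigned genes only
ari_assigned <- function(part, truth) {
  truth <- truth[names(part$labels)]
  keep <- part$labels > 0
  mclust::adjustedRandIndex(part$labels[keep], truth[keep])
}
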