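#' Default cassava cultivar labels used by the simulator
#' @noRd
.default_cultivars <- c("CM6438-14", "COL2215", "BRA337", "CM4574-7", "CM523-7")

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic dual-transcriptome
#' generator. The defaults describe the study conditions the downstream
#' analysis is validated under: a 5 cultivar x (2 fungal isolates + mock)
#' factorial with 3 replicates, five planted co-expression modules per
#' organism of 60--100 genes, a within-module expression correlation of 0.6,
#' three cross-kingdom module links of strength 0.9, and negative-binomial
#' counts at realistic bulk RNA-seq library sizes.
#'
#' @param n_genes named integer vector `c(host=, symbiont=)`: genes simulated
#'   per organism.
#' @param n_modules named integer vector: planted modules per organism.
#' @param module_size_range integer length-2: module sizes are drawn
#'   uniformly from this range.
#' @param cross_links data.frame with columns `host_module`,
#'   `symbiont_module`, `sign` (+1/-1) and `strength` in \[0,1\]: latent-factor
#'   sharing between module pairs across organisms.
#' @param within_module_cor target pairwise correlation of genes within a
#'   planted module, in (0,1).
#' @param gxg_fraction,cultivar_fraction,conserved_fraction fractions of the
#'   background (non-module) genes planted with, respectively, a genotype x
#'   genotype interaction response, a cultivar-only response, and a conserved
#'   response to the fungal treatment (split evenly between mycorrhiza- and
#'   isolate-conserved). Must sum to at most 1; the remainder are null genes.
#' @param nb_dispersion negative-binomial dispersion of the counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param lib_size_range length-2 numeric: per-sample library sizes are drawn
#'   uniformly from this interval.
#' @param trait_loadings data.frame with columns `organism`, `module`,
#'   `trait`, `coefficient`: each trait is a loading-weighted sum of module
#'   factors plus Gaussian noise. A trait named `"colonization"` is forced to
#'   exactly 0 in mock samples.
#' @param signal_sd log-scale amplitude of the latent gene signal.
#' @param factor_noise_sd sample-level noise added to each module factor on
#'   top of its design-driven (cultivar/treatment) mean structure.
#' @param contamination_mean mean count per gene for symbiont genes in mock
#'   samples (sparse cross-contamination, not structural zeros).
#' @param background_fraction fraction of each library consumed by the
#'   unsimulated remainder of the transcriptome. Sequencing is
#'   compositional: without this constant background mass, a module's
#'   coordinated expression swing would shift the per-sample total and
#'   CPM normalisation would partially cancel the module's own signal —
#'   an artifact of simulating only a small gene panel.
#' @param trait_noise_sd standard deviation of the Gaussian trait noise.
#' @param n_cultivars,n_fungal_levels,n_reps,n_blocks design dimensions
#'   passed to [generate_design()].
#' @param seed integer seed for the whole simulation stream.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = c(host = 1200L, symbiont = 1000L),
                       n_modules = c(host = 5L, symbiont = 5L),
                       module_size_range = c(60L, 100L),
                       cross_links = data.frame(
                         host_module = c(1L, 4L, 5L), symbiont_module = 1:3,
                         sign = c(1, -1, 1), strength = 0.9),
                       within_module_cor = 0.6,
                       gxg_fraction = 0.05,
                       cultivar_fraction = 0.35,
                       conserved_fraction = 0.02,
                       nb_dispersion = 0.05,
                       lib_size_range = c(5e5, 2e6),
                       trait_loadings = data.frame(
                         organism = c("symbiont", "host", "host"),
                         module = c(1L, 1L, 2L),
                         trait = c("colonization", "shoot_biomass", "root_biomass"),
                         coefficient = c(0.9, 0.8, 0.6)),
                       signal_sd = 1.2,
                       factor_noise_sd = 1.0,
                       contamination_mean = 0.1,
                       background_fraction = 0.8,
                       trait_noise_sd = 0.3,
                       n_cultivars = 5L, n_fungal_levels = 3L,
                       n_reps = 3L, n_blocks = 3L,
                       seed = 1L) {
  if (missing(trait_loadings) && nrow(trait_loadings) > 0) {
    # default loadings only make sense for modules that exist
    ok <- trait_loadings$module <=
      n_modules[match(trait_loadings$organism, names(n_modules))]
    trait_loadings <- trait_loadings[!is.na(ok) & ok, , drop = FALSE]
  }
  cfg <- list(
    n_genes = n_genes, n_modules = n_modules,
    module_size_range = as.integer(module_size_range),
    cross_links = cross_links, within_module_cor = within_module_cor,
    gxg_fraction = gxg_fraction, cultivar_fraction = cultivar_fraction,
    conserved_fraction = conserved_fraction,
    nb_dispersion = nb_dispersion, lib_size_range = lib_size_range,
    trait_loadings = trait_loadings, signal_sd = signal_sd,
    factor_noise_sd = factor_noise_sd,
    contamination_mean = contamination_mean,
    background_fraction = background_fraction,
    trait_noise_sd = trait_noise_sd,
    n_cultivars = as.integer(n_cultivars),
    n_fungal_levels = as.integer(n_fungal_levels),
    n_reps = as.integer(n_reps), n_blocks = as.integer(n_blocks),
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(all(cfg$n_genes >= 1), all(cfg$n_modules >= 0))
  if (any(cfg$module_size_range < 1))
    stop("module sizes must be >= 1", call. = FALSE)
  frac <- cfg$gxg_fraction + cfg$cultivar_fraction + cfg$conserved_fraction
  if (frac > 1 + 1e-12)
    stop("planted response-class fractions must sum to <= 1", call. = FALSE)
  cl <- cfg$cross_links
  if (nrow(cl) > 0) {
    if (any(cl$strength < 0 | cl$strength > 1))
      stop("cross-link strength must lie in [0, 1]", call. = FALSE)
    if (any(cl$host_module > cfg$n_modules[["host"]]) ||
        any(cl$symbiont_module > cfg$n_modules[["symbiont"]]))
      stop("cross-link references a module that does not exist", call. = FALSE)
    if (any(abs(cl$sign) != 1))
      stop("cross-link sign must be +1 or -1", call. = FALSE)
  }
  if (cfg$within_module_cor <= 0 || cfg$within_module_cor >= 1)
    stop("within_module_cor must lie in (0, 1)", call. = FALSE)
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (cfg$background_fraction < 0 || cfg$background_fraction >= 1)
    stop("background_fraction must lie in [0, 1)", call. = FALSE)
  if (any(cfg$lib_size_range <= 0) || diff(cfg$lib_size_range) < 0)
    stop("lib_size_range must be a positive increasing interval", call. = FALSE)
  invisible(cfg)
}

#' Generate a full-factorial greenhouse sample design
#'
#' Crosses cultivars with fungal treatments (the last treatment level is the
#' mock-inoculated control) over replicates, and assigns samples to blocks
#' round-robin after a seeded shuffle, emulating a randomized greenhouse
#' layout.
#'
#' @param n_cultivars,n_fungal_levels,n_reps,n_blocks positive integers;
#'   `n_fungal_levels` includes exactly one mock level.
#' @param seed integer seed (block randomization).
#' @return data.frame with columns `sample_id`, `cultivar`,
#'   `fungal_treatment`, `block`, `replicate`. The mock level is named
#'   `"mock"`; inoculated levels `"isolateA"`, `"isolateB"`, ...
#' @export
generate_design <- function(n_cultivars = 5L, n_fungal_levels = 3L,
                            n_reps = 3L, n_blocks = 3L, seed = 1L) {
  if (any(c(n_cultivars, n_fungal_levels, n_reps, n_blocks) < 1))
    stop("design dimensions must be positive integers", call. = FALSE)
  cultivars <- if (n_cultivars <= length(.default_cultivars)) {
    .default_cultivars[seq_len(n_cultivars)]
  } else {
    c(.default_cultivars, paste0("CV", seq_len(n_cultivars - length(.default_cultivars))))
  }
  treatments <- if (n_fungal_levels == 1) "mock" else
    c(paste0("isolate", LETTERS[seq_len(n_fungal_levels - 1)]), "mock")
  design <- expand.grid(replicate = seq_len(n_reps),
                        fungal_treatment = treatments,
                        cultivar = cultivars,
                        stringsAsFactors = FALSE)
  design <- design[, c("cultivar", "fungal_treatment", "replicate")]
  design$sample_id <- sprintf("S%03d_%s_%s_r%d", seq_len(nrow(design)),
                              gsub("[^A-Za-z0-9]", "", design$cultivar),
                              design$fungal_treatment, design$replicate)
  set.seed(seed)
  ord <- sample.int(nrow(design))
  design$block <- character(nrow(design))
  design$block[ord] <- paste0("B", rep_len(seq_len(n_blocks), nrow(design)))
  rownames(design) <- NULL
  design[, c("sample_id", "cultivar", "fungal_treatment", "block", "replicate")]
}

#' @noRd
is_mock <- function(design) design$fungal_treatment == "mock"

#' Build one design-driven factor profile over samples
#'
#' Returns an (unstandardized) mean profile for a given response class.
#' @noRd
.factor_effect <- function(design, type) {
  n <- nrow(design)
  cu <- factor(design$cultivar)
  tr <- factor(design$fungal_treatment)
  amf <- !is_mock(design)
  switch(type,
    cultivar_only = {
      eff <- stats::rnorm(nlevels(cu))
      eff[as.integer(cu)]
    },
    mycorrhiza_conserved = {
      amp <- stats::runif(1, 0.8, 1.5)
      ifelse(amf, amp, -amp)
    },
    isolate_conserved = {
      amp <- stats::runif(1, 0.8, 1.5)
      lev <- levels(tr)[levels(tr) != "mock"]
      sgn <- ifelse(design$fungal_treatment == lev[1], 1,
                    ifelse(design$fungal_treatment == lev[min(2, length(lev))], -1, 0))
      amp * sgn
    },
    interaction = {
      cell <- interaction(cu, tr, drop = TRUE)
      eff <- stats::rnorm(nlevels(cell), sd = 1)
      eff[as.integer(cell)]
    },
    null = rep(0, n),
    stop("unknown response class: ", type, call. = FALSE))
}

#' Generate latent module factors
#'
#' One latent factor per planted module, carrying the module's planted
#' response class as a design-driven mean structure plus sample-level noise,
#' standardized to unit variance across samples. Cross-linked host/symbiont
#' module pairs share a common component with the configured sign and
#' strength: at strength 1 and zero noise the two factors are identical up
#' to sign; at strength 0 they are independent.
#'
#' Host module classes cycle through interaction, mycorrhiza-conserved,
#' cultivar-only, isolate-conserved; symbiont modules (whose expression only
#' exists in inoculated samples) cycle through interaction, isolate-conserved
#' and cultivar-only. A cross-linked symbiont module inherits most of its
#' structure from its host partner.
#'
#' @param design a design from [generate_design()].
#' @param config a [sim_config()].
#' @return list with `factors` (factor x sample matrix, rows named
#'   `host_1`, ..., `symbiont_1`, ...), `module_class` (named character:
#'   planted response class per module factor) and `cross_links`.
#' @export
generate_latent_factors <- function(design, config) {
  if (nrow(design) < 2) stop("design must contain at least 2 samples", call. = FALSE)
  validate_sim_config(config)
  n <- nrow(design)
  # each deterministic treatment-contrast class (mycorrhiza- or
  # isolate-conserved) is used at most once per organism, and only by the
  # host: modules sharing such a fixed profile would be correlated by
  # construction, which would plant cross-kingdom links beyond cross_links.
  # interaction and cultivar classes draw fresh random effects per module.
  host_classes <- rep_len(c("interaction", "mycorrhiza_conserved",
                            "cultivar_only", "isolate_conserved"),
                          config$n_modules[["host"]])
  if (config$n_modules[["host"]] > 4)
    host_classes[5:config$n_modules[["host"]]] <-
      rep_len(c("interaction", "cultivar_only"),
              config$n_modules[["host"]] - 4)
  sym_classes <- rep_len(c("interaction", "cultivar_only"),
                         config$n_modules[["symbiont"]])
  standardize <- function(x) {
    s <- stats::sd(x)
    if (s < .Machine$double.eps) x - mean(x) else (x - mean(x)) / s
  }
  make_factor <- function(type) {
    raw <- .factor_effect(design, type) +
      config$factor_noise_sd * stats::rnorm(n)
    standardize(raw)
  }
  fmat <- function(classes, prefix) {
    f <- matrix(0, length(classes), n)
    for (i in seq_along(classes)) f[i, ] <- make_factor(classes[i])
    rownames(f) <- if (length(classes)) paste0(prefix, seq_along(classes))
    f
  }
  host_f <- fmat(host_classes, "host_")
  sym_f <- fmat(sym_classes, "symbiont_")
  cl <- config$cross_links
  if (nrow(cl) > 0) {
    # link strength is defined as the factor-factor Pearson correlation
    # across the inoculated samples (the only samples where symbiont
    # expression exists), so the shared and private components are
    # standardized and orthogonalized on that subset
    inoc <- !is_mock(design)
    if (!any(inoc))
      stop("cross-links require inoculated samples in the design",
           call. = FALSE)
    std_inoc <- function(x) {
      s <- stats::sd(x[inoc])
      if (s < .Machine$double.eps) x - mean(x[inoc])
      else (x - mean(x[inoc])) / s
    }
    for (i in seq_len(nrow(cl))) {
      hm <- cl$host_module[i]; sm <- cl$symbiont_module[i]
      g <- cl$strength[i]; s <- cl$sign[i]
      zh <- std_inoc(host_f[hm, ])
      zs <- std_inoc(sym_f[sm, ])
      if (g > 0 && stats::sd(zh[inoc]) > 0) {
        fit <- stats::lm.fit(cbind(1, zh[inoc]), zs[inoc])
        zs[inoc] <- fit$residuals
        zs <- std_inoc(zs)
      }
      sym_f[sm, ] <- if (g == 1) s * zh else
        std_inoc(s * g * zh + sqrt(1 - g^2) * zs)
      sym_classes[sm] <- host_classes[hm]
    }
  }
  factors <- rbind(host_f, sym_f)
  colnames(factors) <- design$sample_id
  module_class <- c(host_classes, sym_classes)
  names(module_class) <- rownames(factors)
  list(factors = factors, module_class = module_class,
       cross_links = cl)
}

#' @noRd
.assign_modules <- function(n_genes, n_modules, size_range) {
  sizes <- if (n_modules == 0) integer(0) else
    sample(seq(size_range[1], size_range[2]), n_modules, replace = TRUE)
  if (sum(sizes) > n_genes)
    stop("planted modules do not fit in n_genes", call. = FALSE)
  labels <- integer(n_genes)
  pos <- 1L
  for (m in seq_len(n_modules)) {
    labels[pos:(pos + sizes[m] - 1L)] <- m
    pos <- pos + sizes[m]
  }
  labels
}

#' Generate negative-binomial dual count matrices
#'
#' Gene-level latent signals combine the module factors (within-module
#' correlation set by `within_module_cor`) with per-gene noise; background
#' genes receive independent design-driven responses according to the
#' configured class fractions. Expected counts follow a log-linear model,
#' are normalized to per-sample library sizes drawn from `lib_size_range`,
#' and are drawn negative-binomially with the configured dispersion.
#' Symbiont genes in mock samples are drawn from a sparse Poisson
#' contamination process with mean `contamination_mean` per gene.
#'
#' @param design design from [generate_design()].
#' @param latent output of [generate_latent_factors()] for the same design.
#' @param config a [sim_config()].
#' @return list with `host` and `symbiont` [count_matrix()] objects and
#'   `truth`, the planted ground truth (module labels, response classes,
#'   factors, cross links).
#' @export
generate_counts <- function(design, latent, config) {
  validate_sim_config(config)
  if (!identical(colnames(latent$factors), design$sample_id))
    stop("latent factors were generated from a different design", call. = FALSE)
  n <- nrow(design)
  mock <- is_mock(design)
  truth <- list(module_labels = list(), response_class = list(),
                factors = latent$factors, module_class = latent$module_class,
                cross_links = latent$cross_links,
                trait_loadings = config$trait_loadings)

  sim_org <- function(org) {
    ng <- config$n_genes[[org]]
    labels <- .assign_modules(ng, config$n_modules[[org]],
                              config$module_size_range)
    gene_ids <- sprintf("%s_g%04d", ifelse(org == "host", "Manes", "RhiIr"),
                        seq_len(ng))
    names(labels) <- gene_ids
    baseline <- stats::runif(ng, log(100), log(1000))
    # per-gene latent weights inflated by the predicted count-noise
    # attenuation, so that the realized within-module log-CPM correlation
    # matches within_module_cor: counts add shot noise ~1/mu and
    # overdispersion on the log scale, shrinking latent correlations by
    # a_g = s2 / (s2 + v_g) per gene
    s2 <- config$signal_sd^2
    bgf <- config$background_fraction
    depth0 <- mean(config$lib_size_range) / (1 - bgf)
    # e^(s2/2): mean of the lognormal signal, so realized library sizes
    # land in lib_size_range
    total0 <- sum(exp(baseline + s2 / 2)) / (1 - bgf)
    mu0 <- depth0 * exp(baseline + s2 / 2) / total0
    v_g <- config$nb_dispersion + 1 / mu0
    a_g <- s2 / (s2 + v_g)
    w <- pmin(config$within_module_cor / a_g, 0.95)
    z <- matrix(stats::rnorm(ng * n), ng, n)      # per-gene noise, unit var
    classes <- rep("null", ng)
    for (g in seq_len(ng)) {
      if (labels[g] > 0) {
        f <- latent$factors[paste0(org, "_", labels[g]), ]
        z[g, ] <- sqrt(w[g]) * f + sqrt(1 - w[g]) * z[g, ]
        classes[g] <- latent$module_class[[paste0(org, "_", labels[g])]]
      }
    }
    bg <- which(labels == 0)
    n_bg <- length(bg)
    n_gxg <- round(config$gxg_fraction * n_bg)
    n_cv <- round(config$cultivar_fraction * n_bg)
    n_cons <- round(config$conserved_fraction * n_bg)
    planted <- sample(bg, min(n_bg, n_gxg + n_cv + n_cons))
    cls_pool <- c(rep("interaction", n_gxg), rep("cultivar_only", n_cv),
                  rep(c("mycorrhiza_conserved", "isolate_conserved"),
                      length.out = n_cons))
    # symbiont data never contains mock samples downstream, so a
    # mock-vs-AMF response is not identifiable there
    if (org == "symbiont")
      cls_pool[cls_pool == "mycorrhiza_conserved"] <- "isolate_conserved"
    for (k in seq_along(planted)) {
      g <- planted[k]
      eff <- .factor_effect(design, cls_pool[k])
      s <- stats::sd(eff)
      if (s > .Machine$double.eps) {
        eff <- (eff - mean(eff)) / s
        z[g, ] <- sqrt(w[g]) * eff + sqrt(1 - w[g]) * z[g, ]
        classes[g] <- cls_pool[k]
      }
    }
    log_rate <- baseline + config$signal_sd * z
    rate <- exp(log_rate)
    lib <- round(stats::runif(n, config$lib_size_range[1],
                              config$lib_size_range[2]))
    # constant background mass: the unsimulated transcriptome's share of
    # each library, keeping normalisation from cancelling module signal
    bgf <- config$background_fraction
    bg_mass <- bgf / (1 - bgf) * sum(exp(baseline + config$signal_sd^2 / 2))
    counts <- matrix(0L, ng, n, dimnames = list(gene_ids, design$sample_id))
    for (s in seq_len(n)) {
      if (org == "symbiont" && mock[s]) {
        counts[, s] <- stats::rpois(ng, config$contamination_mean)
      } else {
        depth <- lib[s] / (1 - bgf)
        mu <- depth * rate[, s] / (sum(rate[, s]) + bg_mass)
        counts[, s] <- if (config$nb_dispersion == 0) stats::rpois(ng, mu)
          else stats::rnbinom(ng, mu = mu, size = 1 / config$nb_dispersion)
      }
    }
    list(cm = count_matrix(counts, organism = org), labels = labels,
         classes = stats::setNames(classes, gene_ids))
  }

  host <- sim_org("host")
  sym <- sim_org("symbiont")
  truth$module_labels <- list(host = host$labels, symbiont = sym$labels)
  truth$response_class <- list(host = host$classes, symbiont = sym$classes)
  list(host = host$cm, symbiont = sym$cm, truth = truth)
}

#' Generate quantitative trait values
#'
#' Each trait is a loading-weighted sum of module factors plus Gaussian
#' noise. A trait named `"colonization"` emulates percent root-length
#' colonization and is forced to exactly 0 in mock samples.
#'
#' @param design design from [generate_design()].
#' @param latent output of [generate_latent_factors()].
#' @param config a [sim_config()].
#' @return data.frame: `sample_id` plus one numeric column per trait.
#' @export
generate_traits <- function(design, latent, config) {
  tl <- config$trait_loadings
  if (is.null(tl) || nrow(tl) == 0)
    return(data.frame(sample_id = design$sample_id))
  keys <- paste0(tl$organism, "_", tl$module)
  missing <- setdiff(keys, rownames(latent$factors))
  if (length(missing))
    stop("trait loading references unknown module(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- nrow(design)
  traits <- data.frame(sample_id = design$sample_id)
  for (tr in unique(tl$trait)) {
    rows <- tl[tl$trait == tr, ]
    val <- rep(0, n)
    for (i in seq_len(nrow(rows)))
      val <- val + rows$coefficient[i] *
        latent$factors[paste0(rows$organism[i], "_", rows$module[i]), ]
    val <- val + stats::rnorm(n, sd = config$trait_noise_sd)
    if (tr == "colonization") val[is_mock(design)] <- 0
    traits[[tr]] <- unname(val)
  }
  traits
}

#' Simulate a complete dual-transcriptome experiment
#'
#' Runs design, latent factors, counts and traits in sequence under a single
#' seed, so that identical (config, seed) pairs give identical output.
#'
#' @param config a [sim_config()].
#' @param seed integer; overrides `config$seed` when given.
#' @return list with `design`, `host`, `symbiont` (count matrices), `traits`
#'   and `truth`.
#' @export
simulate_dual_experiment <- function(config = sim_config(), seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  design <- generate_design(config$n_cultivars, config$n_fungal_levels,
                            config$n_reps, config$n_blocks, seed = seed)
  # generate_design seeds the stream; everything below continues it
  latent <- generate_latent_factors(design, config)
  cm <- generate_counts(design, latent, config)
  traits <- generate_traits(design, latent, config)
  list(design = design, host = cm$host, symbiont = cm$symbiont,
       traits = traits, truth = cm$truth)
}
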