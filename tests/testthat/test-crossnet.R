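test_that("module-set correlation matches the closed-form t transform", {
  set.seed(15)
  me_h <- matrix(rnorm(3 * 30), 3, 30,
                 dimnames = list(paste0("ME", 1:3), paste0("s", 1:30)))
  me_s <- matrix(rnorm(2 * 30), 2, 30,
                 dimnames = list(paste0("ME", 1:2), paste0("s", 1:30)))
  me_s[1, ] <- me_h[1, ]               # identical eigengene across organisms
  tab <- correlate_module_sets(me_h, me_s)
  row11 <- tab[tab$module_host == "ME1" & tab$module_symbiont == "ME1", ]
  expect_equal(row11$r, 1)
  expect_equal(row11$p, 0)
  expect_true(row11$significant)
  # r = 0.5, n = 30: t = 0.5*sqrt(28/0.75) = 3.0551, two-sided p ~ 0.0049
  t_ref <- 0.5 * sqrt(28 / 0.75)
  p_ref <- 2 * pt(t_ref, 28, lower.tail = FALSE)
  expect_equal(t_ref, 3.0551, tolerance = 1e-4)
  expect_equal(p_ref, 0.0048999, tolerance = 1e-4)
  # verify against the implementation on constructed data with r = 0.5
  f <- scale(rnorm(30))[, 1]
  e <- scale(resid(lm(rnorm(30) ~ f)))[, 1]
  me_h2 <- rbind(ME1 = f)
  me_s2 <- rbind(ME1 = 0.5 * f + sqrt(0.75) * e)
  colnames(me_h2) <- colnames(me_s2) <- paste0("s", 1:30)
  tab2 <- correlate_module_sets(me_h2, me_s2)
  expect_equal(tab2$r, 0.5, tolerance = 1e-10)
  expect_equal(tab2$p, p_ref, tolerance = 1e-8)
  expect_false(tab2$significant)       # 0.0049 > 0.001
  expect_error(correlate_module_sets(me_h[, 1:3], me_s[, 1:3]), "4")
})

test_that("bipartite network holds exactly the significant pairs", {
  edges <- data.frame(module_host = rep(paste0("ME", 1:2), each = 2),
                      module_symbiont = rep(paste0("ME", 1:2), 2),
                      r = c(0.9, 0.1, -0.2, 0.3),
                      p = c(1e-5, 0.5, 0.4, 0.2),
                      q = NA, n = 30,
                      significant = c(TRUE, FALSE, FALSE, FALSE))
  g <- build_bipartite_network(edges)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 4)
  expect_setequal(igraph::V(g)$name[!igraph::V(g)$isolated],
                  c("host:ME1", "symbiont:ME1"))
  expect_equal(igraph::E(g)$weight, 0.9)
  edges$significant <- FALSE
  expect_equal(igraph::ecount(build_bipartite_network(edges)), 0)
})

test_that("gene significance is the plain correlation with the reference", {
  set.seed(16)
  ref <- rnorm(40)
  names(ref) <- paste0("s", 1:40)
  e <- scale(resid(lm(rnorm(40) ~ ref)))[, 1]
  expr <- rbind(same = ref, orth = e,
                matrix(rnorm(5 * 40), 5, 40,
                       dimnames = list(paste0("g", 1:5), names(ref))))
  colnames(expr) <- names(ref)
  gs <- gene_significance(expr, ref)
  expect_equal(gs[["same"]], 1, tolerance = 1e-10)
  expect_equal(gs[["orth"]], 0, tolerance = 1e-10)
  expect_equal(unname(gs[paste0("g", 1:5)]),
               unname(apply(expr[paste0("g", 1:5), ], 1,
                            function(x) cor(x, ref))), tolerance = 1e-12)
})

test_that("key-gene rule equals brute force and is monotone", {
  gs <- setNames(seq(0.1, 1.0, by = 0.1), paste0("g", 1:10))
  kme <- setNames(rep(0.9, 10), names(gs))
  got <- select_key_genes(gs, kme, quantile = 0.9, kme_min = 0.8)
  qthr <- quantile(abs(gs), 0.9)
  expect_identical(unname(got), unname(abs(gs) >= qthr & kme > 0.8))
  # kME rule dominates
  expect_false(any(select_key_genes(gs, setNames(rep(0.5, 10), names(gs)))))
  # single gene sits at its own quantile
  expect_true(select_key_genes(setNames(0.3, "g"), setNames(0.95, "g"))[["g"]])

  # equality with an enumerated brute-force filter and monotonicity
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    gs_i <- setNames(runif(n, -1, 1), paste0("g", seq_len(n)))
    kme_i <- setNames(runif(n, 0, 1), names(gs_i))
    q <- runif(1, 0.5, 0.95); k <- runif(1, 0.3, 0.9)
    got <- select_key_genes(gs_i, kme_i, q, k)
    brute <- abs(gs_i) >= quantile(abs(gs_i), q) & kme_i > k
    expect_identical(unname(got), unname(brute))
    # tightening either threshold never adds genes
    tq <- select_key_genes(gs_i, kme_i, min(q + 0.04, 1), k)
    tk <- select_key_genes(gs_i, kme_i, q, min(k + 0.05, 1))
    expect_true(all(!tq | got))
    expect_true(all(!tk | got))
  }
})

test_that("key genes across organisms carry per-pair provenance", {
  run <- recovery_run(1)
  edges <- correlate_module_sets(run$part_h$ME, run$part_s$ME,
                                 sample_subset = run$inoc)
  kg <- key_genes(run$expr_h, run$expr_s, run$part_h, run$part_s, edges,
                  sample_subset = run$inoc)
  expect_true(all(c("gene_id", "organism", "module", "partner_module",
                    "GS", "kME", "passes") %in% names(kg)))
  expect_true(nrow(kg) > 0)
  expect_true(any(kg$passes))
  # every reported row belongs to a significantly correlated pair
  sig_pairs <- paste(edges$module_host[edges$significant],
                     edges$module_symbiont[edges$significant])
  kg_pairs <- ifelse(kg$organism == "host",
                     paste(kg$module, kg$partner_module),
                     paste(kg$partner_module, kg$module))
  expect_true(all(kg_pairs %in% sig_pairs))
  # passing genes satisfy the rule within their (module, partner) group
  for (grp in split(kg, paste(kg$module, kg$partner_module, kg$organism))) {
    qthr <- quantile(abs(grp$GS), 0.9)
    expect_identical(grp$passes, abs(grp$GS) >= qthr & grp$kME > 0.8)
  }
})

test_that("edge table is symmetric under swapping organism roles", {
  run <- recovery_run(1)
  e1 <- correlate_module_sets(run$part_h$ME, run$part_s$ME,
                              sample_subset = run$inoc)
  e2 <- correlate_module_sets(run$part_s$ME, run$part_h$ME,
                              sample_subset = run$inoc)
  key1 <- paste(e1$module_host, e1$module_symbiont)
  key2 <- paste(e2$module_symbiont, e2$module_host)
  expect_equal(e1$r, e2$r[match(key1, key2)], tolerance = 1e-12)
  expect_equal(e1$p, e2$p[match(key1, key2)], tolerance = 1e-12)
})

test_that("permutation null validates the observed network", {
  # one strongly shared module per organism in a sea of noise genes:
  # relabeling dilutes the shared factor far below detectability
  set.seed(18)
  f <- rnorm(30)
  mk_org <- function(seed) {
    set.seed(seed)
    mod <- t(sapply(1:60, function(i) sqrt(0.7) * f + sqrt(0.3) * rnorm(30)))
    x <- rbind(mod, matrix(rnorm(3000 * 30), 3000, 30))
    dimnames(x) <- list(paste0("g", seq_len(nrow(x))), paste0("s", 1:30))
    x
  }
  xh <- mk_org(181); xs <- mk_org(182)
  labs <- setNames(c(rep(1L, 60), rep(0L, 3000)), rownames(xh))
  expect_error(permutation_null(xh, xs, labs, labs, n_perm = 0), "n_perm")
  pn <- permutation_null(xh, xs, labs, labs, n_perm = 19, seed = 2)
  expect_equal(length(pn$null_counts), 19)
  meh <- module_eigengenes(xh, labs)$ME
  mes <- module_eigengenes(xs, labs)$ME
  expect_equal(pn$observed, sum(correlate_module_sets(meh, mes)$significant))
  expect_equal(pn$observed, 1)
  # the real shared module tops every permutation
  expect_equal(pn$p_value, 1 / 20)
})
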