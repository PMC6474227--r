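test_that("adjacency follows the soft-threshold formulas", {
  # construct profiles with exact correlations 1 and -0.5
  x <- c(1, 2, 3, 4)
  y <- 2 * x + 1                       # cor 1
  z <- c(2.5, 3, 1, 1.5)               # cor(x, z) = -0.5 by construction?
  # force exact -0.5 instead: use orthogonal decomposition
  x0 <- scale(x)[, 1]
  e <- scale(resid(lm(rnorm(4) ~ x0)))[, 1]
  z <- -0.5 * x0 + sqrt(0.75) * e
  expr <- rbind(a = x, b = y, c = z)
  colnames(expr) <- paste0("s", 1:4)
  adj <- adjacency(expr, power = 12)
  expect_equal(adj["a", "b"], 1, tolerance = 1e-12)
  expect_equal(adj["a", "c"], 0.5^12, tolerance = 1e-10)
  expect_equal(adj["a", "c"], 2.44140625e-4, tolerance = 1e-10)
  adj_s <- adjacency(expr, power = 2, mode = "signed")
  expect_equal(adj_s["a", "c"], ((1 - 0.5) / 2)^2, tolerance = 1e-10)
  expect_error(adjacency(expr[, 1:2]), "3 samples")
  expr0 <- rbind(expr, flat = rep(1, 4))
  expect_warning(a0 <- adjacency(expr0), "zero-variance")
  expect_false("flat" %in% rownames(a0))
})

test_that("topological overlap matches formula limits and a naive oracle", {
  ones <- matrix(1, 3, 3)
  expect_equal(unname(topological_overlap(ones)), matrix(1, 3, 3))
  eye <- diag(3)
  t0 <- topological_overlap(eye)
  expect_equal(unname(t0), diag(3))

  naive_tom <- function(a) {
    n <- nrow(a); out <- diag(n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      l <- 0
      for (u in 1:n) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    out
  }
  set.seed(7)
  for (rep in 1:3) {
    r <- matrix(runif(400), 20, 20); r <- (r + t(r)) / 2
    a <- r^2; diag(a) <- 1
    tom <- topological_overlap(a)
    expect_lt(max(abs(unname(tom) - naive_tom(a))), 1e-10)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(unname(tom)))
  }
})

test_that("average-linkage clustering reproduces hand arithmetic and a naive oracle", {
  # 3 points, distances 0.1 / 0.9 / 0.9: first merge the close pair at 0.1,
  # then the singleton joins at the average 0.9
  d3 <- matrix(c(0, .1, .9, .1, 0, .9, .9, .9, 0), 3, 3)
  hc <- cluster_genes(d3)
  expect_equal(hc$height, c(0.1, 0.9), tolerance = 1e-12)
  expect_setequal(-hc$merge[1, ], c(1, 2))

  # two perfectly separated blocks: top split at exactly 1
  db <- matrix(1, 8, 8); db[1:4, 1:4] <- 0; db[5:8, 5:8] <- 0; diag(db) <- 0
  hcb <- cluster_genes(db)
  expect_equal(max(hcb$height), 1)
  expect_setequal(cutree(hcb, 2)[1:4], 1)

  naive_avg <- function(d) {
    act <- as.list(seq_len(nrow(d))); h <- numeric(0)
    dm <- d
    while (length(act) > 1) {
      best <- c(Inf, 0, 0)
      for (i in seq_along(act)) for (j in seq_len(i - 1)) {
        dd <- mean(dm[act[[i]], act[[j]]])
        if (dd < best[1]) best <- c(dd, j, i)
      }
      h <- c(h, best[1])
      act[[best[2]]] <- c(act[[best[2]]], act[[best[3]]])
      act[[best[3]]] <- NULL
    }
    h
  }
  set.seed(8)
  m <- matrix(runif(900), 30, 30); m <- (m + t(m)) / 2; diag(m) <- 0
  expect_equal(cluster_genes(m)$height, naive_avg(m), tolerance = 1e-10)
  expect_error(cluster_genes(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("dynamic cut finds planted blocks and rejects noise", {
  # two clean blocks of 60 -> exactly 2 modules, perfect membership
  x <- block_expr(60, 0, 45, within = 0.999, seed = 1)
  p <- build_modules(x, min_size = 50)
  expect_equal(nrow(p$ME), 2)
  expect_equal(unname(table(p$labels[1:60])), 60, ignore_attr = TRUE)
  expect_equal(length(unique(p$labels[1:60])), 1)
  expect_equal(length(unique(p$labels[61:120])), 1)
  expect_true(all(p$labels > 0))

  # one 40-gene block under min_size 50 -> unassigned
  x40 <- block_expr(40, 0, 45, within = 0.95, seed = 2)[1:40, ]
  adj <- adjacency(x40); hc <- cluster_genes(1 - topological_overlap(adj))
  expect_true(all(suppressWarnings(dynamic_cut(hc, min_size = 50)) == 0))
  expect_warning(dynamic_cut(hc, min_size = 500), "min_size")

  # i.i.d. noise: >= 80% of genes unassigned (median over 10 seeds)
  fr <- sapply(1:10, function(s) {
    set.seed(100 + s)
    noise <- matrix(rnorm(300 * 45), 300, 45,
                    dimnames = list(paste0("g", 1:300), paste0("s", 1:45)))
    part <- suppressWarnings(build_modules(noise))
    mean(part$labels == 0)
  })
  expect_gte(median(fr), 0.8)
})

test_that("module eigengenes equal PCA ground truth", {
  # identical profiles: eigengene is the standardized profile, varexp 1
  set.seed(9)
  prof <- rnorm(45)
  x <- matrix(rep(prof, each = 5), 5, 45,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:45)))
  labs <- setNames(rep(1L, 5), rownames(x))
  eg <- module_eigengenes(x, labs)
  expect_equal(eg$var_explained[["ME1"]], 1, tolerance = 1e-10)
  expect_equal(abs(cor(eg$ME[1, ], prof)), 1, tolerance = 1e-10)
  expect_equal(sd(eg$ME[1, ]), 1, tolerance = 1e-10)

  # 2-gene module: variance explained is (1 + |r|) / 2
  for (rho in c(-0.8, -0.3, 0.2, 0.6, 0.95)) {
    f <- scale(rnorm(45))[, 1]
    e <- scale(resid(lm(rnorm(45) ~ f)))[, 1]
    g2 <- rho * f + sqrt(1 - rho^2) * e
    x2 <- rbind(a = f, b = g2)
    colnames(x2) <- paste0("s", 1:45)
    r <- cor(f, g2)
    eg2 <- module_eigengenes(x2, setNames(c(1L, 1L), c("a", "b")))
    expect_equal(eg2$var_explained[["ME1"]], (1 + abs(r)) / 2,
                 tolerance = 1e-8)
  }

  # 50-gene module: matches the first left singular vector of a full SVD
  x50 <- block_expr(50, 0, 45, within = 0.6, seed = 10)[1:50, ]
  labs50 <- setNames(rep(1L, 50), rownames(x50))
  eg50 <- module_eigengenes(x50, labs50)
  z <- t(scale(t(x50)))
  sv <- svd(t(z))
  ref <- sv$u[, 1] / sd(sv$u[, 1])
  if (mean(cor(ref, t(x50))) < 0) ref <- -ref
  expect_equal(unname(eg50$ME[1, ]), ref, tolerance = 1e-8)
  expect_equal(eg50$var_explained[["ME1"]], sv$d[1]^2 / sum(sv$d^2),
               tolerance = 1e-10)

  # sign anchor: mean kME of own members is positive
  expect_gt(mean(cor(eg50$ME[1, ], t(x50))), 0)

  # single-gene module equals the standardized profile
  eg1 <- module_eigengenes(x50[1, , drop = FALSE],
                           setNames(1L, rownames(x50)[1]))
  expect_equal(unname(eg1$ME[1, ]), as.numeric(scale(x50[1, ])),
               tolerance = 1e-10)
})

test_that("eigengene-based merging joins only near-duplicate modules", {
  set.seed(11)
  f1 <- rnorm(45)
  f2 <- 0.97 * f1 + sqrt(1 - 0.97^2) * rnorm(45)  # eigengene cor ~ 0.95+
  f3 <- rnorm(45)                                  # independent
  mk <- function(f, n, pre) {
    out <- t(sapply(1:n, function(i) 0.995 * f + 0.1 * rnorm(45)))
    rownames(out) <- paste0(pre, 1:n); out
  }
  x <- rbind(mk(f1, 20, "a"), mk(f2, 20, "b"), mk(f3, 20, "c"))
  colnames(x) <- paste0("s", 1:45)
  labs <- setNames(rep(1:3, each = 20), rownames(x))
  merged <- merge_modules(x, labs, merge_cut = 0.1, min_size = 20)
  k <- length(unique(merged$labels[merged$labels > 0]))
  expect_equal(k, 2)                 # a and b merge, c stays
  expect_equal(length(unique(merged$labels[1:40])), 1)
  # repeated merge is idempotent and never increases the module count
  again <- merge_modules(x, merged$labels, merge_cut = 0.1, min_size = 20)
  expect_equal(length(unique(again$labels[again$labels > 0])), k)
  expect_identical(unname(again$labels), unname(merged$labels))
  # duplicated module (one gene set split into two labels) collapses
  labs2 <- setNames(c(rep(1L, 10), rep(2L, 10), rep(0L, 40)), rownames(x))
  m2 <- merge_modules(x, labs2, merge_cut = 0.1, min_size = 10)
  expect_equal(length(unique(m2$labels[m2$labels > 0])), 1)
  expect_true(all(m2$labels[21:60] == 0))
})

test_that("module membership is the gene-eigengene correlation", {
  x <- block_expr(30, 10, 45, within = 0.7, seed = 12)
  labs <- setNames(c(rep(1L, 30), rep(2L, 30), rep(0L, 10)), rownames(x))
  eg <- module_eigengenes(x, labs)
  kme <- module_membership(x, eg$ME)
  ref <- cor(t(x), t(eg$ME))
  expect_equal(kme, ref, tolerance = 1e-12)
  # gene identical to its eigengene
  x2 <- rbind(x, me_copy = eg$ME[1, ])
  kme2 <- module_membership(x2, eg$ME)
  expect_equal(kme2["me_copy", "ME1"], 1, tolerance = 1e-10)
  x3 <- rbind(x, me_neg = -eg$ME[1, ])
  expect_equal(module_membership(x3, eg$ME)["me_neg", "ME1"], -1,
               tolerance = 1e-10)
})

test_that("the module pipeline is invariant to gene and sample order", {
  x <- block_expr(55, 40, 45, within = 0.75, seed = 13)
  base <- suppressWarnings(build_modules(x, min_size = 50))
  set.seed(14)
  xg <- x[sample(nrow(x)), ]
  pg <- suppressWarnings(build_modules(xg, min_size = 50))
  # same partition up to label renumbering
  expect_equal(
    mclust::adjustedRandIndex(base$labels[rownames(x)][base$labels[rownames(x)] > 0 | pg$labels[rownames(x)] > 0],
                              pg$labels[rownames(x)][base$labels[rownames(x)] > 0 | pg$labels[rownames(x)] > 0]),
    1)
  xs <- x[, sample(ncol(x))]
  ps <- suppressWarnings(build_modules(xs, min_size = 50))
  expect_identical(ps$labels[names(base$labels)], base$labels)
})
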