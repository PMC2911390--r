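module_data <- function(n_mod = 30, n_bg = 300, n_samples = 50,
                        b = 1, sd = 0.5, mod_prefix = "MOD") {
  a <- rnorm(n_samples)
  genes <- c(sprintf("%s%03d", mod_prefix, seq_len(n_mod)),
             sprintf("BG%03d", seq_len(n_bg)))
  load <- c(rep(b, n_mod), rep(0, n_bg))
  v <- outer(load, a) + matrix(rnorm(length(genes) * n_samples, sd = sd),
                               length(genes))
  dimnames(v) <- list(genes, sprintf("s%03d", seq_len(n_samples)))
  expr_matrix(v - rowMeans(v), scale = "log10_ratio")
}

test_that("correlation matrix matches the pairwise Pearson oracle", {
  set.seed(22)
  m <- random_ratio_matrix(40, 25)
  cc <- correlation_matrix(m)
  expect_equal(cc, t(cc), tolerance = 1e-12)
  expect_equal(unname(diag(cc)), rep(1, 40))
  idx <- cbind(sample(40, 30, TRUE), sample(40, 30, TRUE))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    want <- if (i == j) 1 else
      oracle_pearson(m$values[i, ], m$values[j, ])
    expect_equal(cc[i, j], want, tolerance = 1e-12)
  }
})

test_that("correlation matrix handles identical, negated and flat profiles", {
  x <- c(1, 3, 2, 5, 4)
  v <- rbind(A = x, B = x, C = -x, FLAT = rep(2, 5))
  colnames(v) <- sprintf("s%d", 1:5)
  m <- expr_matrix(v - rowMeans(v), "log10_ratio")
  expect_warning(cc <- correlation_matrix(m), "FLAT")
  expect_equal(cc["A", "B"], 1, tolerance = 1e-12)
  expect_equal(cc["A", "C"], -1, tolerance = 1e-12)
  expect_false("FLAT" %in% rownames(cc))

  expect_error(correlation_matrix(m, genes = "A"), "fewer than 2")
  tiny <- expr_matrix(matrix(1:4, 2, 2,
                             dimnames = list(c("A", "B"), c("s1", "s2"))),
                      "log10_ratio")
  expect_error(correlation_matrix(tiny), "at least 3 samples")
})

test_that("a planted module is recovered exactly at default thresholds", {
  set.seed(23)
  m <- module_data()
  cc <- correlation_matrix(m)
  mod <- find_coherent_module(cc)
  expect_setequal(mod, sprintf("MOD%03d", 1:30))
})

test_that("no module is reported on pure background in most runs", {
  set.seed(24)
  empty <- replicate(60, {
    m <- module_data(n_mod = 0, n_bg = 300)
    length(find_coherent_module(correlation_matrix(m))) == 0
  })
  expect_gte(mean(empty), 0.95)
})

test_that("the largest qualifying module wins", {
  set.seed(25)
  n <- 60
  a1 <- rnorm(n); a2 <- rnorm(n)
  genes <- c(sprintf("BIG%03d", 1:30), sprintf("SML%03d", 1:15),
             sprintf("BG%03d", 1:100))
  load <- rbind(cbind(rep(1, 30), 0), cbind(rep(0, 15), 1),
                matrix(0, 100, 2))
  # within-module r ~ 0.65: each module clears the 0.40 bar but their
  # union (mean r ~ 0.545 * 0.65) cannot, so "largest" decides between
  # the two planted modules alone
  v <- load %*% rbind(a1, a2) +
    matrix(rnorm(length(genes) * n, sd = 0.73), length(genes))
  dimnames(v) <- list(genes, sprintf("s%03d", 1:n))
  m <- expr_matrix(v - rowMeans(v), "log10_ratio")
  mod <- find_coherent_module(correlation_matrix(m))
  expect_setequal(mod, sprintf("BIG%03d", 1:30))
})

test_that("module discovery is invariant to gene and sample order", {
  set.seed(26)
  m <- module_data(n_mod = 20, n_bg = 80, n_samples = 40)
  mod <- find_coherent_module(correlation_matrix(m))

  gperm <- sample(nrow(m$values)); sperm <- sample(ncol(m$values))
  m2 <- expr_matrix(m$values[gperm, sperm], "log10_ratio")
  expect_setequal(find_coherent_module(correlation_matrix(m2)), mod)
})

test_that("returned modules always satisfy the mean pairwise r criterion", {
  set.seed(27)
  for (b in c(0.4, 0.6, 1)) {
    m <- module_data(n_mod = 15, n_bg = 60, n_samples = 30, b = b)
    cc <- correlation_matrix(m)
    mod <- find_coherent_module(cc)
    if (length(mod)) {
      sub <- cc[mod, mod]
      expect_gte(mean(sub[upper.tri(sub)]), 0.40)
    }
  }
})

test_that("module intersection is plain set algebra", {
  expect_setequal(intersect_modules(list(c("a", "b", "c"),
                                         c("b", "c", "d"),
                                         c("b", "c"))),
                  c("b", "c"))
  expect_setequal(intersect_modules(list(c("x", "y"))), c("x", "y"))
  expect_warning(out <- intersect_modules(list("a", "b")), "empty")
  expect_length(out, 0)
})

test_that("down-arm selection applies an inclusive anticorrelation cutoff", {
  up_profile <- c(1, 2, 3, 4, 5)
  boundary <- c(2, 5, 4, 3, 1)         # cor with up_profile = -0.4
  v <- rbind(UPX = up_profile, BOUND = boundary,
             ANTI = -up_profile, NOISE = c(3, 1, 2, 3, 3))
  colnames(v) <- sprintf("s%d", 1:5)
  m <- expr_matrix(v, "log10_ratio")
  down <- select_down_arm(m, "UPX")
  expect_true("ANTI" %in% down)        # r = -1
  expect_false("NOISE" %in% down)

  # the bound is inclusive: a gene sitting exactly at the configured
  # cutoff is selected
  r_bound <- cor(boundary, up_profile)
  cfg <- module_discovery_config(down_arm_max_r = r_bound)
  expect_true("BOUND" %in% select_down_arm(m, "UPX", cfg))
  cfg_tighter <- module_discovery_config(
    down_arm_max_r = r_bound - 1e-12)
  expect_false("BOUND" %in% select_down_arm(m, "UPX", cfg_tighter))
})

test_that("uncorrelated genes are essentially never selected for the down arm", {
  set.seed(28)
  genes <- c("UP01", "UP02", "UP03", sprintf("BG%03d", 1:100))
  a <- rnorm(200)
  v <- rbind(outer(rep(1, 3), a) + matrix(rnorm(600, sd = 0.3), 3),
             matrix(rnorm(100 * 200), 100))
  dimnames(v) <- list(genes, sprintf("s%d", 1:200))
  m <- expr_matrix(v - rowMeans(v), "log10_ratio")
  down <- select_down_arm(m, c("UP01", "UP02", "UP03"))
  expect_length(down, 0)

  expect_error(select_down_arm(m, "ABSENT"), "no up-arm gene")
})

test_that("the full derivation recovers a planted signature", {
  set.seed(29)
  truth <- generate_dataset(synthetic_config(
    up_module_size = 30, down_module_size = 12, n_background_genes = 300,
    n_datasets = 5, seed = 101))
  superset <- c(truth$signature$up_genes, sprintf("BGG%03d", 1:300))
  rep <- build_signature(superset, truth$matrices[1:4],
                         reference = truth$matrices[[5]])
  expect_setequal(rep$up_arm, truth$signature$up_genes)
  expect_true(all(truth$signature$down_genes %in% rep$down_arm))
  expect_length(intersect(rep$up_arm, rep$down_arm), 0)
  expect_s3_class(rep$signature, "two_arm_signature")
})

test_that("a dataset without the module empties the intersection", {
  set.seed(30)
  with_mod <- module_data(n_mod = 20, n_bg = 100, n_samples = 40)
  without <- module_data(n_mod = 20, n_bg = 100, n_samples = 40, b = 0)
  superset <- rownames(with_mod$values)
  expect_error(
    suppressWarnings(build_signature(superset,
                                     list(with_mod, without),
                                     reference = with_mod)),
    "intersection|relaxing")
})

test_that("repeating one dataset gives the same arms as using it once", {
  set.seed(32)
  m <- module_data(n_mod = 20, n_bg = 100, n_samples = 40)
  superset <- rownames(m$values)
  ref <- module_data(n_mod = 20, n_bg = 100, n_samples = 40)
  one <- build_signature(superset, list(m), reference = ref)
  four <- build_signature(superset, list(m, m, m, m), reference = ref)
  expect_setequal(one$up_arm, four$up_arm)
  expect_setequal(one$down_arm, four$down_arm)
})

test_that("module recall rises with strength and falls with noise", {
  set.seed(33)
  recall <- function(b, sd) {
    mean(replicate(30, {
      m <- module_data(n_mod = 20, n_bg = 80, n_samples = 40,
                       b = b, sd = sd)
      mod <- find_coherent_module(correlation_matrix(m))
      length(intersect(mod, sprintf("MOD%03d", 1:20))) / 20
    }))
  }
  grid <- outer(c(0.25, 0.5, 1), c(0.3, 0.5, 0.8),
                Vectorize(function(b, sd) recall(b, sd)))
  # non-decreasing in b (rows), non-increasing in noise sd (columns)
  expect_true(all(apply(grid, 2, function(col) all(diff(col) >= -0.02))))
  expect_true(all(apply(grid, 1, function(row) all(diff(row) <= 0.02))))
})
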