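# Simulator core: initialization, grouping, loss, swap optimization.

test_that("init_genotypes matches marginal targets", {
  # degenerate frequencies
  stats <- make_stats(c("z", "o"), c(0, 1))
  X <- init_genotypes(stats, 50, rng_seed = 1)
  expect_true(all(X[, "z"] == 0L))
  expect_true(all(X[, "o"] == 2L))

  # non-HWE column holds exact genotype counts
  stats2 <- make_stats("d", 0.5, hwe = TRUE, fracs = list(d = c(0.5, 0.0, 0.5)))
  X2 <- init_genotypes(stats2, 100, rng_seed = 2)
  expect_equal(sum(X2[, "d"] == 0L), 50)
  expect_equal(sum(X2[, "d"] == 1L), 0)
  expect_equal(sum(X2[, "d"] == 2L), 50)

  # largest-remainder rounding keeps counts summing to N
  stats3 <- make_stats("r", 0.35, hwe = TRUE,
                       fracs = list(r = c(0.4233, 0.4534, 0.1233)))
  X3 <- init_genotypes(stats3, 997, rng_seed = 3)
  counts <- tabulate(X3[, "r"] + 1L, 3)
  expect_equal(sum(counts), 997)
  expect_true(all(abs(counts - c(0.4233, 0.4534, 0.1233) * 997) <= 1))

  # HWE column: empirical frequency within 4 binomial standard errors
  stats4 <- make_stats("h", 0.3)
  X4 <- init_genotypes(stats4, 10000, rng_seed = 4)
  fhat <- mean(X4[, "h"]) / 2
  expect_lt(abs(fhat - 0.3), 4 * sqrt(0.3 * 0.7 / 20000))

  # deterministic given the seed
  expect_identical(init_genotypes(stats4, 100, rng_seed = 9),
                   init_genotypes(stats4, 100, rng_seed = 9))

  # flagged SNP without fractions is an error
  bad <- summary_stats(data.frame(
    snp_id = "x", effect_allele = "A", other_allele = "G",
    freq = 0.5, hwe_deviates = FALSE
  ))
  bad$hwe_deviates <- TRUE  # bypass constructor to hit the runtime check
  expect_error(init_genotypes(bad, 10, 1), "frac")
})

test_that("build_groups extracts thresholded connected components", {
  snps <- c("A", "B", "C", "D", "E", "F", "G", "H")
  stats <- make_stats(snps, rep(0.4, 8))
  corr <- make_corr(
    c("A", "A", "B", "C", "D", "F"),
    c("B", "C", "C", "D", "E", "G"),
    c(0.5, 0.4, 0.6, 0.3, 0.25, 0.45)
  )
  part <- build_groups(corr, stats, corr_threshold = 0.1)
  expect_length(part$groups, 2)
  expect_setequal(part$groups[[1]]$snp_ids, c("A", "B", "C", "D", "E"))
  expect_setequal(part$groups[[2]]$snp_ids, c("F", "G"))
  expect_equal(part$uncorrelated, "H")
  expect_equal(nrow(part$groups[[1]]$edges), 5)

  # empty table: everything uncorrelated
  empty <- correlation_table(data.frame(snp_a = character(),
                                        snp_b = character(), rho = numeric()))
  p0 <- build_groups(empty, stats, 0.1)
  expect_length(p0$groups, 0)
  expect_setequal(p0$uncorrelated, snps)

  # unknown SNP in the table is rejected
  expect_error(build_groups(make_corr("A", "Z", 0.5), stats, 0.1), "Z")
})

test_that("thresholding agrees with an independent union-find oracle", {
  set.seed(42)
  for (rep in 1:5) {
    snps <- paste0("s", 1:10)
    stats <- make_stats(snps, runif(10, 0.2, 0.5))
    pairs <- t(combn(snps, 2))
    keep <- sample(nrow(pairs), 12)
    rho <- round(runif(12, -0.3, 0.3), 3)
    corr <- make_corr(pairs[keep, 1], pairs[keep, 2], rho)
    thr <- 0.1
    part <- build_groups(corr, stats, thr)

    kept <- abs(rho) >= thr
    comps <- oracle_components(snps, pairs[keep, 1][kept], pairs[keep, 2][kept])
    comps <- Filter(function(m) length(m) > 1, comps)
    got <- lapply(part$groups, function(g) sort(g$snp_ids))
    want <- lapply(unname(comps), sort)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
    # only |rho| >= threshold edges are retained
    for (g in part$groups) {
      expect_true(all(abs(g$edges$rho_target) >= thr))
    }
  }
})

test_that("group_loss implements the mean squared correlation deviation", {
  # realized equal to target on every edge -> zero
  X <- make_X(list(a = c(0L, 1L, 2L, 1L), b = c(0L, 1L, 2L, 1L)))
  g <- list(snp_ids = c("a", "b"),
            edges = data.frame(snp_a = "a", snp_b = "b", rho_target = 1.0))
  expect_equal(group_loss(X, g), 0)

  # single-edge case: loss = (rho_hat - 0)^2 with rho_hat hand-computed
  X2 <- make_X(list(a = c(0L, 1L, 2L, 1L), b = c(2L, 1L, 0L, 1L)))
  g2 <- list(snp_ids = c("a", "b"),
             edges = data.frame(snp_a = "a", snp_b = "b", rho_target = 0))
  rho_hat <- oracle_pearson(c(0, 1, 2, 1), c(2, 1, 0, 1))
  expect_equal(group_loss(X2, g2), rho_hat^2, tolerance = 1e-12)

  # multi-edge: average of squared deviations, against the oracle
  bundle <- small_bundle()
  part <- build_groups(bundle$corr, bundle$stats, 0.1)
  gl <- group_loss(bundle$X_truth, part$groups[[1]])
  expect_equal(gl, oracle_group_loss(bundle$X_truth, part$groups[[1]]$edges),
               tolerance = 1e-12)

  # constant column is an error naming the SNP
  X3 <- make_X(list(a = rep(1L, 4), b = c(0L, 1L, 2L, 1L)))
  expect_error(group_loss(X3, g2), "constant column.*a")
})

test_that("optimize_group preserves marginals and decreases loss monotonically", {
  bundle <- small_bundle()
  part <- build_groups(bundle$corr, bundle$stats, 0.1)
  cfg <- simulation_config(n_samples = 2000, tolerance = 0.001,
                           iteration_limit = 20, seed = 5)
  X0 <- init_genotypes(bundle$stats, 2000, rng_seed = 123)
  g <- part$groups[[1]]
  res <- optimize_group(X0, g, cfg, rng_seed = 77, trace = TRUE)

  # (a) column multisets unchanged
  for (s in colnames(X0)) {
    expect_equal(tabulate(res$X[, s] + 1L, 3), tabulate(X0[, s] + 1L, 3))
  }
  # (c) columns outside the group untouched
  outside <- setdiff(colnames(X0), g$snp_ids)
  expect_identical(res$X[, outside], X0[, outside])

  # (b) accepted-state losses strictly decreasing, and the incremental
  # losses agree with a from-scratch evaluation replayed swap by swap
  tr <- res$report$trace
  expect_gt(nrow(tr), 0)
  expect_true(all(diff(tr$loss) < 0))
  cols <- X0[, g$snp_ids, drop = FALSE]
  diffs <- numeric(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    i <- tr$sample_i[k]
    j <- tr$sample_j[k]
    s <- tr$snp_swap[k]
    tmp <- cols[i, s]
    cols[i, s] <- cols[j, s]
    cols[j, s] <- tmp
    diffs[k] <- abs(tr$loss[k] - oracle_group_loss(cols, g$edges))
  }
  expect_lt(max(diffs), 1e-9)
  # final state equals the replayed state and reported loss
  expect_equal(unname(res$X[, g$snp_ids]), unname(cols))
  expect_equal(res$report$final_loss, oracle_group_loss(res$X, g$edges),
               tolerance = 1e-9)
  expect_equal(res$report$converged, res$report$final_loss <= cfg$tolerance)
  expect_lte(res$report$swaps_accepted, res$report$swaps_attempted)
})

test_that("a group already below tolerance is returned unchanged", {
  X <- make_X(list(a = c(0L, 1L, 2L, 1L, 0L, 2L), b = c(0L, 1L, 2L, 1L, 0L, 2L)))
  rho_now <- cor(X[, "a"], X[, "b"])  # exactly 1
  g <- list(snp_ids = c("a", "b"),
            edges = data.frame(snp_a = "a", snp_b = "b", rho_target = rho_now))
  cfg <- simulation_config(n_samples = 6, tolerance = 0.03, seed = 1)
  res <- optimize_group(X, g, cfg, rng_seed = 1)
  expect_identical(res$X, X)
  expect_equal(res$report$swaps_attempted, 0L)
  expect_equal(res$report$passes, 0L)
  expect_true(res$report$converged)
})

test_that("converged 2-SNP group satisfies the single-edge error bound", {
  spec <- fixture_spec(
    n_samples = 500,
    snps = data.frame(snp_id = c("u", "v"), freq = c(0.4, 0.35)),
    latent_corr = matrix(c(1, 0.7, 0.7, 1), 2, 2), seed = 21
  )
  Xt <- copula_genotypes(spec)
  ss <- compute_summary_stats(Xt)
  target <- ss$corr$rho[1]
  cfg <- simulation_config(n_samples = 500, tolerance = 1e-3, seed = 9)
  res <- simulate_array(ss$stats, ss$corr, cfg)
  expect_true(res$report$groups[[1]]$converged)
  realized <- oracle_pearson(as.numeric(res$X[, "u"]), as.numeric(res$X[, "v"]))
  expect_lte(abs(realized - target), sqrt(1e-3))
})

test_that("non-convergence is reported, not raised", {
  # an impossible target (rho -0.95 between two common SNPs) with a tiny
  # attempt budget: optimizer must return best-so-far with converged FALSE
  stats <- make_stats(c("a", "b"), c(0.5, 0.5))
  corr <- make_corr("a", "b", -0.95)
  cfg <- simulation_config(n_samples = 100, tolerance = 1e-6,
                           iteration_limit = 2, seed = 3)
  res <- simulate_array(stats, corr, cfg)
  g <- res$report$groups[[1]]
  expect_false(g$converged)
  expect_gte(g$final_loss, 0)
  expect_lte(g$swaps_attempted, 2 * 50)
})

test_that("simulate_array pipeline contracts hold", {
  bundle <- small_bundle()
  cfg <- simulation_config(n_samples = 1000, seed = 31)

  # no correlations: output identical to initialization, zero groups
  empty <- correlation_table(data.frame(snp_a = character(),
                                        snp_b = character(), rho = numeric()))
  res0 <- simulate_array(bundle$stats, empty, cfg)
  expect_identical(res0$X, init_genotypes(bundle$stats, 1000,
                                          rng_seed = grsim:::derive_seed(31L, 0L)))
  expect_length(res0$report$groups, 0)

  res <- simulate_array(bundle$stats, bundle$corr, cfg)
  # uncorrelated columns bit-identical to their initialized state
  part <- build_groups(bundle$corr, bundle$stats, cfg$corr_threshold)
  expect_identical(res$X[, part$uncorrelated], res0$X[, part$uncorrelated])

  # marginal conservation across the whole pipeline
  for (s in colnames(res$X)) {
    expect_equal(tabulate(res$X[, s] + 1L, 3), tabulate(res0$X[, s] + 1L, 3))
  }

  # reproducibility: bit-identical matrix and per-group losses
  res2 <- simulate_array(bundle$stats, bundle$corr, cfg)
  expect_identical(res$X, res2$X)
  expect_equal(
    vapply(res$report$groups, `[[`, 0, "final_loss"),
    vapply(res2$report$groups, `[[`, 0, "final_loss")
  )

  # report covers every group with the convergence flag consistent
  for (g in res$report$groups) {
    expect_equal(g$converged, g$final_loss <= cfg$tolerance)
  }
})

test_that("simulation report JSON has the agreed schema", {
  bundle <- small_bundle()
  cfg <- simulation_config(n_samples = 500, seed = 8)
  res <- simulate_array(bundle$stats, bundle$corr, cfg)
  p <- tempfile(fileext = ".json")
  write_simulation_report(res$report, p)
  j <- jsonlite::read_json(p)
  expect_named(j, c("groups", "seed", "elapsed_seconds"))
  expect_equal(j$seed, 8)
  for (g in j$groups) {
    expect_named(g, c("group_index", "snp_ids", "converged", "final_loss",
                      "swaps_accepted", "swaps_attempted", "passes"))
  }
})
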