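# Marginal-preserving genotype simulation. Columns are first generated to
# match the target marginal distributions exactly in distributional form;
# a swap optimizer then permutes values *within* columns -- which cannot
# change any column's genotype counts -- until realized pairwise Pearson
# correlations match their targets to within a loss tolerance.

#' Simulation configuration
#'
#' Bundles the tunable parameters of the simulator. Defaults follow the
#' reference settings: correlation threshold 0.1 (below which pairwise
#' correlations are treated as noise and not targeted), loss tolerance
#' 0.03 on the per-group mean squared correlation deviation, and an
#' iteration limit of 10000 "passes worth" of attempted exchanges per
#' group (the attempt budget is `iteration_limit * floor(N/2)`).
#'
#' @param n_samples number of samples N to simulate (default 5000).
#' @param corr_threshold adjacency threshold on |rho|, in \[0,1\].
#' @param tolerance positive convergence tolerance on the group loss.
#' @param iteration_limit positive integer pass budget per group.
#' @param time_limit_seconds optional wall-clock budget per group.
#' @param seed master RNG seed; all randomness derives from it.
#' @return object of class `grs_simconfig`.
#' @export
simulation_config <- function(n_samples = 5000, corr_threshold = 0.1,
                              tolerance = 0.03, iteration_limit = 10000,
                              time_limit_seconds = NULL, seed = 1) {
  if (!is.numeric(n_samples) || n_samples < 1) stop_input("n_samples must be >= 1")
  if (!is.numeric(corr_threshold) || corr_threshold < 0 || corr_threshold > 1) {
    stop_input("corr_threshold must be in [0,1]")
  }
  if (!is.numeric(tolerance) || tolerance <= 0) stop_input("tolerance must be > 0")
  if (!is.numeric(iteration_limit) || iteration_limit < 1) {
    stop_input("iteration_limit must be >= 1")
  }
  if (!is.null(time_limit_seconds) &&
      (!is.numeric(time_limit_seconds) || time_limit_seconds <= 0)) {
    stop_input("time_limit_seconds must be > 0 when given")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    corr_threshold = as.numeric(corr_threshold),
    tolerance = as.numeric(tolerance),
    iteration_limit = as.integer(iteration_limit),
    time_limit_seconds = time_limit_seconds,
    seed = as.integer(seed)
  ), class = "grs_simconfig")
}

#' Initialize a genotype matrix from marginal targets
#'
#' For a SNP in HWE with frequency f, each entry is the sum of two
#' independent Bernoulli(f) draws (one per chromosome copy). For a SNP
#' flagged as deviating from HWE, the column contains *exactly* the
#' genotype counts implied by its class fractions (largest-remainder
#' rounding so the counts sum to N), in uniformly random order.
#' Deterministic given `rng_seed`.
#'
#' @param stats a [summary_stats()] object.
#' @param n_samples number of samples.
#' @param rng_seed integer seed.
#' @return genotype matrix with sample ids `S1..SN`.
#' @export
init_genotypes <- function(stats, n_samples, rng_seed) {
  stats <- summary_stats(stats)
  n <- as.integer(n_samples)
  if (n < 1) stop_input("n_samples must be >= 1")
  p <- nrow(stats)
  with_seed(rng_seed, {
    X <- matrix(0L, nrow = n, ncol = p)
    for (j in seq_len(p)) {
      if (isTRUE(stats$hwe_deviates[j])) {
        fr <- c(stats$frac0[j], stats$frac1[j], stats$frac2[j])
        if (anyNA(fr)) {
          stop_input("SNP ", stats$snp_id[j],
                     " flagged hwe_deviates but fractions absent")
        }
        counts <- round_counts(fr, n)
        col <- rep(0:2, times = counts)
        X[, j] <- col[sample.int(n)]
      } else {
        f <- stats$freq[j]
        X[, j] <- stats::rbinom(n, 1L, f) + stats::rbinom(n, 1L, f)
      }
    }
    genotype_matrix(X, sample_ids = paste0("S", seq_len(n)),
                    snp_ids = stats$snp_id)
  })
}

#' Partition SNPs into correlated groups
#'
#' Builds the thresholded correlation graph (edge iff `|rho| >=
#' corr_threshold`) and extracts its connected components: each component
#' with at least two members becomes a group carrying its kept edges and
#' their target correlations; SNPs touching no kept edge are
#' "uncorrelated" and bypass the optimizer entirely.
#'
#' @param corr a [correlation_table()].
#' @param stats a [summary_stats()]; every SNP in `corr` must appear here.
#' @param corr_threshold adjacency threshold on |rho|.
#' @return list of class `grs_groups` with components `groups` (each a
#'   list with `snp_ids` and an `edges` data.frame of
#'   `snp_a`/`snp_b`/`rho_target`) and `uncorrelated` (character vector).
#' @export
build_groups <- function(corr, stats, corr_threshold = 0.1) {
  corr <- correlation_table(corr)
  stats <- summary_stats(stats)
  unknown <- setdiff(unique(c(corr$snp_a, corr$snp_b)), stats$snp_id)
  if (length(unknown) > 0) {
    stop_input("correlation table references SNP(s) absent from stats: ",
               paste(unknown, collapse = ", "))
  }
  kept <- corr[abs(corr$rho) >= corr_threshold, , drop = FALSE]
  all_snps <- stats$snp_id
  if (nrow(kept) == 0) {
    return(structure(list(groups = list(), uncorrelated = all_snps),
                     class = "grs_groups"))
  }
  g <- igraph::graph_from_data_frame(
    kept[, c("snp_a", "snp_b")], directed = FALSE,
    vertices = data.frame(name = all_snps)
  )
  comp <- igraph::components(g)
  member <- split(names(comp$membership), comp$membership)
  groups <- list()
  # order groups by the first member's position in stats for determinism
  first_pos <- vapply(member, function(m) min(match(m, all_snps)), numeric(1))
  member <- member[order(first_pos)]
  for (m in member) {
    if (length(m) < 2) next
    in_g <- kept$snp_a %in% m & kept$snp_b %in% m
    edges <- data.frame(snp_a = kept$snp_a[in_g], snp_b = kept$snp_b[in_g],
                        rho_target = kept$rho[in_g], stringsAsFactors = FALSE)
    m_sorted <- all_snps[sort(match(m, all_snps))]
    groups[[length(groups) + 1L]] <- list(snp_ids = m_sorted, edges = edges)
  }
  grouped <- unlist(lapply(groups, `[[`, "snp_ids"))
  structure(list(groups = groups,
                 uncorrelated = setdiff(all_snps, grouped)),
            class = "grs_groups")
}

#' Per-group correlation loss
#'
#' The mean over a group's l kept edges of the squared deviation between
#' the realized Pearson correlation of the two dosage columns and its
#' target: \deqn{loss = \frac{1}{l}\sum_{j=1}^{l} (\hat\rho_j - \rho_j)^2.}
#' Zero iff every edge's realized correlation equals its target.
#'
#' @param X genotype matrix containing the group's columns.
#' @param group one element of [build_groups()]`$groups`.
#' @return nonnegative scalar loss.
#' @export
group_loss <- function(X, group) {
  edges <- group$edges
  if (is.null(edges) || nrow(edges) == 0) stop_input("group has no edges")
  for (s in group$snp_ids) {
    col <- X[, s]
    if (stats::var(as.numeric(col)) == 0) {
      stop_input("constant column in group (correlation undefined) for SNP ", s)
    }
  }
  rho_hat <- vapply(seq_len(nrow(edges)), function(k) {
    stats::cor(X[, edges$snp_a[k]], X[, edges$snp_b[k]])
  }, numeric(1))
  mean((rho_hat - edges$rho_target)^2)
}

# Internal optimizer state over the group's columns: because swaps permute
# values within a column, column means and variances are constants of the
# motion; only the per-edge cross-product sums S_xy change. This makes the
# candidate-loss update O(edges incident to the swapped SNP).
optimize_group_impl <- function(cols, edges, tolerance, iteration_limit,
                                time_limit_seconds, trace = FALSE) {
  n <- nrow(cols)
  h <- ncol(cols)
  l <- nrow(edges)
  snps <- colnames(cols)
  ea <- match(edges$snp_a, snps)
  eb <- match(edges$snp_b, snps)
  tgt <- edges$rho_target

  mu <- unname(colMeans(cols))
  # sample sd via sums of squares; constant throughout
  ss <- unname(colSums(cols^2))
  sdv <- sqrt((ss - n * mu^2) / (n - 1))
  if (any(sdv == 0)) {
    stop_input("constant column in group (correlation undefined) for SNP ",
               snps[which(sdv == 0)[1]])
  }
  sxy <- vapply(seq_len(l), function(k) sum(cols[, ea[k]] * cols[, eb[k]]),
                numeric(1))
  denom <- (n - 1) * sdv[ea] * sdv[eb]
  cross <- n * mu[ea] * mu[eb]
  rho <- (sxy - cross) / denom
  dev2 <- (rho - tgt)^2
  loss <- sum(dev2) / l

  # edges incident to each SNP column
  incident <- lapply(seq_len(h), function(j) which(ea == j | eb == j))

  start <- proc.time()[["elapsed"]]
  max_attempts <- as.double(iteration_limit) * (n %/% 2L)
  attempts <- 0
  accepted <- 0
  passes <- 0L
  trace_rows <- if (trace) list() else NULL
  n_pairs_half <- n %/% 2L

  # ordered (keep, swap) SNP pairs within the group
  op <- which(outer(seq_len(h), seq_len(h), "!="), arr.ind = TRUE)
  done <- loss <= tolerance

  while (!done) {
    passes <- passes + 1L
    for (pi in sample.int(nrow(op))) {
      if (done) break
      s_swap <- op[pi, 1L]
      inc <- incident[[s_swap]]
      if (length(inc) == 0) next  # swapping this column cannot change the loss
      perm <- sample.int(n)
      xs <- cols[, s_swap]
      for (q in seq_len(n_pairs_half)) {
        i <- perm[2L * q - 1L]
        jj <- perm[2L * q]
        attempts <- attempts + 1
        xi <- xs[i]
        xj <- xs[jj]
        if (xi != xj) {
          d <- as.double(xj - xi)
          new_loss <- loss
          new_sxy <- sxy[inc]
          new_dev2 <- dev2[inc]
          for (t in seq_along(inc)) {
            k <- inc[t]
            other <- if (ea[k] == s_swap) eb[k] else ea[k]
            ns <- sxy[k] + d * (cols[i, other] - cols[jj, other])
            nr <- (ns - cross[k]) / denom[k]
            nd <- (nr - tgt[k])^2
            new_sxy[t] <- ns
            new_dev2[t] <- nd
            new_loss <- new_loss + (nd - dev2[k]) / l
          }
          if (new_loss < loss) {
            xs[i] <- xj
            xs[jj] <- xi
            sxy[inc] <- new_sxy
            dev2[inc] <- new_dev2
            loss <- new_loss
            accepted <- accepted + 1
            if (trace) {
              trace_rows[[length(trace_rows) + 1L]] <-
                c(attempts, s_swap, i, jj, loss)
            }
            if (loss <= tolerance) { done <- TRUE }
          }
        }
        if (attempts >= max_attempts) { done <- TRUE }
        if (!is.null(time_limit_seconds) &&
            proc.time()[["elapsed"]] - start > time_limit_seconds) {
          done <- TRUE
        }
        if (done) break
      }
      cols[, s_swap] <- xs
      if (done) break
    }
    if (loss <= tolerance) done <- TRUE
  }

  report <- list(
    converged = loss <= tolerance,
    final_loss = loss,
    swaps_accepted = as.integer(accepted),
    swaps_attempted = as.integer(attempts),
    passes = passes
  )
  if (trace) {
    tr <- do.call(rbind, trace_rows)
    report$trace <- if (is.null(tr)) {
      data.frame(attempt = integer(), snp_swap = character(),
                 sample_i = integer(), sample_j = integer(), loss = numeric())
    } else {
      data.frame(attempt = as.integer(tr[, 1]), snp_swap = snps[tr[, 2]],
                 sample_i = as.integer(tr[, 3]), sample_j = as.integer(tr[, 4]),
                 loss = tr[, 5])
    }
  }
  list(cols = cols, report = report)
}

#' Optimize one correlated group by marginal-preserving swaps
#'
#' One pass visits every ordered SNP pair (s_keep, s_swap) of the group in
#' random order; for each pair a fresh random permutation of samples is
#' drawn and its adjacent disjoint sample pairs are walked. For each
#' sample pair the two samples' values of the *swapped* SNP's column are
#' exchanged; the exchange is kept iff the group loss strictly decreases,
#' else reverted. Stops as soon as the loss reaches the tolerance, the
#' attempt budget `iteration_limit * floor(N/2)` is exhausted, or the time
#' limit expires. Column genotype counts are invariant by construction;
#' columns outside the group are untouched; accepted-state losses are
#' strictly decreasing.
#'
#' @param X genotype matrix.
#' @param group one element of [build_groups()]`$groups` (>= 2 SNPs, >= 1
#'   edge).
#' @param config a [simulation_config()].
#' @param rng_seed integer seed for this group's RNG stream.
#' @param trace if TRUE the report carries a data.frame of accepted swaps
#'   (attempt index, swapped SNP, sample pair, loss after) for
#'   instrumentation.
#' @return list with `X` (updated matrix) and `report` (per-group
#'   convergence record).
#' @export
optimize_group <- function(X, group, config, rng_seed, trace = FALSE) {
  X <- genotype_matrix(X)
  if (length(group$snp_ids) < 2 || nrow(group$edges) < 1) {
    stop_input("group must have >= 2 SNPs and >= 1 edge")
  }
  missing_snp <- setdiff(group$snp_ids, colnames(X))
  if (length(missing_snp) > 0) {
    stop_input("group SNP(s) not in matrix: ", paste(missing_snp, collapse = ", "))
  }
  cols <- X[, group$snp_ids, drop = FALSE]
  storage.mode(cols) <- "double"
  res <- with_seed(rng_seed, {
    optimize_group_impl(cols, group$edges, config$tolerance,
                        config$iteration_limit, config$time_limit_seconds,
                        trace = trace)
  })
  X[, group$snp_ids] <- as.integer(res$cols)
  list(X = X, report = res$report)
}

#' Simulate a genotype array from summary statistics
#'
#' The full pipeline: initialize columns from the marginal targets
#' ([init_genotypes()]), partition correlated SNPs ([build_groups()]),
#' then optimize each group independently ([optimize_group()]) with an
#' RNG substream derived from `(seed, group_index)` so results do not
#' depend on group processing order. Uncorrelated columns are exactly the
#' initialized columns. Deterministic given `config$seed`.
#'
#' @param stats a [summary_stats()].
#' @param corr a [correlation_table()]; every SNP must appear in `stats`.
#' @param config a [simulation_config()].
#' @return list with `X` (simulated genotype matrix) and `report` (class
#'   `grs_simreport`: per-group records, seed, elapsed seconds).
#' @export
simulate_array <- function(stats, corr, config = simulation_config()) {
  stopifnot(inherits(config, "grs_simconfig"))
  t0 <- proc.time()[["elapsed"]]
  stats <- summary_stats(stats)
  corr <- correlation_table(corr)
  part <- build_groups(corr, stats, config$corr_threshold)
  X <- init_genotypes(stats, config$n_samples, rng_seed = derive_seed(config$seed, 0L))
  group_reports <- list()
  for (gi in seq_along(part$groups)) {
    g <- part$groups[[gi]]
    res <- optimize_group(X, g, config, rng_seed = derive_seed(config$seed, gi))
    X <- res$X
    rep_g <- res$report
    rep_g$group_index <- gi
    rep_g$snp_ids <- g$snp_ids
    group_reports[[gi]] <- rep_g[c("group_index", "snp_ids", "converged",
                                   "final_loss", "swaps_accepted",
                                   "swaps_attempted", "passes")]
  }
  report <- structure(list(
    groups = group_reports,
    seed = config$seed,
    elapsed_seconds = proc.time()[["elapsed"]] - t0
  ), class = "grs_simreport")
  list(X = X, report = report)
}

#' Write a simulation report as JSON
#'
#' @param report the `report` component of [simulate_array()].
#' @param path output path.
#' @export
write_simulation_report <- function(report, path) {
  out <- list(
    groups = lapply(report$groups, function(g) {
      list(group_index = g$group_index, snp_ids = g$snp_ids,
           converged = g$converged, final_loss = g$final_loss,
           swaps_accepted = g$swaps_accepted,
           swaps_attempted = g$swaps_attempted, passes = g$passes)
    }),
    seed = report$seed,
    elapsed_seconds = report$elapsed_seconds
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.grs_simreport <- function(x, ...) {
  cat("Genotype simulation report (seed ", x$seed, ", ",
      sprintf("%.2f", x$elapsed_seconds), " s)\n", sep = "")
  if (length(x$groups) == 0) {
    cat("  no correlated groups\n")
  }
  for (g in x$groups) {
    cat(sprintf("  group %d [%s]: %s, loss %.5g, %d/%d swaps accepted, %d passes\n",
                g$group_index, paste(g$snp_ids, collapse = ","),
                if (g$converged) "converged" else "NOT converged",
                g$final_loss, g$swaps_accepted, g$swaps_attempted, g$passes))
  }
  invisible(x)
}
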