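# Independent oracles, deliberately written from first principles and not
# sharing code with the package internals they check.

# Textbook Pearson r: covariance over product of standard deviations,
# computed from raw sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  sx <- sqrt(sum((x - mx)^2) / (n - 1))
  sy <- sqrt(sum((y - my)^2) / (n - 1))
  sxy / (sx * sy)
}

# O(n^2) pairwise AUC: fraction of (case, control) pairs where the case
# outscores the control, ties counted 1/2.
oracle_auc <- function(cases, controls) {
  tot <- 0
  for (a in cases) {
    for (b in controls) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(cases) * length(controls))
}

# Union-find connected components over an edge list of node name pairs.
oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k])
    rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  split(nodes, roots)
}

# Trapezoidal integral of a curve given as (x, y) points.
oracle_trapz <- function(x, y) {
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# From-scratch Eq.-style group loss: mean over edges of squared deviation
# of cor() from target, no incremental state.
oracle_group_loss <- function(X, edges) {
  devs <- mapply(function(a, b, t) {
    (stats::cor(as.numeric(X[, a]), as.numeric(X[, b])) - t)^2
  }, edges$snp_a, edges$snp_b, edges$rho_target)
  mean(devs)
}

# Naive per-sample GRS: loop over samples and model rows, no matrix
# algebra, enumerating all satisfied interaction entries and taking the
# minimum rank.
oracle_grs <- function(X, model, allele_map) {
  n <- nrow(X)
  lin <- numeric(n)
  inter <- numeric(n)
  ranks <- rep(NA_integer_, n)
  pred_ok <- function(x, p) {
    switch(p, eq0 = x == 0, eq1 = x == 1, eq2 = x == 2,
           ge1 = x >= 1, ge2 = x >= 2)
  }
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(model$linear))) {
      s <- model$linear$snp_id[r]
      am <- allele_map[allele_map$snp_id == s, ]
      x <- X[i, s]
      if (model$linear$effect_allele[r] == am$other_allele) x <- 2 - x
      lin[i] <- lin[i] + model$linear$weight[r] * x
    }
    it <- model$interactions
    satisfied <- integer(0)
    for (k in seq_len(nrow(it))) {
      xa <- X[i, it$snp_a[k]]
      xb <- X[i, it$snp_b[k]]
      ama <- allele_map[allele_map$snp_id == it$snp_a[k], ]
      amb <- allele_map[allele_map$snp_id == it$snp_b[k], ]
      la <- model$linear[model$linear$snp_id == it$snp_a[k], ]
      lb <- model$linear[model$linear$snp_id == it$snp_b[k], ]
      if (la$effect_allele == ama$other_allele) xa <- 2 - xa
      if (lb$effect_allele == amb$other_allele) xb <- 2 - xb
      if (pred_ok(xa, it$predicate_a[k]) && pred_ok(xb, it$predicate_b[k])) {
        satisfied <- c(satisfied, k)
      }
    }
    if (length(satisfied) > 0) {
      best <- satisfied[which.min(it$rank[satisfied])]
      inter[i] <- it$weight[best]
      ranks[i] <- it$rank[best]
    }
  }
  list(linear = lin, interaction = inter, total = lin + inter, ranks = ranks)
}
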