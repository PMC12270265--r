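# Evaluation battery for comparing real against simulated arrays/scores:
# bootstrap distribution summaries, ROC/AUC, and 2-component PCA
# projections.

#' Summarize a score distribution with bootstrap confidence intervals
#'
#' Sample mean, standard deviation (n-1 denominator) and median, with
#' percentile-bootstrap (2.5/97.5) confidence intervals for the mean and
#' sd over `n_boot` resamples. Deterministic given `seed`.
#'
#' @param scores numeric vector, length >= 2.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @return list of class `grs_summary`: `mean`, `sd`, `median`, `ci_mean`,
#'   `ci_sd` (each a `c(lo, hi)` pair), `n`, `n_boot`, `seed`.
#' @export
summarize_scores <- function(scores, n_boot = 1000, seed = 1) {
  scores <- as.numeric(scores)
  n <- length(scores)
  if (n < 2) stop_input("need at least 2 scores to summarize (n = ", n, ")")
  if (n_boot < 1) stop_input("n_boot must be >= 1")
  m <- mean(scores)
  s <- stats::sd(scores)
  med <- stats::median(scores)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      x <- scores[sample.int(n, n, replace = TRUE)]
      c(mean(x), stats::sd(x))
    }, numeric(2))
  })
  ci_mean <- unname(stats::quantile(boots[1, ], c(0.025, 0.975), type = 7))
  ci_sd <- unname(stats::quantile(boots[2, ], c(0.025, 0.975), type = 7))
  structure(list(mean = m, sd = s, median = med,
                 ci_mean = ci_mean, ci_sd = ci_sd,
                 n = n, n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "grs_summary")
}

#' ROC curve and AUC for case vs control scores
#'
#' The curve sweeps all distinct score thresholds (predicting "case" for
#' score >= threshold); the AUC is the trapezoidal integral, which with
#' ties counted 1/2 equals the Mann-Whitney U statistic divided by
#' `n_case * n_control` -- the probability a random case outscores a
#' random control.
#'
#' @param case_scores,control_scores nonempty numeric vectors.
#' @return list with `curve` (data.frame of `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(case_scores, control_scores) {
  case_scores <- as.numeric(case_scores)
  control_scores <- as.numeric(control_scores)
  if (length(case_scores) == 0 || length(control_scores) == 0) {
    stop_input("case and control score vectors must be nonempty")
  }
  n1 <- length(case_scores)
  n0 <- length(control_scores)
  thr <- sort(unique(c(case_scores, control_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(case_scores >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(control_scores >= t) / n0, numeric(1))
  curve <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  # Mann-Whitney with midranks: exact, tie-aware
  r <- rank(c(case_scores, control_scores), ties.method = "average")
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(curve = curve, auc = auc)
}

#' Project two genotype matrices onto two principal components
#'
#' Columns are mean-centered, not variance-scaled. `mode = "separate"`
#' fits a PCA on each matrix independently (axes are then not directly
#' comparable between the two); `mode = "joint"` fits one PCA on the
#' row-concatenation and projects both matrices through it. Each
#' component's loading vector is oriented so its largest-magnitude
#' element is positive, making output signs deterministic. Constant
#' columns simply contribute zero variance.
#'
#' @param X_a,X_b genotype matrices with identical SNP columns in
#'   identical order.
#' @param mode `"separate"` or `"joint"`.
#' @return list with `proj_a`, `proj_b` (n x 2 matrices of scores),
#'   `loadings_a`, `loadings_b` (p x 2; identical in joint mode), `mode`.
#' @export
pca_compare <- function(X_a, X_b, mode = c("separate", "joint")) {
  mode <- match.arg(mode)
  X_a <- genotype_matrix(X_a)
  X_b <- genotype_matrix(X_b)
  if (!identical(colnames(X_a), colnames(X_b))) {
    stop_input("the two matrices must have the same SNP columns in the same order")
  }
  fit2 <- function(M) {
    Mc <- scale(M, center = TRUE, scale = FALSE)
    sv <- svd(Mc, nu = 0, nv = min(2L, ncol(Mc)))
    V <- sv$v
    if (ncol(V) < 2) V <- cbind(V, 0)
    for (k in 1:2) {
      jmax <- which.max(abs(V[, k]))
      if (V[jmax, k] < 0) V[, k] <- -V[, k]
    }
    list(V = V, center = attr(Mc, "scaled:center"))
  }
  project <- function(M, fit) {
    sweep(M, 2, fit$center) %*% fit$V
  }
  if (mode == "separate") {
    fa <- fit2(X_a)
    fb <- fit2(X_b)
    pa <- project(X_a, fa)
    pb <- project(X_b, fb)
    la <- fa$V
    lb <- fb$V
  } else {
    fj <- fit2(rbind(X_a, X_b))
    pa <- project(X_a, fj)
    pb <- project(X_b, fj)
    la <- lb <- fj$V
  }
  colnames(pa) <- colnames(pb) <- c("PC1", "PC2")
  rownames(la) <- rownames(lb) <- colnames(X_a)
  colnames(la) <- colnames(lb) <- c("PC1", "PC2")
  list(proj_a = pa, proj_b = pb, loadings_a = la, loadings_b = lb, mode = mode)
}

#' @export
print.grs_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean %.4g (%.4g-%.4g), sd %.4g (%.4g-%.4g), median %.4g\n",
              x$n, x$mean, x$ci_mean[1], x$ci_mean[2],
              x$sd, x$ci_sd[1], x$ci_sd[2], x$median))
  invisible(x)
}
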