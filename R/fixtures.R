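# Ground-truth fixture generator: correlated genotype arrays with known
# frequencies and latent LD structure via a Gaussian copula on haplotype
# indicators. Two independent latent multivariate-normal draws per sample
# (one per chromosome copy) are thresholded at the standard-normal
# quantile of (1 - freq); the dosage is the sum of the two indicators, so
# HWE holds by construction for non-flagged SNPs. This stands in for real
# reference arrays so the whole pipeline is testable without external
# data.

#' Fixture specification
#'
#' @param n_samples number of samples to draw.
#' @param snps data.frame with columns `snp_id`, `freq`, and optionally
#'   `effect_allele`, `other_allele`, `frac0`, `frac1`, `frac2` (non-`NA`
#'   fractions flag a SNP as HWE-deviating: its column is generated by
#'   exact counts, breaking that SNP's latent correlation).
#' @param latent_corr symmetric unit-diagonal correlation matrix of the
#'   latent haplotype normals (p x p, SNP order as in `snps`).
#' @param grs_model optional [grs_model()] bundled with the fixture.
#' @param seed RNG seed.
#' @param case_shift optional additive shift applied to `case_snps`
#'   frequencies to create a "case" population.
#' @param case_snps SNP ids to shift when `case_shift` is given.
#' @return object of class `grs_fixturespec`.
#' @export
fixture_spec <- function(n_samples, snps, latent_corr, grs_model = NULL,
                         seed = 1, case_shift = NULL, case_snps = NULL) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "freq") %in% names(snps))) {
    stop_input("snps must have columns snp_id and freq")
  }
  p <- nrow(snps)
  if (!"effect_allele" %in% names(snps)) snps$effect_allele <- rep("A", p)
  if (!"other_allele" %in% names(snps)) snps$other_allele <- rep("G", p)
  for (fc in c("frac0", "frac1", "frac2")) {
    if (!fc %in% names(snps)) snps[[fc]] <- NA_real_
  }
  latent_corr <- as.matrix(latent_corr)
  if (nrow(latent_corr) != p || ncol(latent_corr) != p) {
    stop_input("latent_corr must be ", p, " x ", p)
  }
  if (max(abs(latent_corr - t(latent_corr))) > 1e-12 ||
      max(abs(diag(latent_corr) - 1)) > 1e-12) {
    stop_input("latent_corr must be symmetric with unit diagonal")
  }
  off <- latent_corr
  diag(off) <- 0
  correlated <- apply(off != 0, 1, any)
  bad <- correlated & (snps$freq <= 0 | snps$freq >= 1)
  if (any(bad)) {
    stop_input("SNP(s) with nonzero latent correlation need freq in (0,1): ",
               paste(snps$snp_id[bad], collapse = ", "))
  }
  structure(list(n_samples = as.integer(n_samples), snps = snps,
                 latent_corr = latent_corr, grs_model = grs_model,
                 seed = as.integer(seed), case_shift = case_shift,
                 case_snps = case_snps),
            class = "grs_fixturespec")
}

#' Draw a ground-truth genotype matrix from a Gaussian copula
#'
#' See the module description: per sample, two independent latent MVN
#' vectors with correlation `latent_corr` are thresholded at
#' `qnorm(1 - freq)` per SNP to yield two haplotype indicators whose sum
#' is the dosage. SNPs with explicit genotype-class fractions are instead
#' generated by exact counts in random order (their latent correlation is
#' deliberately broken). Deterministic given `spec$seed`.
#'
#' @param spec a [fixture_spec()].
#' @return genotype matrix (`n_samples` x p).
#' @export
copula_genotypes <- function(spec) {
  stopifnot(inherits(spec, "grs_fixturespec"))
  n <- spec$n_samples
  p <- nrow(spec$snps)
  sig <- spec$latent_corr
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(sig + diag(1e-8, p)), error = function(e) NULL)
    if (is.null(ch)) stop_input("latent_corr is not positive semi-definite (after 1e-8 jitter)")
  }
  thr <- stats::qnorm(1 - spec$snps$freq)
  with_seed(spec$seed, {
    z1 <- matrix(stats::rnorm(n * p), n, p) %*% ch
    z2 <- matrix(stats::rnorm(n * p), n, p) %*% ch
    hap1 <- sweep(z1, 2, thr, ">")
    hap2 <- sweep(z2, 2, thr, ">")
    X <- hap1 + hap2
    storage.mode(X) <- "integer"
    nonhwe <- which(!is.na(spec$snps$frac0))
    for (j in nonhwe) {
      fr <- c(spec$snps$frac0[j], spec$snps$frac1[j], spec$snps$frac2[j])
      counts <- round_counts(fr, n)
      col <- rep(0:2, times = counts)
      X[, j] <- col[sample.int(n)]
    }
    genotype_matrix(X, sample_ids = paste0("T", seq_len(n)),
                    snp_ids = spec$snps$snp_id)
  })
}

#' Default GRS model over a set of SNPs
#'
#' A reproducible stand-in model for fixtures: positive weights drawn
#' uniformly on (0.1, 1) for every SNP, plus `n_interactions` ranked
#' pairwise entries over the last SNPs mimicking a heterozygote-pair and
#' a carrier/non-carrier condition. Effect alleles are taken from the
#' stats table, so scoring needs no flipping.
#'
#' @param stats a [summary_stats()].
#' @param n_interactions number of interaction entries (0, 1 or 2).
#' @param seed RNG seed for the weights.
#' @return a [grs_model()].
#' @export
default_grs_model <- function(stats, n_interactions = 2, seed = 1) {
  stats <- summary_stats(stats)
  p <- nrow(stats)
  w <- with_seed(seed, round(stats::runif(p, 0.1, 1), 4))
  linear <- data.frame(snp_id = stats$snp_id,
                       effect_allele = stats$effect_allele,
                       weight = w, stringsAsFactors = FALSE)
  interactions <- NULL
  if (n_interactions > 0) {
    if (p < 2) stop_input("need >= 2 SNPs for interaction entries")
    a <- stats$snp_id[p - 1]
    b <- stats$snp_id[p]
    pool <- data.frame(
      rank = 1:2, snp_a = a, predicate_a = c("eq1", "ge1"),
      snp_b = b, predicate_b = c("eq1", "eq0"),
      weight = c(1.0, 0.5), stringsAsFactors = FALSE
    )
    interactions <- pool[seq_len(min(n_interactions, 2)), , drop = FALSE]
  }
  grs_model(linear, interactions)
}

#' The default fixture specification
#'
#' The standard end-to-end test world: 8 SNPs -- one 4-SNP correlated
#' block with latent correlations 0.4-0.6, one 2-SNP block at 0.5, and
#' two independent SNPs -- allele frequencies between 0.2 and 0.5,
#' N = 2000 samples, seed 7.
#'
#' @param n_samples number of samples (default 2000).
#' @param seed RNG seed (default 7).
#' @return a [fixture_spec()].
#' @export
default_fixture_spec <- function(n_samples = 2000, seed = 7) {
  snps <- data.frame(
    snp_id = paste0("rs", 1:8),
    freq = c(0.30, 0.40, 0.25, 0.35, 0.50, 0.45, 0.20, 0.30),
    effect_allele = c("A", "C", "G", "T", "A", "C", "G", "T"),
    other_allele = c("G", "T", "A", "C", "G", "T", "A", "C"),
    stringsAsFactors = FALSE
  )
  sig <- diag(8)
  block1 <- matrix(c(
    1.00, 0.50, 0.40, 0.45,
    0.50, 1.00, 0.60, 0.40,
    0.40, 0.60, 1.00, 0.50,
    0.45, 0.40, 0.50, 1.00
  ), 4, 4)
  sig[1:4, 1:4] <- block1
  sig[5:6, 5:6] <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  fixture_spec(n_samples = n_samples, snps = snps, latent_corr = sig,
               seed = seed, case_shift = 0.15,
               case_snps = paste0("rs", 1:6))
}

#' Build a complete fixture bundle
#'
#' Draws the ground-truth array from the copula, computes its *realized*
#' summary statistics (the simulator's contract is to match given
#' statistics, not to invert the copula), and attaches a GRS model
#' (supplied or the [default_grs_model()]).
#'
#' @param spec a [fixture_spec()] (default [default_fixture_spec()]).
#' @param hwe_alpha significance level of the HWE flagging test.
#' @return list with `X_truth`, `stats`, `corr`, `model`.
#' @export
build_fixture_bundle <- function(spec = default_fixture_spec(), hwe_alpha = 0.05) {
  stopifnot(inherits(spec, "grs_fixturespec"))
  X_truth <- copula_genotypes(spec)
  ss <- compute_summary_stats(X_truth, hwe_alpha = hwe_alpha,
                              effect_alleles = spec$snps$effect_allele,
                              other_alleles = spec$snps$other_allele)
  model <- spec$grs_model
  if (is.null(model)) {
    model <- default_grs_model(ss$stats, n_interactions = 2,
                               seed = derive_seed(spec$seed, 999L))
  }
  list(X_truth = X_truth, stats = ss$stats, corr = ss$corr, model = model)
}

#' Shift a fixture into its "case" population
#'
#' Applies the spec's `case_shift` additively to the frequencies of
#' `case_snps` (clamped to (0.01, 0.99)), keeping everything else equal.
#' With the shift raising effect-allele frequencies of weighted SNPs,
#' scores of the case population stochastically dominate the controls.
#'
#' @param spec a [fixture_spec()] with `case_shift` set.
#' @param seed optional seed for the case draw (default `spec$seed + 1`).
#' @return a new [fixture_spec()].
#' @export
case_fixture_spec <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "grs_fixturespec"))
  if (is.null(spec$case_shift)) stop_input("fixture spec has no case_shift")
  snps <- spec$snps
  idx <- match(spec$case_snps, snps$snp_id)
  if (anyNA(idx)) {
    stop_input("case_snps not in fixture: ",
               paste(spec$case_snps[is.na(idx)], collapse = ", "))
  }
  snps$freq[idx] <- pmin(pmax(snps$freq[idx] + spec$case_shift, 0.01), 0.99)
  fixture_spec(n_samples = spec$n_samples, snps = snps,
               latent_corr = spec$latent_corr, grs_model = spec$grs_model,
               seed = if (is.null(seed)) spec$seed + 1L else as.integer(seed),
               case_shift = NULL, case_snps = NULL)
}
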