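# Summary-statistics containers and their computation from genotype
# matrices: per-SNP allele frequencies, Hardy-Weinberg assessment with
# observed genotype-class fractions for deviating SNPs, and pairwise
# Pearson correlations of dosage columns.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a per-SNP summary-statistics table
#'
#' Holds the marginal targets the simulator must reproduce: for every SNP
#' the frequency `freq` of the allele coded as dosage 2, whether the SNP
#' deviates from Hardy-Weinberg equilibrium (HWE), and -- for deviating
#' SNPs -- the observed genotype-class fractions `frac0`, `frac1`, `frac2`.
#' For SNPs in HWE the implied fractions are \eqn{(1-f)^2, 2f(1-f), f^2}.
#'
#' @param records data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `freq`, `hwe_deviates`, and (optionally, `NA` for
#'   SNPs in HWE) `frac0`, `frac1`, `frac2`.
#' @return An object of class `grs_sumstats` (a validated data.frame).
#' @export
summary_stats <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("snp_id", "effect_allele", "other_allele", "freq", "hwe_deviates")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop_input("summary stats missing columns: ", paste(missing_cols, collapse = ", "))
  }
  for (fc in c("frac0", "frac1", "frac2")) {
    if (!fc %in% names(records)) records[[fc]] <- NA_real_
  }
  records <- records[, c(needed, "frac0", "frac1", "frac2")]
  records$snp_id <- as.character(records$snp_id)
  records$effect_allele <- as.character(records$effect_allele)
  records$other_allele <- as.character(records$other_allele)
  records$freq <- as.numeric(records$freq)
  records$hwe_deviates <- as.logical(records$hwe_deviates)

  if (anyDuplicated(records$snp_id)) {
    stop_input("duplicate snp_id in summary stats: ",
               paste(unique(records$snp_id[duplicated(records$snp_id)]), collapse = ", "))
  }
  bad_allele <- !(records$effect_allele %in% VALID_ALLELES) |
    !(records$other_allele %in% VALID_ALLELES)
  if (any(bad_allele)) {
    stop_input("invalid allele (must be one of A/C/G/T) for SNP(s): ",
               paste(records$snp_id[bad_allele], collapse = ", "))
  }
  bad_freq <- is.na(records$freq) | records$freq < 0 | records$freq > 1
  if (any(bad_freq)) {
    stop_input("freq outside [0,1] for SNP(s): ",
               paste(records$snp_id[bad_freq], collapse = ", "))
  }
  dev <- which(records$hwe_deviates)
  for (i in dev) {
    fr <- c(records$frac0[i], records$frac1[i], records$frac2[i])
    if (anyNA(fr)) {
      stop_input("SNP ", records$snp_id[i],
                 " flagged as HWE-deviating but frac0/frac1/frac2 absent")
    }
    if (any(fr < 0 | fr > 1)) {
      stop_input("genotype-class fraction outside [0,1] for SNP ", records$snp_id[i])
    }
    if (abs(sum(fr) - 1) > 1e-9) {
      stop_input("frac0+frac1+frac2 != 1 for SNP ", records$snp_id[i],
                 " (sum = ", format(sum(fr), digits = 12), ")")
    }
    implied <- (fr[2] + 2 * fr[3]) / 2
    if (abs(implied - records$freq[i]) > 1e-9) {
      stop_input("fractions inconsistent with freq for SNP ", records$snp_id[i],
                 ": (frac1 + 2*frac2)/2 = ", format(implied, digits = 12),
                 " but freq = ", format(records$freq[i], digits = 12))
    }
  }
  rownames(records) <- NULL
  class(records) <- c("grs_sumstats", "data.frame")
  records
}

#' Construct a pairwise SNP correlation table
#'
#' Target Pearson correlations \eqn{\rho} between dosage columns; these are
#' the values the swap optimizer drives the simulated array towards. Each
#' unordered pair appears at most once, self-pairs are rejected.
#'
#' @param entries data.frame with columns `snp_a`, `snp_b`, `rho`.
#' @return An object of class `grs_corrtable` (a validated data.frame).
#' @export
correlation_table <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  if (nrow(entries) == 0) {
    entries <- data.frame(snp_a = character(), snp_b = character(),
                          rho = numeric(), stringsAsFactors = FALSE)
  }
  needed <- c("snp_a", "snp_b", "rho")
  if (!all(needed %in% names(entries))) {
    stop_input("correlation table must have columns snp_a, snp_b, rho")
  }
  entries <- entries[, needed]
  entries$snp_a <- as.character(entries$snp_a)
  entries$snp_b <- as.character(entries$snp_b)
  entries$rho <- as.numeric(entries$rho)
  self <- entries$snp_a == entries$snp_b
  if (any(self)) {
    stop_input("self-pair in correlation table: ",
               paste(entries$snp_a[self], collapse = ", "))
  }
  bad <- is.na(entries$rho) | abs(entries$rho) > 1
  if (any(bad)) {
    stop_input("rho outside [-1,1] for pair(s): ",
               paste(entries$snp_a[bad], entries$snp_b[bad], sep = "-", collapse = ", "))
  }
  key <- ifelse(entries$snp_a < entries$snp_b,
                paste(entries$snp_a, entries$snp_b, sep = "\r"),
                paste(entries$snp_b, entries$snp_a, sep = "\r"))
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop_input("duplicate unordered pair in correlation table: ",
               gsub("\r", "-", d, fixed = TRUE))
  }
  rownames(entries) <- NULL
  class(entries) <- c("grs_corrtable", "data.frame")
  entries
}

#' Construct a genotype dosage matrix
#'
#' An `N x p` integer matrix over \{0,1,2\}: rows are samples, columns are
#' SNPs, entries count copies of the SNP's "2"-coded allele. Represented as
#' a plain integer matrix with `rownames` = sample ids and `colnames` =
#' SNP ids, so the usual matrix tooling applies.
#'
#' @param values numeric/integer matrix with entries in \{0,1,2\}.
#' @param sample_ids,snp_ids unique identifier vectors; taken from
#'   `dimnames(values)` when omitted.
#' @return Validated integer matrix with dimnames set.
#' @export
genotype_matrix <- function(values, sample_ids = rownames(values),
                            snp_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (is.null(snp_ids)) stop_input("snp_ids required for a genotype matrix")
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(values) || length(snp_ids) != ncol(values)) {
    stop_input("sample_ids/snp_ids lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) stop_input("duplicate sample_ids")
  if (anyDuplicated(snp_ids)) stop_input("duplicate snp_ids")
  bad <- which(is.na(values) | !(values == 0 | values == 1 | values == 2))
  if (length(bad) > 0) {
    b <- bad[1]
    i <- ((b - 1) %% nrow(values)) + 1
    j <- ((b - 1) %/% nrow(values)) + 1
    stop_input("genotype value not in {0,1,2} at SNP ", snp_ids[j],
               ", sample ", sample_ids[i])
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, snp_ids)
  values
}

# Chi-square goodness-of-fit test of observed genotype counts against the
# HWE expectation (1 df, no continuity correction). Monomorphic columns are
# treated as consistent with HWE (the test is undefined there).
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  f <- (n1 + 2 * n2) / (2 * n)
  if (f <= 0 || f >= 1) return(1)
  e <- n * c((1 - f)^2, 2 * f * (1 - f), f^2)
  o <- c(n0, n1, n2)
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Compute summary statistics from a genotype matrix
#'
#' Derives everything the simulator needs from real data: per-SNP allele
#' frequency \eqn{f = (\#1 + 2\cdot\#2)/(2N)}, an HWE flag from a
#' chi-square goodness-of-fit test at significance `hwe_alpha` (observed
#' fractions recorded when deviating), and the signed Pearson correlation
#' of every unordered pair of dosage columns. Pairs involving a constant
#' (monomorphic) column are omitted from the correlation table with a
#' warning, since their correlation is undefined.
#'
#' @param X genotype matrix (see [genotype_matrix()]).
#' @param hwe_alpha significance level of the HWE test, in (0,1).
#' @param effect_alleles,other_alleles optional per-SNP allele labels for
#'   the "2"-coded and alternative allele (defaults `"A"`/`"G"` when the
#'   matrix carries no allele metadata).
#' @return list with components `stats` ([summary_stats()]) and
#'   `corr` ([correlation_table()]).
#' @export
compute_summary_stats <- function(X, hwe_alpha = 0.05,
                                  effect_alleles = NULL, other_alleles = NULL) {
  X <- genotype_matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2) stop_input("need at least 2 samples to compute correlations (N = ", n, ")")
  if (!is.numeric(hwe_alpha) || hwe_alpha <= 0 || hwe_alpha >= 1) {
    stop_input("hwe_alpha must be in (0,1)")
  }
  snp_ids <- colnames(X)
  if (is.null(effect_alleles)) effect_alleles <- rep("A", p)
  if (is.null(other_alleles)) other_alleles <- rep("G", p)

  n1 <- colSums(X == 1L)
  n2 <- colSums(X == 2L)
  n0 <- n - n1 - n2
  freq <- (n1 + 2 * n2) / (2 * n)
  pvals <- vapply(seq_len(p), function(j) hwe_chisq_p(n0[j], n1[j], n2[j]), numeric(1))
  deviates <- pvals < hwe_alpha
  frac0 <- ifelse(deviates, n0 / n, NA_real_)
  frac1 <- ifelse(deviates, n1 / n, NA_real_)
  frac2 <- ifelse(deviates, n2 / n, NA_real_)

  stats <- summary_stats(data.frame(
    snp_id = snp_ids, effect_allele = effect_alleles, other_allele = other_alleles,
    freq = freq, hwe_deviates = deviates,
    frac0 = frac0, frac1 = frac1, frac2 = frac2,
    stringsAsFactors = FALSE
  ))

  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    warning("monomorphic/constant SNP column(s) excluded from correlation table: ",
            paste(snp_ids[const], collapse = ", "))
  }
  keep <- which(!const)
  entries <- list()
  if (length(keep) >= 2) {
    cm <- stats::cor(X[, keep, drop = FALSE])
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    entries <- data.frame(
      snp_a = snp_ids[keep][idx[, 1]],
      snp_b = snp_ids[keep][idx[, 2]],
      rho = cm[idx],
      stringsAsFactors = FALSE
    )
  } else {
    entries <- data.frame(snp_a = character(), snp_b = character(), rho = numeric())
  }
  list(stats = stats, corr = correlation_table(entries))
}

# Genotype-class fractions implied by a stats record: observed fractions
# for HWE-deviating SNPs, HWE values otherwise.
implied_fractions <- function(stats, snp_id) {
  i <- match(snp_id, stats$snp_id)
  if (is.na(i)) stop_input("unknown SNP ", snp_id)
  if (isTRUE(stats$hwe_deviates[i])) {
    c(stats$frac0[i], stats$frac1[i], stats$frac2[i])
  } else {
    f <- stats$freq[i]
    c((1 - f)^2, 2 * f * (1 - f), f^2)
  }
}
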