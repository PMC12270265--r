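# Shared in-code fixtures for the tests.

make_stats <- function(snp_ids, freqs, hwe = rep(FALSE, length(snp_ids)),
                       fracs = NULL) {
  df <- data.frame(
    snp_id = snp_ids,
    effect_allele = rep("A", length(snp_ids)),
    other_allele = rep("G", length(snp_ids)),
    freq = freqs, hwe_deviates = hwe,
    frac0 = NA_real_, frac1 = NA_real_, frac2 = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(fracs)) {
    for (id in names(fracs)) {
      i <- match(id, df$snp_id)
      df$frac0[i] <- fracs[[id]][1]
      df$frac1[i] <- fracs[[id]][2]
      df$frac2[i] <- fracs[[id]][3]
    }
  }
  summary_stats(df)
}

make_corr <- function(a, b, rho) {
  correlation_table(data.frame(snp_a = a, snp_b = b, rho = rho,
                               stringsAsFactors = FALSE))
}

make_X <- function(cols, sample_ids = NULL) {
  m <- do.call(cbind, cols)
  genotype_matrix(m, sample_ids = sample_ids %||% paste0("S", seq_len(nrow(m))),
                  snp_ids = names(cols))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small two-block bundle used across simulator tests; cached per session
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_fixture_bundle(default_fixture_spec())
    cache
  }
})
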