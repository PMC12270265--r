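# TSV (and optional VCF) plumbing. All numeric output uses 10 significant
# digits so write -> load round-trips are stable at the written precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.10g", v), character(1)))
}

read_tsv_raw <- function(path, expected_cols, what) {
  if (!file.exists(path)) stop_input(what, " file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop_input(what, " file is empty: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  missing_cols <- setdiff(expected_cols, header)
  if (length(missing_cols) > 0) {
    stop_input(what, " file ", path, " missing column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(seq_along(lines)[-1], function(k) {
    fields <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    # strsplit drops trailing empty fields; the tab count is authoritative
    n_fields <- nchar(lines[k]) - nchar(gsub("\t", "", lines[k], fixed = TRUE)) + 1L
    if (length(fields) < n_fields) {
      fields <- c(fields, rep("", n_fields - length(fields)))
    }
    if (length(fields) != length(header)) {
      stop_input("malformed row in ", what, " file ", path, " at line ", k,
                 ": expected ", length(header), " fields, got ", length(fields))
    }
    fields
  })
  m <- do.call(rbind, c(rows, list(matrix(character(), 0, length(header)))))
  colnames(m) <- header
  list(data = m, header = header)
}

parse_num <- function(x, path, what, lines_offset = 1L) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad) > 0) {
    stop_input("malformed numeric field in ", what, " file ", path,
               " at line ", bad[1] + lines_offset)
  }
  out[!nzchar(x)] <- NA_real_
  out
}

#' Write summary statistics and correlations to TSV
#'
#' Frequencies TSV columns: `snp_id`, `effect_allele`, `other_allele`,
#' `freq`, `hwe_deviates` (0/1), `frac0`, `frac1`, `frac2` (frac columns
#' empty when `hwe_deviates` = 0). Correlations TSV columns: `snp_a`,
#' `snp_b`, `rho`. Tab-separated, UTF-8, `.` decimal.
#'
#' @param stats a [summary_stats()] object.
#' @param corr a [correlation_table()] object.
#' @param freq_path,corr_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_summary_stats <- function(stats, corr, freq_path, corr_path) {
  stats <- summary_stats(stats)
  corr <- correlation_table(corr)
  fr <- data.frame(
    snp_id = stats$snp_id,
    effect_allele = stats$effect_allele,
    other_allele = stats$other_allele,
    freq = fmt_num(stats$freq),
    hwe_deviates = as.integer(stats$hwe_deviates),
    frac0 = ifelse(stats$hwe_deviates, fmt_num(stats$frac0), ""),
    frac1 = ifelse(stats$hwe_deviates, fmt_num(stats$frac1), ""),
    frac2 = ifelse(stats$hwe_deviates, fmt_num(stats$frac2), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(fr, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  cr <- data.frame(snp_a = corr$snp_a, snp_b = corr$snp_b,
                   rho = fmt_num(corr$rho), stringsAsFactors = FALSE)
  utils::write.table(cr, corr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(freq_path, corr_path))
}

#' Load summary statistics and correlations from TSV
#'
#' Inverse of [write_summary_stats()]: `write` followed by `load` is the
#' identity on both objects at the written 10-significant-digit precision.
#' Every SNP referenced in the correlations file must be declared in the
#' frequencies file.
#'
#' @param freq_path,corr_path input paths.
#' @return list with components `stats` and `corr`.
#' @export
load_summary_stats <- function(freq_path, corr_path) {
  fr <- read_tsv_raw(freq_path,
                     c("snp_id", "effect_allele", "other_allele", "freq",
                       "hwe_deviates", "frac0", "frac1", "frac2"),
                     "frequencies")
  d <- fr$data
  hwe_raw <- d[, "hwe_deviates"]
  if (!all(hwe_raw %in% c("0", "1"))) {
    bad <- which(!(hwe_raw %in% c("0", "1")))[1]
    stop_input("malformed hwe_deviates (must be 0/1) in frequencies file ",
               freq_path, " at line ", bad + 1L)
  }
  stats <- summary_stats(data.frame(
    snp_id = d[, "snp_id"],
    effect_allele = d[, "effect_allele"],
    other_allele = d[, "other_allele"],
    freq = parse_num(d[, "freq"], freq_path, "frequencies"),
    hwe_deviates = hwe_raw == "1",
    frac0 = parse_num(d[, "frac0"], freq_path, "frequencies"),
    frac1 = parse_num(d[, "frac1"], freq_path, "frequencies"),
    frac2 = parse_num(d[, "frac2"], freq_path, "frequencies"),
    stringsAsFactors = FALSE
  ))
  cr <- read_tsv_raw(corr_path, c("snp_a", "snp_b", "rho"), "correlations")
  cd <- cr$data
  corr <- correlation_table(data.frame(
    snp_a = cd[, "snp_a"], snp_b = cd[, "snp_b"],
    rho = parse_num(cd[, "rho"], corr_path, "correlations"),
    stringsAsFactors = FALSE
  ))
  unknown <- setdiff(unique(c(corr$snp_a, corr$snp_b)), stats$snp_id)
  if (length(unknown) > 0) {
    stop_input("correlation file references SNP(s) absent from frequencies file: ",
               paste(unknown, collapse = ", "))
  }
  list(stats = stats, corr = corr)
}

#' Read / write a genotype matrix as TSV
#'
#' Canonical layout: header row `sample_id` followed by the SNP ids, one
#' row per sample with integer dosages in \{0,1,2\}.
#'
#' @param path file path.
#' @return [read_genotype_tsv()]: a validated genotype matrix.
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop_input("genotype file not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(d) < 2 || names(d)[1] != "sample_id") {
    stop_input("genotype TSV ", path, " must start with a sample_id column")
  }
  sample_ids <- d[[1]]
  vals <- as.matrix(d[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_input("malformed genotype value in ", path, " at line ", bad[1] + 1L,
               ", SNP ", colnames(vals)[bad[2]])
  }
  genotype_matrix(num, sample_ids = sample_ids, snp_ids = colnames(vals))
}

#' @rdname read_genotype_tsv
#' @param X genotype matrix.
#' @export
write_genotype_tsv <- function(X, path) {
  X <- genotype_matrix(X)
  df <- data.frame(sample_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read genotype dosages from a VCF file (convenience)
#'
#' Optional reader over `VariantAnnotation`; the TSV genotype matrix is the
#' canonical input. Only biallelic SNP records are used; the dosage is the
#' count of the ALT allele, so the returned allele metadata codes ALT as
#' the "2" allele. Any missing genotype among the requested SNPs is an
#' error: the method assumes complete data.
#'
#' @param path VCF path (plain or bgzipped).
#' @param snp_ids optional SNP ids to restrict to (VCF ID field).
#' @return list with `X` (genotype matrix), `effect_alleles` (ALT),
#'   `other_alleles` (REF).
#' @export
read_genotype_vcf <- function(path, snp_ids = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop_input("read_genotype_vcf requires the VariantAnnotation package")
  }
  if (!file.exists(path)) stop_input("VCF file not found: ", path)
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1] <- as.character(unlist(altl[n_alt == 1]))
  biallelic <- n_alt == 1 & nchar(ref) == 1 & nchar(alt1) == 1 &
    ref %in% VALID_ALLELES & alt1 %in% VALID_ALLELES
  ids <- rownames(vcf)
  keep <- which(biallelic)
  if (!is.null(snp_ids)) {
    missing_ids <- setdiff(snp_ids, ids[keep])
    if (length(missing_ids) > 0) {
      stop_input("requested SNP(s) not found as biallelic SNPs in VCF: ",
                 paste(missing_ids, collapse = ", "))
    }
    keep <- keep[match(snp_ids, ids[keep])]
  }
  gt <- VariantAnnotation::geno(vcf)$GT[keep, , drop = FALSE]
  dose <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  if (anyNA(dose)) {
    bad <- which(is.na(dose), arr.ind = TRUE)[1, ]
    stop_input("missing genotype in VCF for SNP ", ids[keep][bad[1]],
               ", sample ", colnames(gt)[bad[2]],
               " (the method assumes complete data)")
  }
  X <- genotype_matrix(t(dose), sample_ids = colnames(gt), snp_ids = ids[keep])
  list(X = X, effect_alleles = alt1[keep], other_alleles = ref[keep])
}
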