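# Genetic risk score engine: linear weighted sum over effect-allele
# dosages plus a ranked pairwise interaction term -- per sample, the first
# interaction entry (in rank order) whose two genotype predicates both
# hold contributes its weight; at most one entry applies per sample.

PREDICATES <- c("eq0", "eq1", "eq2", "ge1", "ge2")

#' Construct a GRS model
#'
#' A GRS model has a linear part -- per SNP an effect allele and a weight,
#' the score contribution being `weight * dosage(effect allele)` -- and an
#' optional ranked interaction table. Each interaction entry names two
#' SNPs with genotype predicates (`eq0`/`eq1`/`eq2` exact dosage,
#' `ge1`/`ge2` carrier thresholds, evaluated on effect-allele dosages) and
#' a weight; rank 1 is the highest priority.
#'
#' @param linear data.frame with columns `snp_id`, `effect_allele`,
#'   `weight`.
#' @param interactions optional data.frame with columns `rank`, `snp_a`,
#'   `predicate_a`, `snp_b`, `predicate_b`, `weight`.
#' @return object of class `grs_model`.
#' @export
grs_model <- function(linear, interactions = NULL) {
  linear <- as.data.frame(linear, stringsAsFactors = FALSE)
  needed <- c("snp_id", "effect_allele", "weight")
  if (!all(needed %in% names(linear))) {
    stop_input("linear model table must have columns snp_id, effect_allele, weight")
  }
  linear <- linear[, needed]
  linear$snp_id <- as.character(linear$snp_id)
  linear$effect_allele <- as.character(linear$effect_allele)
  linear$weight <- as.numeric(linear$weight)
  if (anyDuplicated(linear$snp_id)) {
    stop_input("duplicate snp_id in linear model: ",
               paste(unique(linear$snp_id[duplicated(linear$snp_id)]), collapse = ", "))
  }
  if (any(!linear$effect_allele %in% VALID_ALLELES)) {
    bad <- linear$snp_id[!linear$effect_allele %in% VALID_ALLELES]
    stop_input("invalid effect allele for SNP(s): ", paste(bad, collapse = ", "))
  }
  if (anyNA(linear$weight)) stop_input("missing weight in linear model")

  if (is.null(interactions) || NROW(interactions) == 0) {
    interactions <- data.frame(rank = integer(), snp_a = character(),
                               predicate_a = character(), snp_b = character(),
                               predicate_b = character(), weight = numeric(),
                               stringsAsFactors = FALSE)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    ineed <- c("rank", "snp_a", "predicate_a", "snp_b", "predicate_b", "weight")
    if (!all(ineed %in% names(interactions))) {
      stop_input("interaction table must have columns ", paste(ineed, collapse = ", "))
    }
    interactions <- interactions[, ineed]
    interactions$rank <- as.integer(interactions$rank)
    interactions$snp_a <- as.character(interactions$snp_a)
    interactions$snp_b <- as.character(interactions$snp_b)
    interactions$predicate_a <- as.character(interactions$predicate_a)
    interactions$predicate_b <- as.character(interactions$predicate_b)
    interactions$weight <- as.numeric(interactions$weight)
    rk <- sort(interactions$rank)
    if (!identical(rk, seq_len(nrow(interactions)))) {
      stop_input("interaction ranks must be unique and contiguous from 1")
    }
    badp <- !(interactions$predicate_a %in% PREDICATES) |
      !(interactions$predicate_b %in% PREDICATES)
    if (any(badp)) {
      stop_input("invalid predicate (must be ", paste(PREDICATES, collapse = "|"),
                 ") at rank(s): ", paste(interactions$rank[badp], collapse = ", "))
    }
    if (any(interactions$snp_a == interactions$snp_b)) {
      stop_input("interaction entry with snp_a == snp_b at rank(s): ",
                 paste(interactions$rank[interactions$snp_a == interactions$snp_b],
                       collapse = ", "))
    }
    isnps <- unique(c(interactions$snp_a, interactions$snp_b))
    absent <- setdiff(isnps, linear$snp_id)
    if (length(absent) > 0) {
      stop_input("interaction SNP(s) not in linear model: ",
                 paste(absent, collapse = ", "))
    }
    interactions <- interactions[order(interactions$rank), , drop = FALSE]
  }
  rownames(linear) <- NULL
  rownames(interactions) <- NULL
  structure(list(linear = linear, interactions = interactions),
            class = "grs_model")
}

#' Build an allele map from summary statistics
#'
#' The allele map states, per SNP, which allele the genotype matrix's "2"
#' dosage counts (`counted_allele`) and the alternative (`other_allele`).
#' A [summary_stats()] object carries exactly this metadata.
#'
#' @param stats a [summary_stats()] object.
#' @return data.frame with columns `snp_id`, `counted_allele`,
#'   `other_allele`.
#' @export
allele_map_from_stats <- function(stats) {
  stats <- summary_stats(stats)
  data.frame(snp_id = stats$snp_id, counted_allele = stats$effect_allele,
             other_allele = stats$other_allele, stringsAsFactors = FALSE)
}

#' Orient a genotype matrix to a model's effect alleles
#'
#' Flips column k to `2 - x` when the model's effect allele for that SNP
#' is the array's non-counted allele, leaves it unchanged when matched.
#' After this, every model SNP's column counts copies of the model's
#' effect allele, as the linear sum requires.
#'
#' @param X genotype matrix.
#' @param model a [grs_model()].
#' @param allele_map data.frame as from [allele_map_from_stats()].
#' @return genotype matrix with model columns effect-oriented.
#' @export
effect_dosage <- function(X, model, allele_map) {
  X <- genotype_matrix(X)
  stopifnot(inherits(model, "grs_model"))
  for (i in seq_len(nrow(model$linear))) {
    s <- model$linear$snp_id[i]
    if (!s %in% colnames(X)) next
    am <- allele_map[allele_map$snp_id == s, , drop = FALSE]
    if (nrow(am) != 1) stop_input("allele map missing SNP ", s)
    eff <- model$linear$effect_allele[i]
    if (eff == am$counted_allele) {
      # matched: column already counts the effect allele
    } else if (eff == am$other_allele) {
      X[, s] <- 2L - X[, s]
    } else {
      stop_input("effect allele ", eff, " for SNP ", s,
                 " matches neither array allele (", am$counted_allele, "/",
                 am$other_allele, "); probable strand or ID mismatch")
    }
  }
  X
}

eval_predicate <- function(x, pred) {
  switch(pred,
         eq0 = x == 0L, eq1 = x == 1L, eq2 = x == 2L,
         ge1 = x >= 1L, ge2 = x >= 2L,
         stop_input("unknown predicate ", pred))
}

#' Ranked pairwise interaction score
#'
#' Evaluates interaction entries in rank order on an effect-oriented
#' matrix; per sample the first entry whose both predicates hold
#' contributes its weight and all later entries are ignored. A sample
#' satisfying no entry scores 0 with applied rank `NA`.
#'
#' @param Xe effect-oriented genotype matrix.
#' @param model a [grs_model()].
#' @return list with `score` (numeric per sample) and `rank_applied`
#'   (integer per sample, `NA` when no entry applies).
#' @export
interaction_score <- function(Xe, model) {
  stopifnot(inherits(model, "grs_model"))
  n <- nrow(Xe)
  score <- numeric(n)
  rank_applied <- rep(NA_integer_, n)
  it <- model$interactions
  for (k in seq_len(nrow(it))) {
    hit <- eval_predicate(Xe[, it$snp_a[k]], it$predicate_a[k]) &
      eval_predicate(Xe[, it$snp_b[k]], it$predicate_b[k]) &
      is.na(rank_applied)
    score[hit] <- it$weight[k]
    rank_applied[hit] <- it$rank[k]
  }
  list(score = score, rank_applied = rank_applied)
}

#' Compute genetic risk scores
#'
#' Per sample: `linear_score` = sum over model SNPs of weight times
#' effect-allele dosage; `interaction_score` per [interaction_score()];
#' `total` their sum. `snp_subset` restricts the linear part to a listed
#' set of SNPs (e.g. an HLA subset, or the correlated/uncorrelated SNP
#' split) -- interaction entries are kept only when both their SNPs are in
#' the subset; `include_interactions = FALSE` drops the interaction term
#' entirely.
#'
#' @param X genotype matrix.
#' @param model a [grs_model()].
#' @param allele_map data.frame as from [allele_map_from_stats()].
#' @param snp_subset optional character vector of SNP ids to restrict the
#'   model to.
#' @param include_interactions logical; score the interaction term?
#' @param allow_missing if TRUE, model SNPs absent from `X` contribute 0
#'   (with a warning listing them); default is a strict error.
#' @return data.frame of class `grs_scores` with columns `sample_id`,
#'   `linear_score`, `interaction_score`, `total`,
#'   `interaction_rank_applied`.
#' @export
compute_grs <- function(X, model, allele_map, snp_subset = NULL,
                        include_interactions = TRUE, allow_missing = FALSE) {
  X <- genotype_matrix(X)
  stopifnot(inherits(model, "grs_model"))
  linear <- model$linear
  interactions <- model$interactions
  if (!is.null(snp_subset)) {
    linear <- linear[linear$snp_id %in% snp_subset, , drop = FALSE]
    interactions <- interactions[interactions$snp_a %in% snp_subset &
                                   interactions$snp_b %in% snp_subset, ,
                                 drop = FALSE]
    if (nrow(interactions) > 0) interactions$rank <- seq_len(nrow(interactions))
  }
  missing_snp <- setdiff(linear$snp_id, colnames(X))
  if (length(missing_snp) > 0) {
    if (!allow_missing) {
      stop_input("model SNP(s) absent from genotype matrix: ",
                 paste(missing_snp, collapse = ", "),
                 " (set allow_missing = TRUE to score without them)")
    }
    warning("model SNP(s) absent from genotype matrix contribute 0: ",
            paste(missing_snp, collapse = ", "))
    keep <- !(linear$snp_id %in% missing_snp)
    linear <- linear[keep, , drop = FALSE]
    interactions <- interactions[!(interactions$snp_a %in% missing_snp) &
                                   !(interactions$snp_b %in% missing_snp), ,
                                 drop = FALSE]
    if (nrow(interactions) > 0) interactions$rank <- seq_len(nrow(interactions))
  }
  sub_model <- grs_model(linear, interactions)
  Xe <- effect_dosage(X, sub_model, allele_map)
  n <- nrow(X)
  if (nrow(linear) > 0) {
    lin <- as.numeric(Xe[, linear$snp_id, drop = FALSE] %*% linear$weight)
  } else {
    lin <- numeric(n)
  }
  if (include_interactions && nrow(sub_model$interactions) > 0) {
    inter <- interaction_score(Xe, sub_model)
  } else {
    inter <- list(score = numeric(n), rank_applied = rep(NA_integer_, n))
  }
  out <- data.frame(
    sample_id = rownames(X),
    linear_score = lin,
    interaction_score = inter$score,
    total = lin + inter$score,
    interaction_rank_applied = inter$rank_applied,
    stringsAsFactors = FALSE
  )
  class(out) <- c("grs_scores", "data.frame")
  out
}

#' Read / write GRS model tables as TSV
#'
#' Linear table columns: `snp_id`, `effect_allele`, `weight`. Interaction
#' table columns: `rank`, `snp_a`, `predicate_a`, `snp_b`, `predicate_b`,
#' `weight`; predicates spelled exactly `eq0|eq1|eq2|ge1|ge2`.
#'
#' @param linear_path path to the linear table.
#' @param interactions_path optional path to the interaction table.
#' @return [read_grs_model()]: a [grs_model()].
#' @export
read_grs_model <- function(linear_path, interactions_path = NULL) {
  lr <- read_tsv_raw(linear_path, c("snp_id", "effect_allele", "weight"),
                     "GRS linear model")
  d <- lr$data
  linear <- data.frame(
    snp_id = d[, "snp_id"], effect_allele = d[, "effect_allele"],
    weight = parse_num(d[, "weight"], linear_path, "GRS linear model"),
    stringsAsFactors = FALSE
  )
  interactions <- NULL
  if (!is.null(interactions_path)) {
    ir <- read_tsv_raw(interactions_path,
                       c("rank", "snp_a", "predicate_a", "snp_b",
                         "predicate_b", "weight"),
                       "GRS interaction model")
    di <- ir$data
    interactions <- data.frame(
      rank = as.integer(parse_num(di[, "rank"], interactions_path,
                                  "GRS interaction model")),
      snp_a = di[, "snp_a"], predicate_a = di[, "predicate_a"],
      snp_b = di[, "snp_b"], predicate_b = di[, "predicate_b"],
      weight = parse_num(di[, "weight"], interactions_path,
                         "GRS interaction model"),
      stringsAsFactors = FALSE
    )
  }
  grs_model(linear, interactions)
}

#' @rdname read_grs_model
#' @param model a [grs_model()].
#' @export
write_grs_model <- function(model, linear_path, interactions_path = NULL) {
  stopifnot(inherits(model, "grs_model"))
  lin <- data.frame(snp_id = model$linear$snp_id,
                    effect_allele = model$linear$effect_allele,
                    weight = fmt_num(model$linear$weight),
                    stringsAsFactors = FALSE)
  utils::write.table(lin, linear_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(interactions_path)) {
    it <- model$interactions
    itd <- data.frame(rank = it$rank, snp_a = it$snp_a,
                      predicate_a = it$predicate_a, snp_b = it$snp_b,
                      predicate_b = it$predicate_b,
                      weight = fmt_num(it$weight), stringsAsFactors = FALSE)
    utils::write.table(itd, interactions_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(linear_path)
}

#' Read / write a score table as TSV
#'
#' Columns: `sample_id`, `linear_score`, `interaction_score`, `total`,
#' `interaction_rank_applied` (empty when no interaction applied).
#'
#' @param path file path.
#' @export
write_scores_tsv <- function(scores, path) {
  df <- data.frame(
    sample_id = scores$sample_id,
    linear_score = fmt_num(scores$linear_score),
    interaction_score = fmt_num(scores$interaction_score),
    total = fmt_num(scores$total),
    interaction_rank_applied = ifelse(is.na(scores$interaction_rank_applied), "",
                                      as.character(scores$interaction_rank_applied)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_scores_tsv
#' @param scores a score table as returned by [compute_grs()].
#' @export
read_scores_tsv <- function(path) {
  r <- read_tsv_raw(path, c("sample_id", "linear_score", "interaction_score",
                            "total", "interaction_rank_applied"), "scores")
  d <- r$data
  ra <- parse_num(d[, "interaction_rank_applied"], path, "scores")
  out <- data.frame(
    sample_id = d[, "sample_id"],
    linear_score = parse_num(d[, "linear_score"], path, "scores"),
    interaction_score = parse_num(d[, "interaction_score"], path, "scores"),
    total = parse_num(d[, "total"], path, "scores"),
    interaction_rank_applied = as.integer(ra),
    stringsAsFactors = FALSE
  )
  class(out) <- c("grs_scores", "data.frame")
  out
}
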