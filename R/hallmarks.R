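#' Pseudo-counted log2 fold-change enrichment
#'
#' `log2((f_K + eps) / (f_E + eps))` with `f_K = count_k / n_k`,
#' `f_E = count_e / n_e` and pseudo-count `eps = 0.5 / n_total`; positive
#' values mean enrichment in the kinked class.
#'
#' @param count_k,count_e Carrier counts in the kinked / extended class.
#' @param n_k,n_e Class sizes.
#' @param n_total Total number of training observations (sets the
#'   pseudo-count); defaults to `n_k + n_e`.
#' @return Numeric vector of log2 fold changes.
#' @export
log2fc_enrichment <- function(count_k, n_k, count_e, n_e, n_total = n_k + n_e) {
  if (any(n_k <= 0) || any(n_e <= 0) || any(n_total <= 0)) {
    rlang::abort("class sizes must be positive")
  }
  if (any(count_k > n_k) || any(count_e > n_e) ||
      any(count_k < 0) || any(count_e < 0)) {
    rlang::abort("counts must lie in [0, class size]")
  }
  eps <- 0.5 / n_total
  log2((count_k / n_k + eps) / (count_e / n_e + eps))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Tie-inclusive minimum-likelihood convention: the p-value sums all
#' hypergeometric table probabilities not exceeding that of the observed
#' table (the convention of standard statistical packages; delegated to
#' [stats::fisher.test()]).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `matrix(c(a, c, b, d), 2)` i.e. rows are classes, columns
#'   carrier/non-carrier.
#' @return Two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    rlang::abort("cell counts must be non-negative integers")
  }
  if (sum(counts) == 0) return(1)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

#' Discover framework sequence hallmarks of the HCDR3 blueprint
#'
#' Scans every (framework AHo position, amino acid) combination for
#' association with the kinked/extended labels. Candidates must pass a
#' two-sided Fisher test (`p < p_max`) and carry at least `min_obs` total
#' observations (carriers summed across both classes). Survivors are scored
#' by the product of two absolute correlations -- point-biserial of the 0/1
#' carrier indicator with the 0/1 class label, and Pearson of the indicator
#' with the structure-classifier probabilities -- and the top `k` are
#' returned with their pseudo-counted log2 fold changes. CDR positions are
#' never candidates.
#'
#' @param seqs Sequence tibble with columns `id`, `seq`, `label` (values
#'   `"kinked"` / `"extended"`) and `p_struct` (structure-classifier
#'   probability), or pass `labels` / `struct_probs` separately.
#' @param labels,struct_probs Optional vectors overriding the corresponding
#'   columns.
#' @param k Number of hallmarks to return (default 20).
#' @param p_max Fisher p-value threshold (default 0.05).
#' @param min_obs Minimum total carrier observations (default 30).
#' @return A hallmark tibble (`region`, `position`, `aa`, `log2fc`,
#'   `p_value`, `freq_kinked`, `freq_extended`, `score`), ranked by
#'   decreasing score; ties broken by smaller p-value, then position.
#' @export
discover_hallmarks <- function(seqs, labels = seqs$label,
                               struct_probs = seqs$p_struct,
                               k = 20L, p_max = 0.05, min_obs = 30L) {
  if (k <= 0) rlang::abort("`k` must be positive")
  if (is.null(labels) || is.null(struct_probs)) {
    rlang::abort("`labels` and `struct_probs` are required")
  }
  if (!all(labels %in% c("kinked", "extended"))) {
    rlang::abort("labels must be 'kinked' or 'extended'")
  }
  n <- nrow(seqs)
  if (n < 2L) rlang::abort("need at least 2 labelled sequences")
  y <- as.integer(labels == "kinked")
  n_k <- sum(y); n_e <- n - n_k
  if (n_k == 0L || n_e == 0L) rlang::abort("both classes must be present")

  chars <- aho_char_matrix(seqs)  # 149 x n
  fw_pos <- unlist(lapply(FRAMEWORK_REGIONS, aho_positions_of))
  rows <- list()
  for (p in fw_pos) {
    col <- chars[p, ]
    for (a in intersect(unique(col), AA1)) {
      carrier <- as.integer(col == a)
      ck <- sum(carrier[y == 1L]); ce <- sum(carrier[y == 0L])
      if (ck + ce < min_obs) next
      pv <- fisher_exact_two_sided(ck, n_k - ck, ce, n_e - ce)
      if (pv >= p_max) next
      r_label <- suppressWarnings(stats::cor(carrier, y))
      r_struct <- suppressWarnings(stats::cor(carrier, struct_probs))
      if (!is.finite(r_label)) r_label <- 0
      if (!is.finite(r_struct)) r_struct <- 0
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region = aho_region(p), position = as.integer(p), aa = a,
        log2fc = log2fc_enrichment(ck, n_k, ce, n_e, n),
        p_value = pv,
        freq_kinked = ck / n_k, freq_extended = ce / n_e,
        score = abs(r_label) * abs(r_struct)
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(region = character(), position = integer(),
                          aa = character(), log2fc = numeric(),
                          p_value = numeric(), freq_kinked = numeric(),
                          freq_extended = numeric(), score = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$p_value,
                        .data$position, .data$aa)
  utils::head(out, k)
}
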