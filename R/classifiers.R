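sigmoid <- function(z) 1 / (1 + exp(-z))

#' Standardized logistic probability
#'
#' Computes `sigmoid(sum_i w_i * (x_i - mu_i) / sigma_i + b)` for each row of
#' feature values: the shared functional form of both blueprint classifiers.
#'
#' @param x Numeric vector (one observation), matrix, or data frame whose
#'   columns cover the parameter set's feature names.
#' @param params An [logistic_params()] object.
#' @return Numeric vector of probabilities, strictly inside (0, 1).
#' @export
standardized_logistic <- function(x, params) {
  stopifnot(inherits(params, "nb_logistic_params"))
  feats <- params$coef$feature
  if (is.data.frame(x)) {
    missing <- setdiff(feats, names(x))
    if (length(missing)) {
      rlang::abort(sprintf("feature column(s) missing: %s",
                           paste(missing, collapse = ", ")))
    }
    x <- as.matrix(x[, feats, drop = FALSE])
  } else if (is.null(dim(x))) {
    if (length(x) != length(feats)) {
      rlang::abort(sprintf("expected %d feature values, got %d",
                           length(feats), length(x)))
    }
    x <- matrix(x, nrow = 1)
  } else {
    if (ncol(x) != length(feats)) {
      rlang::abort(sprintf("expected %d feature columns, got %d",
                           length(feats), ncol(x)))
    }
    if (!is.null(colnames(x))) x <- x[, feats, drop = FALSE]
  }
  if (any(!is.finite(x))) rlang::abort("non-finite feature value")
  z <- sweep(sweep(x, 2, params$coef$mu), 2, params$coef$sigma, "/")
  as.numeric(sigmoid(z %*% params$coef$w + params$b))
}

#' Structure-based blueprint classification
#'
#' Applies the logistic structure classifier to a table of blueprint
#' descriptors (see [vhh_features()]).
#'
#' @param features Tibble with the six feature columns (and optionally `id`).
#' @param params Parameter set; defaults to the packaged published values
#'   ([nbframe_structure_params()]).
#' @return The input tibble with an added `p_kinked` column.
#' @export
classify_structure <- function(features, params = nbframe_structure_params()) {
  features$p_kinked <- standardized_logistic(features, params)
  features
}

#' Discretize a kinked probability into a blueprint bin
#'
#' Two published threshold schemes: `"deployment"` (extended < 0.3,
#' kinked > 0.7, otherwise unclear) and `"evaluation"` (extended < 0.25,
#' kinked > 0.55, otherwise unclear).
#'
#' @param p_kinked Numeric vector of probabilities in (0, 1).
#' @param scheme `"deployment"` or `"evaluation"`.
#' @return Character vector with values `"kinked"`, `"extended"`,
#'   `"unclear"`.
#' @export
call_blueprint <- function(p_kinked, scheme = c("deployment", "evaluation")) {
  scheme <- match.arg(scheme)
  # saturated probabilities (0 or 1 to machine precision) are accepted
  if (any(!is.finite(p_kinked) | p_kinked < 0 | p_kinked > 1)) {
    rlang::abort("`p_kinked` must lie inside [0, 1]")
  }
  th <- switch(scheme,
    deployment = c(lo = 0.3, hi = 0.7),
    evaluation = c(lo = 0.25, hi = 0.55)
  )
  dplyr::case_when(
    p_kinked < th[["lo"]] ~ "extended",
    p_kinked > th[["hi"]] ~ "kinked",
    TRUE ~ "unclear"
  )
}

#' Encode sequences against a hallmark table
#'
#' For each hallmark j (AHo position p_j, amino acid a_j, enrichment
#' Log2FC_j), the encoded feature is Log2FC_j when the sequence carries a_j
#' at p_j and 0 otherwise. Gaps and unknown residues never match.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param hallmarks Hallmark tibble; defaults to the packaged table
#'   ([nbframe_hallmarks()]).
#' @return Numeric matrix, one row per sequence, one column per hallmark
#'   (named `region/position/aa`), with sequence ids as row names.
#' @export
encode_hallmarks <- function(seqs, hallmarks = nbframe_hallmarks()) {
  m <- matrix(0, nrow = nrow(seqs), ncol = nrow(hallmarks),
              dimnames = list(seqs$id, hallmark_feature_names(hallmarks)))
  for (j in seq_len(nrow(hallmarks))) {
    carrier <- aho_slot(seqs$seq, hallmarks$position[j]) == hallmarks$aa[j]
    m[carrier, j] <- hallmarks$log2fc[j]
  }
  m
}

hallmark_feature_names <- function(hallmarks) {
  paste(hallmarks$region, hallmarks$position, hallmarks$aa, sep = "/")
}

#' Sequence-based blueprint classification
#'
#' Encodes sequences against the hallmark table and applies a standardized
#' logistic model over the 20 encoded features.
#'
#' @param seqs Sequence tibble (`id`, `seq`).
#' @param params An [logistic_params()] object with one entry per hallmark,
#'   in the hallmark table's order. Defaults to the packaged reference set
#'   fitted on synthetic data ([nbframe_sequence_params_synthetic()]) --
#'   NOT the published model's weights, which were not released.
#' @param hallmarks Hallmark tibble.
#' @return The input tibble with an added `p_kinked` column.
#' @export
classify_sequence <- function(seqs,
                              params = nbframe_sequence_params_synthetic(),
                              hallmarks = nbframe_hallmarks()) {
  x <- encode_hallmarks(seqs, hallmarks)
  if (!identical(colnames(x), params$coef$feature)) {
    rlang::abort("`params` features do not align with the hallmark table")
  }
  seqs$p_kinked <- standardized_logistic(x, params)
  seqs
}
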