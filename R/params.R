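#' Logistic classifier parameter sets
#'
#' Both blueprint classifiers share one parameter form: per-feature training
#' means `mu` and standard deviations `sigma` (used to standardize inputs),
#' per-feature weights `w`, and an intercept `b`. Probability of a kinked
#' HCDR3 is `sigmoid(sum(w * (x - mu) / sigma) + b)`.
#'
#' @param feature Character vector of feature names (order matters).
#' @param mu,sigma,w Numeric vectors aligned with `feature`; `sigma > 0`.
#' @param b Intercept.
#' @return An object of class `nb_logistic_params`.
#' @export
logistic_params <- function(feature, mu, sigma, w, b) {
  n <- length(feature)
  if (length(mu) != n || length(sigma) != n || length(w) != n) {
    rlang::abort("`feature`, `mu`, `sigma`, `w` must have equal lengths")
  }
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    rlang::abort("all `sigma` must be finite and > 0")
  }
  structure(
    list(
      coef = tibble::tibble(feature = as.character(feature),
                            mu = as.numeric(mu), sigma = as.numeric(sigma),
                            w = as.numeric(w)),
      b = as.numeric(b)
    ),
    class = "nb_logistic_params"
  )
}

#' @export
print.nb_logistic_params <- function(x, ...) {
  cat(sprintf("<nb_logistic_params: %d features, intercept b = %.4g>\n",
              nrow(x$coef), x$b))
  print(x$coef, ...)
  invisible(x)
}

#' @describeIn logistic_params Read a parameter set from JSON (fields
#'   `feature_names`, `mu`, `sigma`, `w`, `b`).
#' @param path JSON file path.
#' @export
read_logistic_params <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic_params(j$feature_names, j$mu, j$sigma, j$w, j$b)
}

#' @describeIn logistic_params Write a parameter set to JSON.
#' @param params An `nb_logistic_params` object.
#' @export
write_logistic_params <- function(params, path) {
  jsonlite::write_json(
    list(feature_names = params$coef$feature, mu = params$coef$mu,
         sigma = params$coef$sigma, w = params$coef$w, b = params$b),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

pkg_extdata <- function(file) {
  system.file("extdata", file, package = "nbblueprint", mustWork = TRUE)
}

.nb_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (!exists(key, envir = .nb_cache)) assign(key, fn(), envir = .nb_cache)
  get(key, envir = .nb_cache)
}

#' Packaged structure-classifier parameters
#'
#' The published parameterization of the logistic structure classifier:
#' standardization means/SDs and weights for the six blueprint descriptors,
#' intercept `b = -0.352`, fitted on 100 manually labelled VHH structures.
#'
#' @return An `nb_logistic_params` object with features in canonical order
#'   (`alpha_n`, `tau_n`, `alpha_c`, `tau_c`, `contact_density`,
#'   `fr2_rsa_key`).
#' @export
nbframe_structure_params <- function() {
  cached("structure_params",
         function() read_logistic_params(pkg_extdata("nbframe_structure_params.json")))
}

#' Packaged sequence-hallmark table
#'
#' The 20 framework (AHo position, amino acid) hallmarks of the kinked /
#' extended dichotomy, with their log2 fold-change enrichment, two-sided
#' Fisher p-value, and per-class carrier percentages (478 kinked, 351
#' extended training structures; N = 829).
#'
#' @return A tibble with columns `region`, `position`, `aa`, `log2fc`,
#'   `p_value`, `pct_kinked`, `pct_extended`.
#' @export
nbframe_hallmarks <- function() {
  cached("hallmarks", function() {
    tb <- utils::read.table(pkg_extdata("nbframe_hallmarks.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    tibble::as_tibble(tb)
  })
}

#' Reference sequence-classifier parameters (synthetic fit)
#'
#' The published work does not print the fitted weights of the sequence
#' classifier. This parameter set was fitted with [fit_soft_label_logistic()]
#' on a synthetic, seeded training set generated by
#' [sample_hallmark_dataset()]; it demonstrates the file format and pipeline
#' and is NOT the original model's parameterization.
#'
#' @return An `nb_logistic_params` object with 20 features named
#'   `region/position/aa` in the order of [nbframe_hallmarks()].
#' @export
nbframe_sequence_params_synthetic <- function() {
  cached("sequence_params",
         function() read_logistic_params(pkg_extdata("nbframe_sequence_params_synthetic.json")))
}

#' Packaged per-element van der Waals radii
#'
#' A single per-element radii set used by the built-in SASA routine, shipped
#' as an editable TSV. Values (Angstrom): C 1.70, N 1.55, O 1.52, S 1.80,
#' P 1.80, H 1.20.
#'
#' @return Named numeric vector (element symbol to radius).
#' @export
element_radii <- function() {
  cached("radii", function() {
    tb <- utils::read.table(pkg_extdata("element_radii.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    stats::setNames(tb$radius, tb$element)
  })
}

#' Theoretical maximum ASA (Gly-X-Gly)
#'
#' Theoretical maximum accessible surface areas per residue type, from
#' exhaustive conformational sampling of Gly-X-Gly tripeptides (Tien et al.
#' 2013, "theoretical" column), used to normalize SASA into relative solvent
#' accessibility.
#'
#' @return Named numeric vector (one-letter residue code to Angstrom^2).
#' @export
max_asa_gxg <- function() {
  cached("max_asa", function() {
    tb <- utils::read.table(pkg_extdata("max_asa_gxg.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
    stats::setNames(tb$max_asa, tb$aa)
  })
}
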