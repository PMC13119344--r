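BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets, via the SVD of the cross-covariance matrix with the
#' usual determinant correction.
#'
#' @param ref_atoms,mov_atoms Paired coordinates: n x 3 matrices or data
#'   frames with `x`, `y`, `z` columns (row k of one pairs with row k of the
#'   other).
#' @return A list of class `nb_superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `rmsd` (of the paired atoms after fitting),
#'   `n_atoms`. The transform maps moving coordinates as
#'   `x %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(ref_atoms, mov_atoms) {
  p <- as_point_matrix(ref_atoms, "ref_atoms")
  q <- as_point_matrix(mov_atoms, "mov_atoms")
  if (nrow(p) != nrow(q)) rlang::abort("point sets must pair one-to-one")
  if (nrow(p) < 3L) rlang::abort("need at least 3 paired atoms")
  cp <- colMeans(p); cq <- colMeans(q)
  p0 <- sweep(p, 2, cp); q0 <- sweep(q, 2, cq)
  if (min(svd(p0)$d) < 1e-9 * max(svd(p0)$d)) {
    rlang::abort("degenerate (collinear) reference point set")
  }
  h <- crossprod(q0, p0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  trans <- cp - drop(rot %*% cq)
  fitted <- q %*% t(rot) + matrix(trans, nrow(q), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((fitted - p)^2)))
  structure(list(rotation = rot, translation = trans, rmsd = rmsd,
                 n_atoms = nrow(p)),
            class = "nb_superposition")
}

#' @export
print.nb_superposition <- function(x, ...) {
  cat(sprintf("<nb_superposition: %d atoms, RMSD = %.4g Angstrom>\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

# shared backbone atoms between two structures, as paired coordinate tables
paired_backbone <- function(ref, pred, positions, atoms = BACKBONE_ATOMS) {
  r <- ref[ref$aho %in% positions & ref$atom %in% atoms, , drop = FALSE]
  p <- pred[pred$aho %in% positions & pred$atom %in% atoms, , drop = FALSE]
  key_r <- paste(r$aho, r$atom)
  key_p <- paste(p$aho, p$atom)
  shared <- intersect(key_r, key_p)
  list(
    ref = r[match(shared, key_r), , drop = FALSE],
    pred = p[match(shared, key_p), , drop = FALSE]
  )
}

fr_positions <- function() {
  unlist(lapply(c("FR1", "FR2", "FR3", "FR4"), aho_positions_of))
}

#' Region-stratified backbone RMSD after framework superposition
#'
#' Superposes the prediction onto the reference on the shared framework
#' backbone atoms (N, CA, C, O), then reports the RMSD of each requested
#' region's shared backbone atoms under that single framework-fitted
#' transform (no per-region refitting). `"All"` covers every shared backbone
#' atom; `"FR"` is the framework itself and equals the superposition RMSD.
#'
#' @param ref,pred Atom tibbles for one reference and one predicted
#'   structure.
#' @param regions Character vector of regions to report; any of `"All"`,
#'   `"FR"`, `"HCDR1"`, `"HCDR2"`, `"HCDR3"` (or the individual FR/CDR
#'   labels).
#' @param atoms Backbone atom names used throughout.
#' @return Tibble with columns `region`, `rmsd` (Angstrom), `n_atoms`.
#' @export
region_rmsd <- function(ref, pred,
                        regions = c("All", "FR", "HCDR1", "HCDR2", "HCDR3"),
                        atoms = BACKBONE_ATOMS) {
  validate_atoms(ref); validate_atoms(pred)
  fr <- paired_backbone(ref, pred, fr_positions(), atoms)
  if (nrow(fr$ref) < 3L) rlang::abort("too few shared framework backbone atoms")
  sup <- kabsch_superpose(fr$ref, fr$pred)
  pred_fit <- transform_atoms(pred, sup$rotation, sup$translation)
  one <- function(region) {
    positions <- switch(region,
      All = 1:AHO_LENGTH,
      FR = fr_positions(),
      aho_positions_of(region)
    )
    pr <- paired_backbone(ref, pred_fit, positions, atoms)
    if (nrow(pr$ref) == 0L) {
      rlang::abort(sprintf("no shared backbone atoms in region %s", region))
    }
    dx <- pr$ref$x - pr$pred$x
    dy <- pr$ref$y - pr$pred$y
    dz <- pr$ref$z - pr$pred$z
    tibble::tibble(region = region,
                   rmsd = sqrt(mean(dx^2 + dy^2 + dz^2)),
                   n_atoms = nrow(pr$ref))
  }
  dplyr::bind_rows(lapply(regions, one))
}

#' Blueprint-bin agreement between reference and prediction
#'
#' Bins each probability with [call_blueprint()] and measures the fraction
#' of pairs landing in the same bin. By default pairs whose *reference* bin
#' is unclear are excluded from the headline recovery percentage (reported
#' separately); set `include_unclear_ref = TRUE` to count them.
#'
#' @param ref_probs,pred_probs Paired kinked probabilities.
#' @param scheme Threshold scheme for [call_blueprint()]; evaluation
#'   thresholds by default.
#' @param include_unclear_ref Count pairs with an unclear reference bin in
#'   the recovery percentage?
#' @return A list of class `nb_blueprint_recovery`: `recovery_pct`,
#'   `n_scored`, `n_unclear_ref`, `confusion` (3 x 3 tibble), `calls`
#'   (per-pair tibble).
#' @export
blueprint_recovery <- function(ref_probs, pred_probs, scheme = "evaluation",
                               include_unclear_ref = FALSE) {
  if (length(ref_probs) != length(pred_probs)) {
    rlang::abort("`ref_probs` and `pred_probs` must pair one-to-one")
  }
  bins <- c("kinked", "extended", "unclear")
  rb <- call_blueprint(ref_probs, scheme)
  pb <- call_blueprint(pred_probs, scheme)
  calls <- tibble::tibble(ref_bin = rb, pred_bin = pb, match = rb == pb)
  scored <- if (include_unclear_ref) calls else calls[calls$ref_bin != "unclear", ]
  confusion <- as.data.frame(table(
    ref = factor(rb, bins), pred = factor(pb, bins)
  ), responseName = "n")
  structure(
    list(
      recovery_pct = 100 * mean(scored$match),
      n_scored = nrow(scored),
      n_unclear_ref = sum(calls$ref_bin == "unclear"),
      confusion = tibble::as_tibble(confusion),
      calls = calls
    ),
    class = "nb_blueprint_recovery"
  )
}

#' @export
print.nb_blueprint_recovery <- function(x, ...) {
  cat(sprintf("<nb_blueprint_recovery: %.1f%% over %d pair(s) (%d unclear ref)>\n",
              x$recovery_pct, x$n_scored, x$n_unclear_ref))
  invisible(x)
}

#' Structure-level NCDB recovery rate
#'
#' Fraction of structures whose every expected non-canonical disulphide pair
#' is recovered. Structures without a non-canonical pair are excluded (the
#' rate is defined over the NCDB-bearing subset).
#'
#' @param records A tibble with one row per expected pair across structures:
#'   columns `id`, `canonical`, `recovered` (e.g. row-bound outputs of
#'   [ncdb_recovered()] with an `id` column).
#' @return A list: `rate_pct` (structure-level, all-pairs rule), `n_structures`,
#'   `n_recovered`, `pair_rate_pct` (per-pair rate over non-canonical pairs).
#' @export
ncdb_recovery_rate <- function(records) {
  nc <- records[!records$canonical, , drop = FALSE]
  if (nrow(nc) == 0L) rlang::abort("no non-canonical pairs in `records`")
  per_struct <- tapply(nc$recovered, nc$id, all)
  list(
    rate_pct = 100 * mean(per_struct),
    n_structures = length(per_struct),
    n_recovered = sum(per_struct),
    pair_rate_pct = 100 * mean(nc$recovered)
  )
}

#' Percentile bootstrap CI for the median
#'
#' @param values Numeric vector.
#' @param n_boot Number of bootstrap resamples (default 10000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for reproducibility (local RNG state).
#' @return One-row tibble: `median`, `lo`, `hi`, `n`, `n_boot`, `level`.
#' @export
bootstrap_median_ci <- function(values, n_boot = 10000L, level = 0.95,
                                seed = NULL) {
  if (length(values) == 0L) rlang::abort("`values` must be non-empty")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  n <- length(values)
  meds <- vapply(seq_len(n_boot), function(b) {
    stats::median(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(meds, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(median = stats::median(values), lo = qs[1], hi = qs[2],
                 n = n, n_boot = n_boot, level = level)
}

#' Mean-HCDR3-confidence filter
#'
#' Passes a structure when the mean per-residue confidence (pLDDT, on 0-1)
#' over its HCDR3 residues is at least `threshold` (default 0.7).
#'
#' @param scores Tibble with columns `aho`, `plddt` (scores in `[0, 1]`), or
#'   a named numeric vector (names = AHo positions).
#' @param threshold Minimum mean HCDR3 confidence.
#' @return Logical scalar.
#' @export
hcdr3_plddt_filter <- function(scores, threshold = 0.7) {
  if (!is.data.frame(scores)) {
    scores <- tibble::tibble(aho = as.integer(names(scores)),
                             plddt = as.numeric(scores))
  }
  hc <- scores[scores$aho %in% aho_positions_of("HCDR3"), , drop = FALSE]
  if (nrow(hc) == 0L) rlang::abort("no HCDR3 confidence scores supplied")
  mean(hc$plddt) >= threshold
}

#' Peptide-bond violations
#'
#' Flags consecutive occupied AHo positions whose C(i)-N(i+1) distance
#' deviates from the ideal peptide bond (1.33 Angstrom) by more than `tol`.
#' Gaps in AHo occupancy are chain breaks and are skipped.
#'
#' @param atoms Atom tibble (single structure) with C and N backbone atoms.
#' @param ideal Ideal C-N bond length in Angstrom.
#' @param tol Allowed absolute deviation.
#' @return Tibble of violations: `pos_i`, `pos_j`, `dist`.
#' @export
peptide_bond_violations <- function(atoms, ideal = 1.33, tol = 0.3) {
  validate_atoms(atoms)
  occupied <- sort(unique(atoms$aho))
  out <- list()
  for (k in seq_len(length(occupied) - 1L)) {
    i <- occupied[k]; j <- occupied[k + 1L]
    if (j != i + 1L) next  # chain break
    cat_ <- atoms[atoms$aho == i & atoms$atom == "C", , drop = FALSE]
    nat <- atoms[atoms$aho == j & atoms$atom == "N", , drop = FALSE]
    if (nrow(cat_) == 0L || nrow(nat) == 0L) {
      rlang::abort(sprintf("missing backbone atom between AHo %d and %d", i, j))
    }
    d <- sqrt((cat_$x[1] - nat$x[1])^2 + (cat_$y[1] - nat$y[1])^2 +
                (cat_$z[1] - nat$z[1])^2)
    if (abs(d - ideal) > tol) {
      out[[length(out) + 1L]] <- tibble::tibble(pos_i = i, pos_j = j, dist = d)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(pos_i = integer(), pos_j = integer(),
                          dist = numeric()))
  }
  dplyr::bind_rows(out)
}
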