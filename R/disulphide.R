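#' Disulphide-geometry scoring configuration
#'
#' All band, target and width constants plus term weights for the composite
#' disulphide objective. Defaults are the published values; every constant
#' can be overridden.
#'
#' @param sg_band Bonded SG-SG distance band in Angstrom.
#' @param repulsion_min Minimum allowed SG-SG distance for non-bonded pairs.
#' @param cb_band Bonded CB-CB distance band.
#' @param candidate_band Ground-truth SG-SG range defining bond candidates.
#' @param theta_star Target S-S-CB angle (radians).
#' @param huber_delta Huber transition parameter for the angle term.
#' @param chi3_modes The two canonical chi3 rotamer modes (radians).
#' @param chi3_sigma Width of the wrapped-Gaussian chi3 penalty (radians).
#' @param disto_bins Number of distogram bins.
#' @param disto_target_distance SG-SG distance (Angstrom) whose bin is the
#'   distogram target.
#' @param disto_breaks Bin edges; defaults to 64 equal-width bins over
#'   `[2.3125, 21.6875]` Angstrom with open outer bins.
#' @param weights Named term weights (`sg`, `cb`, `ang`, `chi3`, `disto`).
#' @param anneal_steps Number of training steps over which the annealing
#'   factor ramps linearly from 0 to 1.
#' @return A list of class `nb_disulphide_config`.
#' @export
disulphide_config <- function(sg_band = c(1.84, 2.26),
                              repulsion_min = 4.1,
                              cb_band = c(2.85, 4.50),
                              candidate_band = c(1.42, 3.00),
                              theta_star = 2.0,
                              huber_delta = 0.04,
                              chi3_modes = c(1.66012, -1.79512),
                              chi3_sigma = 0.50,
                              disto_bins = 64L,
                              disto_target_distance = 2.05,
                              disto_breaks = NULL,
                              weights = c(sg = 0.5, cb = 0.25,
                                          ang = 1e-4, chi3 = 1e-4,
                                          disto = 1.0),
                              anneal_steps = 100000L) {
  stopifnot(sg_band[1] < sg_band[2], cb_band[1] < cb_band[2],
            candidate_band[1] < candidate_band[2], chi3_sigma > 0,
            all(weights >= 0), anneal_steps > 0)
  if (is.null(disto_breaks)) {
    disto_breaks <- seq(2.3125, 21.6875, length.out = disto_bins + 1L)
    disto_breaks[1] <- -Inf
    disto_breaks[disto_bins + 1L] <- Inf
  }
  if (length(disto_breaks) != disto_bins + 1L) {
    rlang::abort("`disto_breaks` must have `disto_bins + 1` edges")
  }
  structure(
    list(sg_band = sg_band, repulsion_min = repulsion_min, cb_band = cb_band,
         candidate_band = candidate_band, theta_star = theta_star,
         huber_delta = huber_delta, chi3_modes = chi3_modes,
         chi3_sigma = chi3_sigma, disto_bins = as.integer(disto_bins),
         disto_target_distance = disto_target_distance,
         disto_breaks = disto_breaks, weights = weights,
         anneal_steps = anneal_steps),
    class = "nb_disulphide_config"
  )
}

as_point_matrix <- function(x, what) {
  m <- if (is.data.frame(x)) as.matrix(x[, c("x", "y", "z")]) else as.matrix(x)
  if (is.null(dim(m)) || ncol(m) != 3L) {
    rlang::abort(sprintf("`%s` must be an n x 3 coordinate matrix", what))
  }
  if (any(!is.finite(m))) rlang::abort(sprintf("non-finite coordinates in `%s`", what))
  m
}

pair_dist <- function(m, i, j) sqrt(sum((m[i, ] - m[j, ])^2))

#' Greedy selection of bonded cysteine pairs
#'
#' Enumerates all cysteine pairs `i < j`; pairs with ground-truth SG-SG
#' distance inside the candidate band (default `[1.42, 3.00]` Angstrom) are
#' bond candidates. Candidates are accepted greedily in ascending distance
#' order (ties: lower residue-index pair), skipping any pair that shares a
#' cysteine with an accepted bond. All remaining pairs form the non-bonded
#' complement.
#'
#' @param gt_sg Ground-truth SG coordinates: an n x 3 matrix or a data frame
#'   with `x`, `y`, `z` columns.
#' @param cfg A [disulphide_config()].
#' @return A list of class `nb_pairing`: `bonded` and `nonbonded` tibbles
#'   (`i`, `j`, `dist`), and `n` (number of cysteines).
#' @export
select_bonded_pairs <- function(gt_sg, cfg = disulphide_config()) {
  m <- if (length(gt_sg) == 0L) matrix(numeric(), 0, 3) else as_point_matrix(gt_sg, "gt_sg")
  n <- nrow(m)
  empty <- tibble::tibble(i = integer(), j = integer(), dist = numeric())
  if (n < 2L) {
    return(structure(list(bonded = empty, nonbonded = empty, n = n),
                     class = "nb_pairing"))
  }
  idx <- utils::combn(n, 2)
  d <- apply(idx, 2, function(ij) pair_dist(m, ij[1], ij[2]))
  pairs <- tibble::tibble(i = idx[1, ], j = idx[2, ], dist = d)
  cand <- pairs[d >= cfg$candidate_band[1] & d <= cfg$candidate_band[2], ,
                drop = FALSE]
  cand <- cand[order(cand$dist, cand$i, cand$j), , drop = FALSE]
  used <- logical(n)
  take <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used[cand$i[r]] && !used[cand$j[r]]) {
      take[r] <- TRUE
      used[cand$i[r]] <- TRUE
      used[cand$j[r]] <- TRUE
    }
  }
  bonded <- cand[take, , drop = FALSE]
  key <- paste(pairs$i, pairs$j)
  nonbonded <- pairs[!key %in% paste(bonded$i, bonded$j), , drop = FALSE]
  structure(list(bonded = bonded, nonbonded = nonbonded, n = n),
            class = "nb_pairing")
}

#' @export
print.nb_pairing <- function(x, ...) {
  cat(sprintf("<nb_pairing: %d cysteines, %d bonded pair(s), %d non-bonded>\n",
              x$n, nrow(x$bonded), nrow(x$nonbonded)))
  invisible(x)
}

hinge_band <- function(d, lo, hi) pmax(d - hi, 0) + pmax(lo - d, 0)

#' SG-SG distance band loss
#'
#' Bonded pairs are hinged into the band `[1.84, 2.26]` Angstrom; non-bonded
#' pairs are repelled to at least 4.1 Angstrom.
#'
#' @param pred_sg Predicted SG coordinates, indexed like the ground truth
#'   used for pairing.
#' @param pairing An `nb_pairing` from [select_bonded_pairs()].
#' @param cfg A [disulphide_config()].
#' @return Scalar loss.
#' @export
sg_band_loss <- function(pred_sg, pairing, cfg = disulphide_config()) {
  m <- as_point_matrix(pred_sg, "pred_sg")
  check_pairing_index(pairing, nrow(m))
  b <- pairing$bonded
  nb <- pairing$nonbonded
  db <- vapply(seq_len(nrow(b)), function(r) pair_dist(m, b$i[r], b$j[r]), numeric(1))
  dn <- vapply(seq_len(nrow(nb)), function(r) pair_dist(m, nb$i[r], nb$j[r]), numeric(1))
  sum(hinge_band(db, cfg$sg_band[1], cfg$sg_band[2])) +
    sum(pmax(cfg$repulsion_min - dn, 0))
}

#' CB-CB distance band loss
#'
#' Flat-bottom hinge on the predicted CB-CB distance of bonded pairs,
#' band `[2.85, 4.50]` Angstrom.
#'
#' @param pred_cb Predicted CB coordinates.
#' @inheritParams sg_band_loss
#' @return Scalar loss.
#' @export
cb_band_loss <- function(pred_cb, pairing, cfg = disulphide_config()) {
  m <- as_point_matrix(pred_cb, "pred_cb")
  check_pairing_index(pairing, nrow(m))
  b <- pairing$bonded
  r <- vapply(seq_len(nrow(b)), function(k) pair_dist(m, b$i[k], b$j[k]), numeric(1))
  sum(hinge_band(r, cfg$cb_band[1], cfg$cb_band[2]))
}

huber <- function(z, delta) {
  az <- abs(z)
  ifelse(az <= delta, 0.5 * z^2, delta * (az - 0.5 * delta))
}

#' S-S-CB bond angle loss
#'
#' For each bonded pair, the two angles at the sulphurs (between the own CB
#' and the partner SG) are pulled toward 2.0 rad with a Huber penalty
#' (transition 0.04 rad).
#'
#' @param pred_sg,pred_cb Predicted SG and CB coordinates (aligned indices).
#' @inheritParams sg_band_loss
#' @return Scalar loss.
#' @export
ss_cb_angle_loss <- function(pred_sg, pred_cb, pairing,
                             cfg = disulphide_config()) {
  s <- as_point_matrix(pred_sg, "pred_sg")
  cb <- as_point_matrix(pred_cb, "pred_cb")
  check_pairing_index(pairing, nrow(s))
  if (nrow(cb) != nrow(s)) rlang::abort("SG and CB tables must align")
  b <- pairing$bonded
  total <- 0
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    th_i <- pseudo_bond_angle(cb[i, ], s[i, ], s[j, ]) * pi / 180
    th_j <- pseudo_bond_angle(s[i, ], s[j, ], cb[j, ]) * pi / 180
    total <- total + huber(th_i - cfg$theta_star, cfg$huber_delta) +
      huber(th_j - cfg$theta_star, cfg$huber_delta)
  }
  total
}

#' chi3 dihedral loss
#'
#' Bimodal wrapped-Gaussian negative log-likelihood of the disulphide chi3
#' dihedral (CB_i, SG_i, SG_j, CB_j) around the two canonical rotamer modes
#' (+1.66012 and -1.79512 rad, width 0.50 rad).
#'
#' @inheritParams ss_cb_angle_loss
#' @return Scalar loss (bounded below by `-log 2`).
#' @export
chi3_loss <- function(pred_sg, pred_cb, pairing, cfg = disulphide_config()) {
  s <- as_point_matrix(pred_sg, "pred_sg")
  cb <- as_point_matrix(pred_cb, "pred_cb")
  check_pairing_index(pairing, nrow(s))
  b <- pairing$bonded
  total <- 0
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    phi <- pseudo_torsion(cb[i, ], s[i, ], s[j, ], cb[j, ], degrees = FALSE)
    total <- total + chi3_nll(phi, cfg)
  }
  total
}

chi3_nll <- function(phi, cfg) {
  z <- wrap_angle(phi - cfg$chi3_modes) / cfg$chi3_sigma
  -log(sum(exp(-0.5 * z^2)))
}

#' Distogram cross-entropy loss for bonded cysteine pairs
#'
#' Symmetric cross-entropy between predicted distance-bin logits and a
#' one-hot target at the bin containing 2.05 Angstrom, summed over both
#' orders of each bonded pair.
#'
#' @param logits A function `(i, j)` returning the 64-vector of logits for
#'   the ordered pair, or a 3-D array `[i, j, bin]`.
#' @inheritParams sg_band_loss
#' @return Scalar loss.
#' @export
distogram_loss <- function(logits, pairing, cfg = disulphide_config()) {
  get_logits <- if (is.function(logits)) {
    logits
  } else {
    arr <- logits
    function(i, j) arr[i, j, ]
  }
  target_bin <- findInterval(cfg$disto_target_distance, cfg$disto_breaks,
                             rightmost.closed = TRUE)
  b <- pairing$bonded
  total <- 0
  for (r in seq_len(nrow(b))) {
    for (ij in list(c(b$i[r], b$j[r]), c(b$j[r], b$i[r]))) {
      l <- get_logits(ij[1], ij[2])
      if (length(l) != cfg$disto_bins) {
        rlang::abort(sprintf("expected %d logits, got %d", cfg$disto_bins,
                             length(l)))
      }
      total <- total + (log(sum(exp(l - max(l)))) + max(l) - l[target_bin])
    }
  }
  total
}

check_pairing_index <- function(pairing, n) {
  if (!inherits(pairing, "nb_pairing")) rlang::abort("`pairing` must come from select_bonded_pairs()")
  if (pairing$n != n) {
    rlang::abort(sprintf("pairing indexes %d cysteines but %d coordinates supplied",
                         pairing$n, n))
  }
}

#' Composite annealed disulphide objective
#'
#' Pairs cysteines on the ground-truth SG coordinates, evaluates all five
#' geometry terms on the prediction, combines them as
#' `0.5 L_SG + 0.25 L_CB + 1e-4 (L_ang + L_chi3) + 1 L_disto`, and scales by
#' the annealing factor `min(step / anneal_steps, 1)`.
#'
#' @param pred_sg,pred_cb Predicted SG / CB coordinates (one row per
#'   cysteine, aligned with `gt_sg`).
#' @param gt_sg Ground-truth SG coordinates (defines the pairing).
#' @param logits Optional distogram logits (see [distogram_loss()]); the
#'   distogram term is dropped when `NULL`.
#' @param step Training step (controls annealing; `step >= anneal_steps`
#'   gives factor 1).
#' @param cfg A [disulphide_config()].
#' @return A list of class `nb_disulphide_report`: `total` (annealed),
#'   `anneal`, `terms` (unannealed per-term tibble), `pairing`.
#' @export
total_disulphide_loss <- function(pred_sg, pred_cb, gt_sg, logits = NULL,
                                  step = Inf, cfg = disulphide_config()) {
  if (step < 0) rlang::abort("`step` must be >= 0")
  pairing <- select_bonded_pairs(gt_sg, cfg)
  terms <- c(
    sg = sg_band_loss(pred_sg, pairing, cfg),
    cb = cb_band_loss(pred_cb, pairing, cfg),
    ang = ss_cb_angle_loss(pred_sg, pred_cb, pairing, cfg),
    chi3 = chi3_loss(pred_sg, pred_cb, pairing, cfg),
    disto = if (is.null(logits)) 0 else distogram_loss(logits, pairing, cfg)
  )
  anneal <- min(step / cfg$anneal_steps, 1)
  total <- anneal * sum(cfg$weights[names(terms)] * terms)
  structure(
    list(total = total, anneal = anneal,
         terms = tibble::tibble(term = names(terms), loss = unname(terms),
                                weight = unname(cfg$weights[names(terms)])),
         pairing = pairing),
    class = "nb_disulphide_report"
  )
}

#' @export
print.nb_disulphide_report <- function(x, ...) {
  cat(sprintf("<nb_disulphide_report: total = %.6g (anneal %.3g)>\n",
              x$total, x$anneal))
  print(x$terms, ...)
  invisible(x)
}

sg_coords <- function(atoms, positions) {
  out <- matrix(NA_real_, length(positions), 3)
  for (k in seq_along(positions)) {
    row <- atoms[atoms$aho == positions[k] & atoms$atom == "SG", , drop = FALSE]
    if (nrow(row) > 0L) out[k, ] <- c(row$x[1], row$y[1], row$z[1])
  }
  out
}

#' Expected disulphide pairs of a reference structure
#'
#' Runs the greedy pairing on the reference's cysteine SG atoms, keeping
#' pairs with SG-SG distance below `max_dist` (default 3 Angstrom). The
#' conserved canonical pair (AHo 23-106) is flagged; every other pair is a
#' non-canonical disulphide bond.
#'
#' @param atoms Reference atom tibble (single structure).
#' @param max_dist Maximum SG-SG distance retained for evaluation.
#' @return Tibble with columns `pos_i`, `pos_j` (AHo positions), `dist`,
#'   `canonical`.
#' @export
extract_expected_pairs <- function(atoms, max_dist = 3.0) {
  validate_atoms(atoms)
  cys <- sort(unique(atoms$aho[atoms$aa == "C"]))
  sg <- sg_coords(atoms, cys)
  present <- stats::complete.cases(sg)
  cys <- cys[present]
  sg <- sg[present, , drop = FALSE]
  cfg <- disulphide_config(candidate_band = c(1.42, max_dist))
  pairing <- select_bonded_pairs(sg, cfg)
  b <- pairing$bonded[pairing$bonded$dist < max_dist, , drop = FALSE]
  tibble::tibble(
    pos_i = cys[b$i], pos_j = cys[b$j], dist = b$dist,
    canonical = cys[b$i] == 23L & cys[b$j] == 106L
  )
}

#' Check recovery of expected disulphide pairs in a prediction
#'
#' A pair counts as recovered when the predicted SG-SG distance is at most
#' `threshold` (default 2.46 Angstrom, the 99th percentile of experimental
#' disulphide SG-SG distances). A missing SG atom is a violation and the
#' pair is not recovered.
#'
#' @param pred Predicted atom tibble (single structure).
#' @param expected_pairs Tibble with columns `pos_i`, `pos_j` (e.g. from
#'   [extract_expected_pairs()] on the reference).
#' @param threshold Recovery distance threshold in Angstrom.
#' @return The `expected_pairs` tibble with added `pred_dist`, `recovered`,
#'   `violation` columns.
#' @export
ncdb_recovered <- function(pred, expected_pairs, threshold = 2.46) {
  validate_atoms(pred)
  sg_i <- sg_coords(pred, expected_pairs$pos_i)
  sg_j <- sg_coords(pred, expected_pairs$pos_j)
  d <- sqrt(rowSums((sg_i - sg_j)^2))
  expected_pairs$pred_dist <- d
  expected_pairs$violation <- !is.finite(d)
  expected_pairs$recovered <- is.finite(d) & d <= threshold
  expected_pairs
}
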