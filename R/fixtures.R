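# Seeded generators for every input the rest of the package consumes.
# Fixtures are geometric idealizations that exercise code paths, not
# physically relaxed structures: sidechains are single pseudo-atoms, and
# disulphide sulphurs are placed to realize requested distances exactly.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  force(code)
}

#' Synthetic C-alpha stem trace with prescribed pseudo-angles
#'
#' Builds four C-alpha atoms at the given AHo window positions whose
#' measured pseudo-torsion equals `alpha` and whose pseudo-bond angle over
#' the first three positions equals `tau`, to 1e-6 degrees. With a `seed`,
#' the trace is additionally subjected to a random rigid transform (same
#' angles, different embedding).
#'
#' @param alpha Pseudo-torsion in degrees, in `(-180, 180]`.
#' @param tau Pseudo-bond angle in degrees, strictly inside `(0, 180)`.
#' @param anchor Four consecutive AHo positions (default the N-terminal stem
#'   window 105:108).
#' @param bond Consecutive C-alpha spacing in Angstrom (default 3.8).
#' @param seed Optional seed for a random embedding.
#' @param id Structure id.
#' @return An atom tibble with four CA rows.
#' @export
make_stem_trace <- function(alpha, tau, anchor = 105:108, bond = 3.8,
                            seed = NULL, id = "stem_trace") {
  if (length(anchor) != 4L) rlang::abort("`anchor` must name four positions")
  if (!is.finite(tau) || tau <= 0 || tau >= 180) {
    rlang::abort("`tau` must lie strictly inside (0, 180): the torsion is degenerate otherwise")
  }
  tau_r <- tau * pi / 180
  p1 <- c(0, 0, 0)
  p2 <- c(bond, 0, 0)
  p3 <- p2 + bond * c(-cos(tau_r), sin(tau_r), 0)
  p4 <- place_internal(p1, p2, p3, bond, 109.5 * pi / 180, alpha * pi / 180)
  xyz <- rbind(p1, p2, p3, p4)
  if (!is.null(seed)) {
    xyz <- with_seed(seed, {
      rot <- random_rotation()
      sweep(xyz %*% t(rot), 2, stats::rnorm(3, sd = 10), "+")
    })
  }
  tibble::tibble(
    id = id, aho = as.integer(anchor), aa = "G", atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

#' Ideal disulphide geometry with prescribed descriptors
#'
#' Places the SG and CB atoms of a cysteine pair so that the SG-SG distance
#' is `d_sg`, both S-S-CB angles equal `theta`, the chi3 dihedral equals
#' `chi3`, and the CB-CB distance equals `r_cb` (all to 1e-6). The free
#' parameter absorbed to satisfy `r_cb` is the (shared) CB-SG bond length,
#' solved numerically; an unreachable combination errors.
#'
#' @param d_sg SG-SG distance, Angstrom.
#' @param r_cb CB-CB distance, Angstrom.
#' @param theta S-S-CB angle at both sulphurs, radians, in `(0, pi)`.
#' @param chi3 CB-SG-SG-CB dihedral, radians.
#' @return A list: `sg` (2 x 3 matrix), `cb` (2 x 3), `bond` (the solved
#'   CB-SG length).
#' @export
make_ideal_disulphide <- function(d_sg = 2.05, r_cb = 3.8, theta = 2.0,
                                  chi3 = 1.66012) {
  if (d_sg <= 0) rlang::abort("`d_sg` must be positive")
  if (theta <= 0 || theta >= pi) rlang::abort("`theta` must lie in (0, pi)")
  s_i <- c(0, 0, 0)
  s_j <- c(d_sg, 0, 0)
  geom <- function(b) {
    c_i <- b * c(cos(theta), sin(theta), 0)
    c_j <- place_internal(c_i, s_i, s_j, b, theta, chi3)
    list(c_i = c_i, c_j = c_j, r = sqrt(sum((c_i - c_j)^2)))
  }
  f <- function(b) geom(b)$r - r_cb
  lo <- 1e-3; hi <- 50
  if (f(lo) * f(hi) > 0) {
    rlang::abort("inconsistent parameter combination: requested r_cb unreachable")
  }
  b <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  g <- geom(b)
  list(sg = rbind(s_i, s_j), cb = rbind(g$c_i, g$c_j), bond = b)
}

# march along a serpentine: 14 residues per row (FR2 = row 4 exactly),
# rows `row_gap` apart, alternating direction; returns CA coordinates
serpentine_ca <- function(positions, spacing = 3.8, row_gap = 5.4) {
  per_row <- 14L
  row <- (positions - 1L) %/% per_row
  col <- (positions - 1L) %% per_row
  x <- ifelse(row %% 2L == 0L, spacing * col, spacing * (per_row - 1L - col))
  cbind(x, row_gap * row, 0)
}

# backbone + CB atoms for a run of residues along given CA coordinates;
# C(i) and N(i+1) sit on the CA(i)->CA(i+1) segment so the peptide bond is
# exact wherever consecutive CAs are `spacing` apart
chain_atoms <- function(positions, ca, aa, cb_dir = c(0, 0, 1)) {
  n <- length(positions)
  rows <- list()
  for (k in seq_len(n)) {
    u_next <- if (k < n) {
      d <- ca[k + 1L, ] - ca[k, ]
      d / sqrt(sum(d^2))
    } else if (n > 1L) {
      d <- ca[k, ] - ca[k - 1L, ]
      d / sqrt(sum(d^2))
    } else c(1, 0, 0)
    u_prev <- if (k > 1L) {
      d <- ca[k, ] - ca[k - 1L, ]
      d / sqrt(sum(d^2))
    } else u_next
    npos <- ca[k, ] - 1.235 * u_prev
    cpos <- ca[k, ] + 1.235 * u_next
    opos <- cpos + c(0, 0, 1.23)
    cbpos <- ca[k, ] + 1.53 * cb_dir
    rows[[k]] <- tibble::tibble(
      aho = positions[k],
      aa = aa[k],
      atom = c("N", "CA", "C", "O", "CB"),
      element = c("N", "C", "C", "O", "C"),
      x = c(npos[1], ca[k, 1], cpos[1], opos[1], cbpos[1]),
      y = c(npos[2], ca[k, 2], cpos[2], opos[2], cbpos[2]),
      z = c(npos[3], ca[k, 3], cpos[3], opos[3], cbpos[3])
    )
  }
  dplyr::bind_rows(rows)
}

#' Synthetic toy VHH domain with a chosen blueprint
#'
#' Builds a self-consistent toy domain exercising the whole feature /
#' classifier / disulphide surface without real data. The framework (AHo
#' 1-104) is a serpentine C-alpha trace whose fourth row is exactly FR2
#' (AHo 43-56); the two HCDR3 stem windows carry the classifier's training-
#' mean pseudo-angles, so the blueprint call is driven by contact density
#' and FR2 burial, as in real kinked domains. The kinked variant caps FR2
#' positions 44-55 with the HCDR3 loop at contact range (4.1 Angstrom
#' vertically); the extended variant projects the loop away from the
#' framework. Cysteines sit at AHo 23/106 (canonical pair, SG atoms 2.05
#' Angstrom apart) and optionally at a requested non-canonical pair.
#'
#' The geometry is an idealization: sidechains are single CB pseudo-atoms,
#' disulphide SG atoms float at their requested separations, and the
#' serpentine's row turns are not peptide-bond-exact (straight runs are).
#'
#' @param blueprint `"kinked"` or `"extended"`.
#' @param ncdb Optional length-2 integer vector: AHo positions of an
#'   additional cysteine pair (anchor position, HCDR3 position), e.g.
#'   `c(57, 115)`.
#' @param hcdr3_len Number of HCDR3 residues (6 to 30); stem positions 108
#'   and 135-138 are always present, loop residues fill 110 upward.
#' @param seed Seed for the random rigid embedding (the fixture is
#'   bit-identical for a given argument set).
#' @return A list: `atoms` (atom tibble), `sequence` (one-row `id`/`seq`
#'   tibble).
#' @export
make_toy_vhh <- function(blueprint = c("kinked", "extended"), ncdb = NULL,
                         hcdr3_len = 12L, seed = 1L) {
  blueprint <- match.arg(blueprint)
  hcdr3_len <- as.integer(hcdr3_len)
  if (hcdr3_len < 6L || hcdr3_len > 30L) {
    rlang::abort("`hcdr3_len` must be between 6 and 30")
  }
  n_loop <- hcdr3_len - 5L  # 108 + loop + 135:138
  loop_pos <- seq(110L, by = 1L, length.out = n_loop)

  aa_of <- function(pos) {
    out <- rep("A", length(pos))
    out[pos %in% c(44L, 54L)] <- "F"
    out[pos %in% c(23L, 106L)] <- "C"
    if (!is.null(ncdb)) out[pos %in% ncdb] <- "C"
    out
  }

  # framework 1..104 serpentine
  fw_pos <- 1:104
  fw <- chain_atoms(fw_pos, serpentine_ca(fw_pos), aa_of(fw_pos))

  # stem windows carry the structure classifier's training-mean angles
  stem_ca <- function(alpha, tau, origin) {
    tr <- make_stem_trace(alpha, tau)
    sweep(as.matrix(tr[, c("x", "y", "z")]), 2, origin, "+")
  }
  stem_n <- chain_atoms(105:108, stem_ca(-62.09, 126.22, c(55, 37.8, 0)),
                        aa_of(105:108))
  stem_c <- chain_atoms(135:138, stem_ca(-13.31, 109.68, c(70, 37.8, 0)),
                        aa_of(135:138))

  # HCDR3 loop: cap over FR2 (kinked) or a distant strand (extended)
  fr2_ca <- serpentine_ca(44:55)
  loop_ca <- if (blueprint == "kinked") {
    idx <- ((seq_len(n_loop) - 1L) %% 12L) + 1L
    cbind(fr2_ca[idx, 1], fr2_ca[idx, 2], 4.1 + 0.3 * ((seq_len(n_loop) - 1L) %/% 12L))
  } else {
    cbind(3.8 * (seq_len(n_loop) - 1L), 60 + 5.4 * 0, 0)
  }
  loop_cb_dir <- if (blueprint == "kinked") c(0, 0, -1) else c(0, 0, 1)
  loop <- chain_atoms(loop_pos, loop_ca, aa_of(loop_pos), cb_dir = loop_cb_dir)

  atoms <- dplyr::bind_rows(fw, stem_n, loop, stem_c)

  # disulphide SG atoms: canonical pair 23-106, optional non-canonical pair
  add_sg <- function(atoms, pair, offset) {
    for (p in pair) {
      if (!p %in% atoms$aho) {
        rlang::abort(sprintf("NCDB position %d is not an occupied residue", p))
      }
      if (unique(atoms$aa[atoms$aho == p]) != "C") {
        rlang::abort(sprintf("NCDB position %d is not a cysteine", p))
      }
    }
    ca1 <- as.numeric(atoms[atoms$aho == pair[1] & atoms$atom == "CA",
                            c("x", "y", "z")])
    sg1 <- ca1 + offset
    sg2 <- sg1 + c(2.05, 0, 0)
    dplyr::bind_rows(atoms, tibble::tibble(
      aho = pair, aa = "C", atom = "SG", element = "S",
      x = c(sg1[1], sg2[1]), y = c(sg1[2], sg2[2]), z = c(sg1[3], sg2[3])
    ))
  }
  atoms <- add_sg(atoms, c(23L, 106L), c(0, 0, -2.0))
  if (!is.null(ncdb)) {
    if (length(ncdb) != 2L) rlang::abort("`ncdb` must name two AHo positions")
    atoms <- add_sg(atoms, as.integer(ncdb), c(0, 0, -3.5))
  }

  atoms$id <- paste0("toy_", blueprint)
  atoms <- atoms[, c("id", "aho", "aa", "atom", "element", "x", "y", "z")]
  atoms <- with_seed(seed, {
    rot <- random_rotation()
    transform_atoms(atoms, rot, stats::rnorm(3, sd = 5))
  })
  list(atoms = atoms, sequence = structure_sequence(atoms))
}

#' Seeded synthetic hallmark dataset
#'
#' Draws AHo-aligned sequences independently per position: planted
#' positions carry their amino acid with class-conditional carrier
#' frequencies `f_k` / `f_e` (non-carriers drawn uniformly from the rest of
#' the alphabet), all other positions uniformly from `background_alphabet`.
#' Structure-classifier probabilities are emitted label-correlated (0.9 for
#' kinked, 0.1 for extended, plus seeded Gaussian noise, clamped inside
#' (0, 1)).
#'
#' @param n_kinked,n_extended Class sizes.
#' @param planted Optional data frame with columns `position`, `aa`, `f_k`,
#'   `f_e`; positions must lie in framework regions.
#' @param background_alphabet Letters for unplanted positions (default all
#'   20 amino acids).
#' @param prob_noise SD of the noise on the emitted probabilities.
#' @param seed Seed; the dataset is bit-identical for a given argument set.
#' @return Tibble with columns `id`, `seq`, `label`, `p_struct`.
#' @export
sample_hallmark_dataset <- function(n_kinked, n_extended, planted = NULL,
                                    background_alphabet = AA1,
                                    prob_noise = 0.05, seed = 1L) {
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    if (any(planted$f_k < 0 | planted$f_k > 1 | planted$f_e < 0 | planted$f_e > 1)) {
      rlang::abort("planted frequencies must lie in [0, 1]")
    }
    if (!all(aho_region(planted$position) %in% FRAMEWORK_REGIONS)) {
      rlang::abort("planted positions must lie in framework regions")
    }
  }
  n <- n_kinked + n_extended
  label <- c(rep("kinked", n_kinked), rep("extended", n_extended))
  with_seed(seed, {
    m <- matrix(sample(background_alphabet, AHO_LENGTH * n, replace = TRUE),
                nrow = AHO_LENGTH)
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        p <- planted$position[r]
        f <- ifelse(label == "kinked", planted$f_k[r], planted$f_e[r])
        carrier <- stats::runif(n) < f
        other <- setdiff(background_alphabet, planted$aa[r])
        if (length(other) == 0L) other <- setdiff(AA1, planted$aa[r])
        m[p, ] <- ifelse(carrier, planted$aa[r],
                         sample(other, n, replace = TRUE))
      }
    }
    p_struct <- ifelse(label == "kinked", 0.9, 0.1) +
      stats::rnorm(n, sd = prob_noise)
    p_struct <- pmin(pmax(p_struct, 1e-3), 1 - 1e-3)
    tibble::tibble(
      id = paste0("s", seq_len(n)),
      seq = apply(m, 2, paste, collapse = ""),
      label = label,
      p_struct = p_struct
    )
  })
}

#' Perturb one region of a structure
#'
#' Produces a predicted-like copy of a reference structure: `rigid_shift`
#' displaces every atom of the region by exactly `magnitude` along a seeded
#' random direction; `per_atom_noise` adds seeded isotropic Gaussian noise
#' with root-mean-square displacement `magnitude` per atom.
#'
#' @param ref Reference atom tibble (single structure).
#' @param region Region label (`"FR1"`, ..., `"HCDR3"`, `"FR4"`), `"FR"` or
#'   `"All"`.
#' @param magnitude Displacement magnitude in Angstrom.
#' @param mode `"rigid_shift"` or `"per_atom_noise"`.
#' @param seed Seed; same seed, same output.
#' @return Perturbed atom tibble.
#' @export
perturb_structure <- function(ref, region, magnitude,
                              mode = c("rigid_shift", "per_atom_noise"),
                              seed = 1L) {
  mode <- match.arg(mode)
  validate_atoms(ref)
  positions <- switch(region,
    All = 1:AHO_LENGTH,
    FR = fr_positions(),
    aho_positions_of(region)
  )
  sel <- ref$aho %in% positions
  if (!any(sel)) rlang::abort(sprintf("region %s not present in structure", region))
  with_seed(seed, {
    if (mode == "rigid_shift") {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      ref$x[sel] <- ref$x[sel] + magnitude * u[1]
      ref$y[sel] <- ref$y[sel] + magnitude * u[2]
      ref$z[sel] <- ref$z[sel] + magnitude * u[3]
    } else {
      k <- sum(sel)
      sd1 <- magnitude / sqrt(3)
      ref$x[sel] <- ref$x[sel] + stats::rnorm(k, sd = sd1)
      ref$y[sel] <- ref$y[sel] + stats::rnorm(k, sd = sd1)
      ref$z[sel] <- ref$z[sel] + stats::rnorm(k, sd = sd1)
    }
    ref
  })
}
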