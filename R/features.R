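HCDR3_STEM_EXCLUDE <- c(108L, 109L, 136L, 137L, 138L)
FR2_CONTACT_RANGE <- 44:55
FR2_RSA_POSITIONS <- c(44L, 54L)
STEM_N_WINDOW <- 105:108
STEM_C_WINDOW <- 135:138

# pull one CA coordinate, with an error naming the missing position
ca_coord <- function(atoms, pos) {
  row <- atoms[atoms$aho == pos & atoms$atom == "CA", , drop = FALSE]
  if (nrow(row) == 0L) {
    rlang::abort(sprintf("missing CA atom at AHo position %d", pos))
  }
  c(row$x[1], row$y[1], row$z[1])
}

#' Stem pseudo-angles of the HCDR3 loop
#'
#' For each structure, measures the four stem descriptors over consecutive
#' C-alpha atoms: at the N-terminal stem (AHo 105-108) and the C-terminal
#' stem (AHo 135-138). `alpha` is the signed four-point pseudo-torsion over
#' the full window; `tau` is the three-point pseudo-bond angle over the first
#' three window positions.
#'
#' @param atoms Atom tibble (one or more structures, keyed by `id`).
#' @param tau_anchor Which three window positions carry the bond angle:
#'   `"first"` (positions 1-3 of each window, the default) or `"last"`.
#' @return Tibble with columns `id`, `alpha_n`, `tau_n`, `alpha_c`, `tau_c`
#'   (degrees).
#' @export
stem_angles <- function(atoms, tau_anchor = c("first", "last")) {
  tau_anchor <- match.arg(tau_anchor)
  validate_atoms(atoms)
  out <- lapply(split_structures(atoms), function(a) {
    one_stem <- function(window) {
      p <- lapply(window, function(k) ca_coord(a, k))
      tri <- if (tau_anchor == "first") p[1:3] else p[2:4]
      c(alpha = pseudo_torsion(p[[1]], p[[2]], p[[3]], p[[4]]),
        tau = pseudo_bond_angle(tri[[1]], tri[[2]], tri[[3]]))
    }
    n <- one_stem(STEM_N_WINDOW)
    cc <- one_stem(STEM_C_WINDOW)
    tibble::tibble(alpha_n = n[["alpha"]], tau_n = n[["tau"]],
                   alpha_c = cc[["alpha"]], tau_c = cc[["tau"]])
  })
  dplyr::bind_cols(tibble::tibble(id = names(out)), dplyr::bind_rows(out))
}

#' HCDR3-FR2 contact density
#'
#' Counts heavy-atom pairs closer than `cutoff` between non-stem HCDR3
#' residues and FR2 residues at AHo 44-55, then divides by the full HCDR3
#' length (number of residues present at AHo 108-138). Stem residues (AHo
#' 108, 109, 136, 137, 138) are excluded from contact counting but still
#' count toward the length.
#'
#' @param atoms Atom tibble.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @return Tibble with columns `id`, `n_contacts`, `hcdr3_length`,
#'   `contact_density`.
#' @export
contact_density <- function(atoms, cutoff = 4.5) {
  validate_atoms(atoms)
  hcdr3 <- aho_positions_of("HCDR3")
  out <- lapply(split_structures(atoms), function(a) {
    len <- length(unique(a$aho[a$aho %in% hcdr3]))
    if (len == 0L) rlang::abort("structure has no HCDR3 residues")
    loop <- a[a$aho %in% setdiff(hcdr3, HCDR3_STEM_EXCLUDE), , drop = FALSE]
    fr2 <- a[a$aho %in% FR2_CONTACT_RANGE, , drop = FALSE]
    n <- 0L
    if (nrow(loop) > 0L && nrow(fr2) > 0L) {
      d2 <- outer(loop$x, fr2$x, "-")^2 + outer(loop$y, fr2$y, "-")^2 +
        outer(loop$z, fr2$z, "-")^2
      n <- sum(d2 <= cutoff^2)
    }
    tibble::tibble(n_contacts = n, hcdr3_length = len,
                   contact_density = n / len)
  })
  dplyr::bind_cols(tibble::tibble(id = names(out)), dplyr::bind_rows(out))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by the Shrake-Rupley quadrature: each atom's solvent-
#' accessible sphere (van der Waals radius + probe) is sampled at `n_points`
#' quasi-uniform points (Fibonacci spiral), and a point counts as accessible
#' when it lies outside every neighbour's accessible sphere. The neighbour
#' search is restricted to atoms within `r_i + r_j + 2 * probe`.
#'
#' The quadrature grid is laid out in a molecule-intrinsic frame (anchored on
#' the structure's own atoms), so the result is exactly invariant under rigid
#' motions of the input rather than invariant only up to quadrature error.
#'
#' @param atoms Atom tibble (a single structure or several; computed per
#'   structure).
#' @param probe Probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points Number of quadrature points per atom (default 960).
#' @param radii Named numeric vector of per-element van der Waals radii in
#'   Angstrom; defaults to the packaged table ([element_radii()]).
#' @return The input tibble with an added `sasa` column (Angstrom^2).
#' @seealso [residue_sasa()], [fr2_rsa_key()]
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L,
                               radii = element_radii()) {
  validate_atoms(atoms)
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown)) {
    rlang::abort(sprintf("no radius entry for element(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  sphere <- fibonacci_sphere(n_points)
  pieces <- lapply(split_structures(atoms), function(a) {
    xyz <- canonical_coords(as.matrix(a[, c("x", "y", "z")]))
    r <- unname(radii[a$element]) + probe
    n <- nrow(xyz)
    sasa <- numeric(n)
    for (i in seq_len(n)) {
      d2i <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
        (xyz[, 3] - xyz[i, 3])^2
      nb <- which(d2i < (r + r[i])^2 & seq_len(n) != i)
      if (length(nb) == 0L) {
        sasa[i] <- 4 * pi * r[i]^2
        next
      }
      pts <- sphere * r[i]
      pts[, 1] <- pts[, 1] + xyz[i, 1]
      pts[, 2] <- pts[, 2] + xyz[i, 2]
      pts[, 3] <- pts[, 3] + xyz[i, 3]
      free <- rep(TRUE, n_points)
      for (j in nb) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 > r[j]^2
        if (!any(free)) break
      }
      sasa[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
    }
    a$sasa <- sasa
    a
  })
  dplyr::bind_rows(pieces)
}

# quasi-uniform unit sphere points (Fibonacci spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  rho <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

# express coordinates in a frame built from the structure's own geometry so
# downstream quadrature is exactly covariant with rigid motions
canonical_coords <- function(xyz) {
  n <- nrow(xyz)
  if (n < 3L) return(sweep(xyz, 2, xyz[1, ]))
  a1 <- xyz[1, ]
  a2 <- xyz[n, ]
  e1 <- a2 - a1
  if (sum(e1^2) < 1e-12) return(sweep(xyz, 2, a1))
  e1 <- e1 / sqrt(sum(e1^2))
  rel <- sweep(xyz, 2, a1)
  proj <- rel %*% e1
  perp <- rel - proj %*% t(e1)
  d2 <- rowSums(perp^2)
  k <- which.max(d2)
  if (d2[k] < 1e-12) return(sweep(xyz, 2, a1))
  e2 <- perp[k, ] / sqrt(d2[k])
  e3 <- cross3(e1, e2)
  rel %*% cbind(e1, e2, e3)
}

#' Per-residue SASA
#'
#' @param atom_sasa Output of [shrake_rupley_sasa()].
#' @return Tibble with columns `id`, `aho`, `aa`, `sasa` (sum over member
#'   atoms).
#' @export
residue_sasa <- function(atom_sasa) {
  dplyr::summarise(
    dplyr::group_by(atom_sasa, .data$id, .data$aho, .data$aa),
    sasa = sum(.data$sasa), .groups = "drop"
  )
}

#' FR2 key-position relative solvent accessibility
#'
#' Mean relative solvent accessibility (RSA) of AHo positions 44 and 54,
#' the hydrophobic FR2 positions shielded by a kinked HCDR3. RSA is the
#' residue SASA divided by the residue type's theoretical maximum (Gly-X-Gly
#' tripeptide values); it is deliberately not clipped at 1.
#'
#' @param atoms Atom tibble.
#' @param atom_sasa Optional precomputed output of [shrake_rupley_sasa()] for
#'   the same atoms; computed on the fly when `NULL`.
#' @param max_asa Named numeric vector of theoretical maximum ASA per
#'   one-letter residue code; defaults to the packaged table
#'   ([max_asa_gxg()]).
#' @return Tibble with columns `id`, `fr2_rsa_key`.
#' @export
fr2_rsa_key <- function(atoms, atom_sasa = NULL, max_asa = max_asa_gxg()) {
  validate_atoms(atoms)
  if (is.null(atom_sasa)) atom_sasa <- shrake_rupley_sasa(atoms)
  res <- residue_sasa(atom_sasa)
  out <- lapply(split(res, factor(res$id, levels = unique(res$id))), function(r) {
    rows <- r[r$aho %in% FR2_RSA_POSITIONS, , drop = FALSE]
    missing <- setdiff(FR2_RSA_POSITIONS, rows$aho)
    if (length(missing)) {
      rlang::abort(sprintf("missing residue at AHo position(s) %s",
                           paste(missing, collapse = ", ")))
    }
    mx <- max_asa[rows$aa]
    if (any(is.na(mx))) {
      rlang::abort(sprintf("no max-ASA entry for residue(s): %s",
                           paste(rows$aa[is.na(mx)], collapse = ", ")))
    }
    mean(rows$sasa / unname(mx))
  })
  tibble::tibble(id = names(out), fr2_rsa_key = unlist(out, use.names = FALSE))
}

#' The six HCDR3 blueprint descriptors
#'
#' Assembles, per structure, the feature vector consumed by the structure
#' classifier: `alpha_n`, `tau_n`, `alpha_c`, `tau_c` (stem pseudo-angles,
#' degrees), `contact_density` (HCDR3-FR2 contacts per HCDR3 residue) and
#' `fr2_rsa_key` (mean RSA of AHo 44/54).
#'
#' @param atoms Atom tibble (one or more structures).
#' @param cutoff Contact cutoff in Angstrom.
#' @param probe,n_points SASA quadrature settings.
#' @return Tibble with one row per structure and the six feature columns.
#' @export
vhh_features <- function(atoms, cutoff = 4.5, probe = 1.4, n_points = 960L) {
  validate_atoms(atoms)
  ang <- stem_angles(atoms)
  cd <- contact_density(atoms, cutoff = cutoff)
  sasa <- shrake_rupley_sasa(atoms, probe = probe, n_points = n_points)
  rsa <- fr2_rsa_key(atoms, atom_sasa = sasa)
  dplyr::left_join(ang, cd[, c("id", "contact_density")], by = "id") |>
    dplyr::left_join(rsa, by = "id")
}

BLUEPRINT_FEATURES <- c("alpha_n", "tau_n", "alpha_c", "tau_c",
                        "contact_density", "fr2_rsa_key")
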