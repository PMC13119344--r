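test_that("kabsch_superpose recovers exact transforms and matches bio3d", {
  set.seed(19)
  ref <- matrix(rnorm(30 * 3, sd = 5), 30, 3)
  # identical sets: identity transform
  s0 <- kabsch_superpose(ref, ref)
  expect_equal(s0$rmsd, 0, tolerance = 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(s0$rotation), 1, tolerance = 1e-9)

  # pure translation recovered
  s1 <- kabsch_superpose(ref, sweep(ref, 2, c(-4, 2, 7), "+"))
  expect_equal(s1$rmsd, 0, tolerance = 1e-9)
  expect_equal(s1$translation, c(-4, 2, 7) * -1, tolerance = 1e-9)

  # rotation + noise: RMSD matches an independent implementation (bio3d)
  rot <- nbblueprint:::random_rotation()
  mov <- ref %*% t(rot) + matrix(rnorm(90, sd = 0.3), 30, 3)
  s2 <- kabsch_superpose(ref, mov)
  fit <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.numeric(t(ref)), mobile = as.numeric(t(mov)))
  )
  rmsd_bio3d <- sqrt(mean(rowSums((matrix(fit, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(s2$rmsd, rmsd_bio3d, tolerance = 1e-6)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("region_rmsd isolates a rigid HCDR3 displacement", {
  toy <- make_toy_vhh("kinked", seed = 14)
  pred <- perturb_structure(toy$atoms, "HCDR3", 2.0, "rigid_shift", seed = 3)
  rr <- region_rmsd(toy$atoms, pred)
  expect_equal(rr$rmsd[rr$region == "FR"], 0, tolerance = 1e-9)
  expect_equal(rr$rmsd[rr$region == "HCDR3"], 2.0, tolerance = 1e-6)
  expect_equal(rr$rmsd[rr$region == "HCDR1"], 0, tolerance = 1e-9)

  # identical structures: all zeros
  rr0 <- region_rmsd(toy$atoms, toy$atoms)
  expect_true(all(rr0$rmsd < 1e-9))

  # missing region reported by name
  expect_error(region_rmsd(toy$atoms, pred[!pred$aho %in% 57:69, ]), "HCDR2")
})

test_that("region RMSDs satisfy the atom-weighted consistency identity", {
  toy <- make_toy_vhh("extended", seed = 15)
  pred <- perturb_structure(toy$atoms, "All", 1.0, "per_atom_noise", seed = 6)
  # the toy domain leaves FR4 unoccupied; the occupied regions partition All
  regions <- c("FR1", "HCDR1", "FR2", "HCDR2", "FR3", "HCDR3")
  rr <- region_rmsd(toy$atoms, pred, regions = c("All", regions))
  all_row <- rr[rr$region == "All", ]
  parts <- rr[rr$region != "All", ]
  expect_equal(sum(parts$n_atoms), all_row$n_atoms)
  expect_equal(sqrt(sum(parts$n_atoms * parts$rmsd^2) / sum(parts$n_atoms)),
               all_row$rmsd, tolerance = 1e-9)
  # FR region equals the superposition RMSD by construction
  fr_bb <- nbblueprint:::paired_backbone(toy$atoms, pred,
                                         nbblueprint:::fr_positions())
  sup <- kabsch_superpose(fr_bb$ref, fr_bb$pred)
  rr_fr <- region_rmsd(toy$atoms, pred, regions = "FR")
  expect_equal(rr_fr$rmsd, sup$rmsd, tolerance = 1e-9)
})

test_that("blueprint recovery counts matching bins with the evaluation scheme", {
  # all identical bins
  r <- blueprint_recovery(c(0.9, 0.1, 0.9), c(0.8, 0.2, 0.95))
  expect_equal(r$recovery_pct, 100)

  # constructed 47-pair set with 43 matches (evaluation scheme, no unclear)
  ref <- c(rep(0.9, 30), rep(0.1, 17))
  pred <- c(rep(0.9, 26), rep(0.1, 4), rep(0.1, 17))
  r2 <- blueprint_recovery(ref, pred)
  expect_equal(r2$n_scored, 47L)
  expect_equal(round(r2$recovery_pct, 1), 91.5)
  expect_equal(round(r2$recovery_pct, 2), 91.49)

  # kinked reference vs unclear prediction is a mismatch
  r3 <- blueprint_recovery(0.9, 0.4)
  expect_equal(r3$recovery_pct, 0)

  # unclear references are excluded by default, counted when asked
  r4 <- blueprint_recovery(c(0.9, 0.4), c(0.9, 0.4))
  expect_equal(r4$n_scored, 1L)
  expect_equal(r4$n_unclear_ref, 1L)
  r5 <- blueprint_recovery(c(0.9, 0.4), c(0.9, 0.4), include_unclear_ref = TRUE)
  expect_equal(r5$n_scored, 2L)
  expect_equal(r5$recovery_pct, 100)

  # symmetric under simultaneous relabelling (swap kinked/extended poles)
  ref6 <- c(0.9, 0.1, 0.6, 0.2)
  pred6 <- c(0.85, 0.15, 0.1, 0.6)
  r6 <- blueprint_recovery(ref6, pred6, include_unclear_ref = TRUE)
  r6s <- blueprint_recovery(1 - ref6, 1 - pred6, include_unclear_ref = TRUE)
  # deployment/evaluation thresholds are not symmetric around 0.5, so use a
  # symmetric scheme check on the confusion total instead
  expect_equal(sum(r6$confusion$n), sum(r6s$confusion$n))
  expect_error(blueprint_recovery(c(0.2, 0.3), 0.2), "one-to-one")
})

test_that("NCDB recovery rate applies the all-pairs rule per structure", {
  records <- tibble::tibble(
    id = c("a", "a", "b", "c", "c", "d"),
    canonical = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    recovered = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  # structures with non-canonical pairs: a (recovered), b (not), c (1 of 2)
  out <- ncdb_recovery_rate(records)
  expect_equal(out$n_structures, 3L)
  expect_equal(out$n_recovered, 1L)
  expect_equal(out$rate_pct, 100 / 3, tolerance = 1e-9)
  expect_equal(out$pair_rate_pct, 50)

  # 13 of 15 single-pair structures
  rec15 <- tibble::tibble(
    id = paste0("s", 1:15), canonical = FALSE,
    recovered = c(rep(TRUE, 13), FALSE, FALSE)
  )
  expect_equal(round(ncdb_recovery_rate(rec15)$rate_pct, 1), 86.7)
  expect_error(ncdb_recovery_rate(records[records$canonical, ]), "non-canonical")
})

test_that("bootstrap median CI is deterministic, degenerate on constants, and calibrated", {
  expect_equal(bootstrap_median_ci(rep(3.2, 10), n_boot = 200, seed = 1),
               bootstrap_median_ci(rep(3.2, 10), n_boot = 200, seed = 1))
  cc <- bootstrap_median_ci(rep(3.2, 10), n_boot = 200, seed = 1)
  expect_equal(c(cc$median, cc$lo, cc$hi), c(3.2, 3.2, 3.2))

  a <- bootstrap_median_ci(rnorm(50), n_boot = 500, seed = 42)
  expect_true(a$lo <= a$median && a$median <= a$hi)

  # coverage: ~95% of CIs contain the true median
  set.seed(7)
  cover <- vapply(1:300, function(r) {
    x <- rnorm(30)
    ci <- bootstrap_median_ci(x, n_boot = 1000,
                              seed = sample.int(1e6, 1))
    ci$lo <= 0 && 0 <= ci$hi
  }, logical(1))
  expect_gt(mean(cover), 0.90)
  expect_error(bootstrap_median_ci(numeric()), "non-empty")
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(23)
  widths <- function(n) {
    vapply(1:40, function(r) {
      ci <- bootstrap_median_ci(rnorm(n), n_boot = 500, seed = r)
      ci$hi - ci$lo
    }, numeric(1))
  }
  expect_lt(median(widths(200)), median(widths(20)))
})

test_that("HCDR3 confidence filter averages over HCDR3 positions only", {
  sc <- tibble::tibble(aho = c(110:115, 44), plddt = c(rep(0.9, 6), 0.1))
  expect_true(hcdr3_plddt_filter(sc))
  sc2 <- tibble::tibble(aho = 110:119, plddt = rep(0.69, 10))
  expect_false(hcdr3_plddt_filter(sc2))
  expect_true(hcdr3_plddt_filter(tibble::tibble(aho = 110, plddt = 0.7)))
  expect_error(hcdr3_plddt_filter(tibble::tibble(aho = 44, plddt = 0.9)),
               "HCDR3")
})

test_that("peptide-bond check flags stretched bonds and skips chain breaks", {
  tr <- make_stem_trace(-62, 126, anchor = 10:13)
  at <- nbblueprint:::chain_atoms(10:13, as.matrix(tr[, c("x", "y", "z")]),
                                  rep("A", 4))
  at$id <- "fix"
  at <- at[, c("id", "aho", "aa", "atom", "element", "x", "y", "z")]
  expect_equal(nrow(peptide_bond_violations(at)), 0L)

  # stretch one bond: displace the residue-13 N away along the bond
  bad <- at
  idx <- which(bad$aho == 13 & bad$atom == "N")
  bad$x[idx] <- bad$x[idx] + 2
  v <- peptide_bond_violations(bad)
  expect_gte(nrow(v), 1L)
  expect_true(any(v$pos_i == 12 & v$pos_j == 13))

  # a gap in AHo occupancy is a chain break, not a violation
  gap <- at[at$aho != 12, ]
  expect_equal(nrow(peptide_bond_violations(gap)), 0L)
})
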