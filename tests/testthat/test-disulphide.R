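test_that("wrap_angle maps to (-pi, pi] with the boundary convention", {
  expect_equal(wrap_angle(3 * pi / 2), -pi / 2)
  expect_equal(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(0.1), 0.1)
  expect_equal(wrap_angle(pi), pi)
  xs <- seq(-20, 20, by = 0.37)
  w <- wrap_angle(xs)
  expect_true(all(w > -pi & w <= pi + 1e-12))
  expect_equal(sin(w), sin(xs), tolerance = 1e-12)
  expect_equal(cos(w), cos(xs), tolerance = 1e-12)
})

test_that("greedy pairing selects non-overlapping bonds in ascending distance", {
  # two SGs at bond distance
  p <- select_bonded_pairs(rbind(c(0, 0, 0), c(2.05, 0, 0)))
  expect_equal(nrow(p$bonded), 1L)
  expect_equal(p$bonded$dist, 2.05)
  expect_equal(nrow(p$nonbonded), 0L)

  # chain of three: nearest pair wins, remainder is non-bonded
  sg <- rbind(c(0, 0, 0), c(2.0, 0, 0), c(-2.9, 0, 0))
  p3 <- select_bonded_pairs(sg)
  expect_equal(p3$bonded[, c("i", "j")], tibble::tibble(i = 1L, j = 2L))
  expect_equal(nrow(p3$nonbonded), 2L)

  # two disjoint pairs
  sg4 <- rbind(c(0, 0, 0), c(2.05, 0, 0), c(10, 0, 0), c(12.05, 0, 0))
  p4 <- select_bonded_pairs(sg4)
  expect_equal(nrow(p4$bonded), 2L)

  # zero or one cysteine
  expect_equal(nrow(select_bonded_pairs(matrix(numeric(), 0, 3))$bonded), 0L)
  expect_equal(nrow(select_bonded_pairs(rbind(c(1, 2, 3)))$bonded), 0L)
})

test_that("greedy pairing agrees with the exhaustive matching oracle", {
  set.seed(99)
  for (k in 1:200) {
    sg <- random_cysteine_instance()
    got <- select_bonded_pairs(sg)$bonded
    keys <- sort(paste0(got$i, "-", got$j))
    expect_equal(keys, matching_oracle(sg))
  }
})

test_that("hinge losses are zero in-band with unit slopes outside", {
  mk <- function(d) rbind(c(0, 0, 0), c(d, 0, 0))
  pairing <- select_bonded_pairs(mk(2.05))
  expect_equal(sg_band_loss(mk(2.05), pairing), 0)
  expect_equal(sg_band_loss(mk(2.50), pairing), 0.24, tolerance = 1e-12)
  expect_equal(sg_band_loss(mk(1.50), pairing), 0.34, tolerance = 1e-12)
  # finite-difference slope +-1 beyond the band edges
  eps <- 1e-6
  up <- (sg_band_loss(mk(2.50 + eps), pairing) - sg_band_loss(mk(2.50), pairing)) / eps
  dn <- (sg_band_loss(mk(1.50 - eps), pairing) - sg_band_loss(mk(1.50), pairing)) / eps
  expect_equal(up, 1, tolerance = 1e-4)
  expect_equal(dn, 1, tolerance = 1e-4)

  # non-bonded repulsion: pair too far for a bond but inside 4.1
  far <- rbind(c(0, 0, 0), c(3.0 + 1e-9, 0, 0))
  pr <- select_bonded_pairs(far)
  expect_equal(nrow(pr$bonded), 0L)
  expect_equal(sg_band_loss(rbind(c(0, 0, 0), c(3.0, 0, 0)), pr), 1.1,
               tolerance = 1e-9)

  expect_equal(cb_band_loss(mk(3.8), pairing), 0)
  expect_equal(cb_band_loss(mk(5.0), pairing), 0.5, tolerance = 1e-12)
  expect_equal(cb_band_loss(mk(2.0), pairing), 0.85, tolerance = 1e-12)
})

test_that("angle loss follows the Huber branches around theta* = 2 rad", {
  g0 <- make_ideal_disulphide(2.05, 3.8, 2.0, 1.66012)
  pairing <- select_bonded_pairs(g0$sg)
  expect_equal(ss_cb_angle_loss(g0$sg, g0$cb, pairing), 0, tolerance = 1e-12)
  # quadratic branch: both angles off by 0.04
  g1 <- make_ideal_disulphide(2.05, 3.8, 2.04, 1.66012)
  expect_equal(ss_cb_angle_loss(g1$sg, g1$cb, pairing),
               2 * 0.5 * 0.04^2, tolerance = 1e-9)
  # linear branch: both angles off by 1 rad
  g2 <- make_ideal_disulphide(2.05, 3.8, 3.0, 1.66012)
  expect_equal(ss_cb_angle_loss(g2$sg, g2$cb, pairing),
               2 * 0.04 * (1 - 0.02), tolerance = 1e-9)
})

test_that("chi3 loss is near zero at both canonical modes and 5.180 at zero", {
  pairing <- select_bonded_pairs(rbind(c(0, 0, 0), c(2.05, 0, 0)))
  loss_at <- function(phi) {
    g <- make_ideal_disulphide(2.05, 3.8, 2.0, phi)
    chi3_loss(g$sg, g$cb, pairing)
  }
  expect_equal(loss_at(1.66012), 0, tolerance = 1e-6)
  expect_equal(loss_at(-1.79512), 0, tolerance = 1e-6)
  expect_equal(loss_at(0), 5.180, tolerance = 1e-3)
  # bounded below by -log(2); and the bound is approached nowhere here
  for (phi in seq(-3, 3, by = 0.5)) {
    expect_gte(loss_at(phi), -log(2))
  }
})

test_that("distogram loss is symmetric cross-entropy against the 2.05 A bin", {
  cfg <- disulphide_config()
  pairing <- select_bonded_pairs(rbind(c(0, 0, 0), c(2.05, 0, 0)))
  uniform <- array(0, dim = c(2, 2, 64))
  expect_equal(distogram_loss(uniform, pairing, cfg), 2 * log(64),
               tolerance = 1e-9)
  # all mass on the target bin (2.05 A falls in the first, open, bin)
  onehot <- array(-1e4, dim = c(2, 2, 64))
  onehot[, , 1] <- 1e4
  expect_equal(distogram_loss(onehot, pairing, cfg), 0, tolerance = 1e-6)
  # swapping the directions leaves the loss unchanged
  set.seed(4)
  lg <- array(rnorm(2 * 2 * 64), dim = c(2, 2, 64))
  swapped <- lg
  swapped[1, 2, ] <- lg[2, 1, ]
  swapped[2, 1, ] <- lg[1, 2, ]
  expect_equal(distogram_loss(lg, pairing, cfg),
               distogram_loss(swapped, pairing, cfg), tolerance = 1e-12)
  expect_error(distogram_loss(array(0, dim = c(2, 2, 10)), pairing, cfg),
               "64")
})

test_that("total loss anneals linearly and sits at its floor on ideal geometry", {
  g <- make_ideal_disulphide(2.05, 3.8, 2.0, 1.66012)
  onehot <- array(-1e4, dim = c(2, 2, 64))
  onehot[, , 1] <- 1e4
  rep_inf <- total_disulphide_loss(g$sg, g$cb, g$sg, logits = onehot,
                                   step = 100000)
  expect_lt(abs(rep_inf$total), 1e-6)
  expect_equal(rep_inf$anneal, 1)

  # step 0: total exactly zero, components still reported
  worse <- g$sg
  worse[2, 1] <- 3.2
  rep0 <- total_disulphide_loss(worse, g$cb, g$sg, step = 0)
  expect_identical(rep0$total, 0)
  expect_gt(sum(rep0$terms$loss), 0)

  # half-way annealing halves the total
  rep_half <- total_disulphide_loss(worse, g$cb, g$sg, step = 50000)
  rep_full <- total_disulphide_loss(worse, g$cb, g$sg, step = 100000)
  expect_equal(rep_half$total, 0.5 * rep_full$total, tolerance = 1e-12)

  # published term weighting
  expect_equal(rep_full$terms$weight,
               unname(c(0.5, 0.25, 1e-4, 1e-4, 1.0)))
})

test_that("all loss terms are invariant under rigid transforms of the prediction", {
  g <- make_ideal_disulphide(2.20, 4.3, 2.2, 1.2)
  pairing <- select_bonded_pairs(g$sg)
  base <- c(
    sg_band_loss(g$sg, pairing),
    cb_band_loss(g$cb, pairing),
    ss_cb_angle_loss(g$sg, g$cb, pairing),
    chi3_loss(g$sg, g$cb, pairing)
  )
  set.seed(41)
  for (k in 1:20) {
    rot <- nbblueprint:::random_rotation()
    tr <- rnorm(3, sd = 15)
    sg2 <- g$sg %*% t(rot) + matrix(tr, 2, 3, byrow = TRUE)
    cb2 <- g$cb %*% t(rot) + matrix(tr, 2, 3, byrow = TRUE)
    moved <- c(
      sg_band_loss(sg2, pairing),
      cb_band_loss(cb2, pairing),
      ss_cb_angle_loss(sg2, cb2, pairing),
      chi3_loss(sg2, cb2, pairing)
    )
    expect_equal(moved, base, tolerance = 1e-6)
  }
})

test_that("expected pairs and NCDB recovery implement the distance rules", {
  toy <- make_toy_vhh("kinked", ncdb = c(57, 115), seed = 8)
  pairs <- extract_expected_pairs(toy$atoms)
  expect_equal(nrow(pairs), 2L)
  expect_equal(sum(pairs$canonical), 1L)
  expect_setequal(paste(pairs$pos_i, pairs$pos_j),
                  c("23 106", "57 115"))

  # prediction identical to reference: everything recovered
  rec <- ncdb_recovered(toy$atoms, pairs)
  expect_true(all(rec$recovered))

  # push one SG out to 2.47 A: boundary excluded
  pred <- toy$atoms
  idx <- which(pred$aho == 115 & pred$atom == "SG")
  sg57 <- as.numeric(pred[pred$aho == 57 & pred$atom == "SG", c("x", "y", "z")])
  sg115 <- as.numeric(pred[idx, c("x", "y", "z")])
  u <- (sg115 - sg57) / sqrt(sum((sg115 - sg57)^2))
  pred[idx, c("x", "y", "z")] <- as.list(sg57 + 2.47 * u)
  rec2 <- ncdb_recovered(pred, pairs)
  expect_false(rec2$recovered[!rec2$canonical])
  expect_true(rec2$recovered[rec2$canonical])

  # missing SG: violation, not recovered
  pred3 <- pred[-idx, ]
  rec3 <- ncdb_recovered(pred3, pairs)
  expect_true(rec3$violation[!rec3$canonical])
  expect_false(rec3$recovered[!rec3$canonical])

  # a 3.5 A cysteine pair is not an expected pair
  lone <- toy$atoms
  idx2 <- which(lone$aho == 115 & lone$atom == "SG")
  lone[idx2, c("x", "y", "z")] <- as.list(sg57 + 3.5 * u)
  expect_equal(nrow(extract_expected_pairs(lone)), 1L)
})
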