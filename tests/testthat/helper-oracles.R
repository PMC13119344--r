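# Independent oracles used across the suite. These stay deliberately naive
# (enumeration, brute force) so they check the package's faster paths from a
# different route.

# two-sided Fisher p-value by full hypergeometric enumeration
fisher_enum_oracle <- function(a, b, c, d) {
  m1 <- a + b  # row 1 total
  k <- a + c   # column 1 total
  n <- a + b + c + d
  xs <- max(0, k - (n - m1)):min(k, m1)
  probs <- stats::dhyper(xs, m1, n - m1, k)
  p_obs <- stats::dhyper(a, m1, n - m1, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# all-pairs brute-force contact count between two atom tables
contact_count_oracle <- function(loop, fr2, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(loop))) {
    for (j in seq_len(nrow(fr2))) {
      d <- sqrt((loop$x[i] - fr2$x[j])^2 + (loop$y[i] - fr2$y[j])^2 +
                  (loop$z[i] - fr2$z[j])^2)
      if (d <= cutoff) n <- n + 1L
    }
  }
  n
}

# exhaustive maximal matching on candidate edges: maximum cardinality,
# ties broken by minimum total distance; returns sorted "i-j" keys
matching_oracle <- function(sg, band = c(1.42, 3.00)) {
  n <- nrow(sg)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((sg[i, ] - sg[j, ])^2))
      if (d >= band[1] && d <= band[2]) {
        edges[[length(edges) + 1L]] <- c(i, j, d)
      }
    }
  }
  if (length(edges) == 0L) return(character())
  best <- list(card = -1L, dist = Inf, keys = character())
  recurse <- function(idx, used, keys, dist) {
    if (length(idx) == 0L) {
      card <- length(keys)
      ks <- sort(keys)
      better <- card > best$card ||
        (card == best$card && dist < best$dist) ||
        (card == best$card && dist == best$dist &&
           paste(ks, collapse = ",") < paste(best$keys, collapse = ","))
      if (better) best <<- list(card = card, dist = dist, keys = ks)
      return(invisible())
    }
    e <- edges[[idx[1]]]
    # skip this edge
    recurse(idx[-1], used, keys, dist)
    if (!used[e[1]] && !used[e[2]]) {
      used2 <- used
      used2[e[1]] <- used2[e[2]] <- TRUE
      recurse(idx[-1], used2, c(keys, paste0(e[1], "-", e[2])), dist + e[3])
    }
  }
  recurse(seq_along(edges), logical(n), character(), 0)
  best$keys
}

# random cysteine arrangement: well-separated bonded pairs, lone cysteines
# and occasional triangles -- the arrangements that occur in structures
random_cysteine_instance <- function() {
  kind <- sample(c("pairs", "pairs_plus_lone", "triangle"), 1,
                 prob = c(0.5, 0.35, 0.15))
  centers <- matrix(stats::runif(3 * 3, 0, 40), ncol = 3)
  # enforce >= 8 Angstrom separation between cluster centers
  while (min(dist(centers)) < 8) {
    centers <- matrix(stats::runif(3 * 3, 0, 40), ncol = 3)
  }
  pts <- list()
  add_pair <- function(center) {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    d <- stats::runif(1, 1.6, 2.9)
    rbind(center - u * d / 2, center + u * d / 2)
  }
  if (kind == "triangle") {
    r <- stats::runif(1, 1.3, 1.7)
    # deliberately scalene: exact distance ties do not occur in structures
    tri <- rbind(c(r, 0, 0), c(-r / 2, r * sqrt(3) / 2, 0),
                 c(-r / 2 * 1.05, -r * sqrt(3) / 2 * 0.95, 0))
    pts[[1]] <- sweep(tri, 2, centers[1, ], "+")
    pts[[2]] <- add_pair(centers[2, ])
  } else {
    pts[[1]] <- add_pair(centers[1, ])
    pts[[2]] <- add_pair(centers[2, ])
    if (kind == "pairs_plus_lone") pts[[3]] <- centers[3, , drop = FALSE]
  }
  do.call(rbind, pts)
}

# a tiny two-window CA scaffold carrying both stems (for stem_angles tests)
both_stem_trace <- function(alpha_n = -62, tau_n = 126, alpha_c = -13.31,
                            tau_c = 109.68, seed_n = NULL, seed_c = NULL) {
  n <- make_stem_trace(alpha_n, tau_n, anchor = 105:108, seed = seed_n)
  c_ <- make_stem_trace(alpha_c, tau_c, anchor = 135:138, seed = seed_c)
  c_$x <- c_$x + 30
  rbind(n, c_)
}
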