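#!/usr/bin/env Rscript
# Regenerates inst/extdata/nbframe_sequence_params_synthetic.json: the
# reference sequence-classifier parameter set fitted on a synthetic training
# set. The published work does not print its fitted sequence-classifier
# weights, so the packaged set demonstrates the format and pipeline only.
#
# The synthetic training set mirrors the packaged hallmark table: each
# hallmark position draws its amino acid from the per-class carrier
# percentages (several hallmark letters can share one position), all other
# framework positions are uniform background, and the soft training targets
# are label-correlated structure probabilities. Class sizes match the
# published training composition (478 kinked / 351 extended).

library(nbblueprint)

set.seed(20260926)

n_k <- 478L
n_e <- 351L
n <- n_k + n_e
label <- c(rep("kinked", n_k), rep("extended", n_e))
h <- nbframe_hallmarks()

background <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
m <- matrix(sample(background, 149L * n, replace = TRUE), nrow = 149L)
for (p in unique(h$position)) {
  rows <- h[h$position == p, ]
  for (cls in c("kinked", "extended")) {
    freqs <- if (cls == "kinked") rows$pct_kinked else rows$pct_extended
    freqs <- freqs / 100
    rest <- max(0, 1 - sum(freqs))
    letters_p <- c(rows$aa, setdiff(background, rows$aa))
    probs <- c(freqs * (1 / max(1, sum(freqs) + rest)),
               rep(rest / max(1, sum(freqs) + rest) /
                     length(setdiff(background, rows$aa)),
                   length(setdiff(background, rows$aa))))
    idx <- which(label == cls)
    m[p, idx] <- sample(letters_p, length(idx), replace = TRUE, prob = probs)
  }
}
seqs <- tibble::tibble(id = paste0("t", seq_len(n)),
                       seq = apply(m, 2, paste, collapse = ""))

targets <- ifelse(label == "kinked", 0.9, 0.1) + rnorm(n, sd = 0.05)
targets <- pmin(pmax(targets, 1e-3), 1 - 1e-3)

x <- encode_hallmarks(seqs, h)
fit <- fit_soft_label_logistic(x, targets, l2 = 1e-3, tol = 1e-8)
write_logistic_params(fit$params, "inst/extdata/nbframe_sequence_params_synthetic.json")
cat("wrote", nrow(fit$params$coef), "feature weights; mean CE =", fit$loss, "\n")
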