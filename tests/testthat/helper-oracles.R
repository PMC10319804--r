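# Independent oracles used across the suite. Each is deliberately built on a
# different route than the package implementation it checks.

# Mann-Whitney p by complete enumeration over value assignments, with U
# computed from pairwise comparisons (not ranks).
enum_mw_p <- function(x, y, alternative = "two.sided") {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(x, y)
  p_le <- mean(u_all <= u_obs + 1e-9)
  p_ge <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         greater = p_ge,
         less = p_le)
}

# One-sided (row1-enriched) Fisher p by direct hypergeometric enumeration.
hyper_fisher_greater <- function(a, b, c, d) {
  ks <- max(0, a + b - (b + d)):min(a + b, a + c)
  probs <- stats::dhyper(ks, a + c, b + d, a + b)
  sum(probs[ks >= a])
}

# Two-sided Fisher p: sum of all table probabilities not exceeding the
# observed one (same convention as fisher.test).
hyper_fisher_two <- function(a, b, c, d) {
  ks <- max(0, a + b - (b + d)):min(a + b, a + c)
  probs <- stats::dhyper(ks, a + c, b + d, a + b)
  obs <- stats::dhyper(a, a + c, b + d, a + b)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the textbook step-up sort-and-scan.
bh_adjust_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Dinucleotide count vector (16 cells) of an ACGT string.
dinu_counts <- function(s) {
  x <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
  tabulate((x[-length(x)] - 1L) * 4L + x[-1L], 16L)
}

# Random row-normalized PWM over ACGT.
random_pwm <- function(L) {
  m <- matrix(stats::rgamma(4 * L, 1), L, 4)
  m <- m / rowSums(m)
  colnames(m) <- c("A", "C", "G", "T")
  m
}

make_motif <- function(matrix, id = "m1", rbp = "RBP1",
                       consensus = NULL) {
  if (is.null(consensus))
    consensus <- paste(colnames(matrix)[apply(matrix, 1, which.max)],
                       collapse = "")
  circscape:::new_motif(id, rbp, matrix, consensus)
}

# Brute-force PWM tail probability over all 4^L words, on the same
# discretized integer scores as the DP.
brute_pwm_tail <- function(scores_int, background, cutoffs) {
  L <- nrow(scores_int)
  words <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(scores_int[cbind(rep(seq_len(L), each = nrow(words)),
                                        as.vector(words))],
                       nrow(words), L))
  pr <- apply(matrix(background[words], nrow(words), L), 1, prod)
  vapply(cutoffs, function(q) sum(pr[sc >= q]), numeric(1))
}
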