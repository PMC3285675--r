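# Independent oracles used to verify the package's statistics. Each is a
# deliberately naive implementation (enumeration, closed form, direct
# arithmetic) kept separate from the code paths it checks.

# All permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Brute-force F score: enumerate every gene pair, classify within/between.
brute_force_F <- function(ranks, groups) {
  genes <- unlist(groups, use.names = FALSE)
  label <- rep(names(groups), lengths(groups))
  w <- c(); b <- c()
  for (i in seq_along(genes)) for (j in seq_len(i - 1L)) {
    d <- sqrt(sum((ranks[genes[i], ] - ranks[genes[j], ])^2))
    if (label[i] == label[j]) w <- c(w, d) else b <- c(b, d)
  }
  list(F = mean(w) - mean(b), N = length(w), M = length(b))
}

# Exact permutation p for the VDRE test: evaluate F under every distinct
# ordering of the label vector (duplicates arising from equal labels leave
# the p-value unchanged).
exact_vdre_p <- function(ranks, groups) {
  genes <- unlist(groups, use.names = FALSE)
  labels <- rep(names(groups), lengths(groups))
  obs <- brute_force_F(ranks, groups)$F
  perms <- all_perms(length(genes))
  f_all <- apply(perms, 1L, function(p) {
    g <- split(genes, labels[p])
    brute_force_F(ranks, g)$F
  })
  mean(f_all <= obs + 1e-12)
}

# Direct clustering score from ranks and types (independent loop).
brute_force_S <- function(r, types) {
  w <- c(); b <- c()
  for (i in seq_along(r)) for (j in seq_len(i - 1L)) {
    d <- abs(r[i] - r[j])
    if (types[i] == types[j]) w <- c(w, d) else b <- c(b, d)
  }
  list(S = mean(b) - mean(w), C_W = mean(w), C_Q = mean(b),
       A = length(w), B = length(b))
}

# Exact permutation p for the clustering test over all label arrangements.
exact_clustering_p <- function(r, types) {
  obs <- brute_force_S(r, types)$S
  perms <- all_perms(length(r))
  s_all <- apply(perms, 1L, function(p) brute_force_S(r, types[p])$S)
  mean(s_all >= obs - 1e-12)
}

# Two-sided Fisher p by explicit hypergeometric enumeration over all tables
# with the observed margins (probability ordering, with the conventional
# 1 + 1e-7 tolerance for float ties).
enum_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  if (m == 0L || n == 0L || k == 0L || (b + d) == 0L) return(1)
  support <- max(0L, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Storey q-values computed by direct nested loops over the definition.
brute_force_storey <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  q <- numeric(m)
  for (i in seq_len(m)) {
    candidates <- c()
    for (j in seq_len(m)) {
      pj <- p[j]
      if (pj >= p[i]) {
        rank_j <- sum(p <= pj)
        candidates <- c(candidates, pi0 * m * pj / rank_j)
      }
    }
    q[i] <- min(1, min(candidates))
  }
  q
}

# Least-squares slope via the normal equations.
normal_eq_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Exact 99% binomial acceptance band for a rejection count.
binom_band <- function(n, rate, conf = 0.99) {
  alpha <- (1 - conf) / 2
  c(qbinom(alpha, n, rate), qbinom(1 - alpha, n, rate))
}
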