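# Independently coded reference implementations ("oracles") used to validate
# the package's statistics. Deliberately written with explicit loops and
# hand-coded probability mass functions, not by calling the package code.

# Brute-force TMM: per-gene loops, explicit trimming by rank windows.
oracle_tmm <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) unname(quantile(counts[, j], 0.75)) / lib[j],
                numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    M <- c(); A <- c(); W <- c()
    for (g in seq_len(nrow(counts))) {
      yo <- counts[g, j]; yr <- counts[g, ref]
      if (yo > 0 && yr > 0) {
        po <- yo / lib[j]; pr <- yr / lib[ref]
        M <- c(M, log2(po / pr))
        A <- c(A, (log2(po) + log2(pr)) / 2)
        W <- c(W, 1 / ((lib[j] - yo) / (lib[j] * yo) +
                         (lib[ref] - yr) / (lib[ref] * yr)))
      }
    }
    n <- length(M)
    if (n == 0 || max(abs(M)) < 1e-6) { fac[j] <- 1; next }
    loM <- floor(n * trim_M) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_A) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- which(rM >= loM & rM <= hiM & rA >= loA & rA <= hiA)
    if (length(keep) == 0) { fac[j] <- 1; next }
    f <- sum(M[keep] * W[keep]) / sum(W[keep])
    fac[j] <- 2^f
  }
  fac / exp(mean(log(fac)))
}

# Hand-coded log pmfs (no dnbinom/dpois).
nb_lpmf <- function(x, r, mu) {
  lgamma(x + r) - lgamma(r) - lfactorial(x) +
    r * (log(r) - log(r + mu)) + x * (log(mu) - log(r + mu))
}
pois_lpmf <- function(x, lam) x * log(lam) - lam - lfactorial(x)

# Full enumeration of the conditional exact NB test.
oracle_exact_nb_p <- function(a, b, phi) {
  na <- length(a); nb <- length(b)
  sa <- sum(a); t <- sa + sum(b)
  if (t == 0) return(1)
  mu <- t / (na + nb)
  lp <- numeric(t + 1)
  for (s in 0:t) {
    lp[s + 1] <- if (phi == 0) {
      pois_lpmf(s, na * mu) + pois_lpmf(t - s, nb * mu)
    } else {
      nb_lpmf(s, na / phi, na * mu) + nb_lpmf(t - s, nb / phi, nb * mu)
    }
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  pobs <- pr[sa + 1]
  tot <- 0
  for (s in 0:t) if (pr[s + 1] <= pobs * (1 + 1e-8)) tot <- tot + pr[s + 1]
  min(1, tot)
}

# Step-up BH by explicit loop over the sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    v <- min(prev, sorted[i] * n / i, 1)
    adj[i] <- v
    prev <- v
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# GSEA enrichment score by walking the full ranked list position by position.
oracle_gsea_es <- function(ranking, set, weight_p = 1) {
  ord <- order(ranking, decreasing = TRUE)
  metric <- ranking[ord]
  hit <- names(metric) %in% set
  N <- length(hit); k <- sum(hit)
  w <- abs(metric)^weight_p
  denom <- sum(w[hit])
  rs <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- cur + if (hit[i]) w[i] / denom else -1 / (N - k)
    rs[i] <- cur
  }
  rs[which.max(abs(rs))]
}

# Upper-tail hypergeometric by direct enumeration with choose().
oracle_hyper_p <- function(overlap, set_size, universe_size, query_size) {
  tot <- 0
  for (i in overlap:min(set_size, query_size)) {
    tot <- tot + choose(set_size, i) *
      choose(universe_size - set_size, query_size - i)
  }
  tot / choose(universe_size, query_size)
}
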