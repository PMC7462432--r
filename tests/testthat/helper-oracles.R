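# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and its C++ kernels): triangle enumeration over triples,
# Floyd-Warshall distances, exhaustive set-partition search for modularity,
# direct pair counting for AUC, manual BH step-up.

randomAdjacency <- function(n, p = 0.3) {
  a <- matrix(0L, n, n)
  iu <- which(upper.tri(a))
  a[iu] <- as.integer(stats::runif(length(iu)) < p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  a
}

randomBinaryGraph <- function(n, p = 0.3) BinaryGraph(randomAdjacency(n, p))

oracleDegree <- function(a) {
  vapply(seq_len(nrow(a)), function(i) sum(a[i, ]), numeric(1))
}

# triangle enumeration over all node triples
oracleClustering <- function(a) {
  n <- nrow(a)
  tri <- numeric(n)
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      if (a[i, j] && a[j, k] && a[i, k]) {
        tri[i] <- tri[i] + 1; tri[j] <- tri[j] + 1; tri[k] <- tri[k] + 1
      }
    }
  }
  k <- oracleDegree(a)
  ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
}

oracleFloydWarshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

oracleGlobalEfficiency <- function(a) {
  n <- nrow(a)
  if (n < 2) return(0)
  d <- oracleFloydWarshall(a)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

oracleLocalEfficiency <- function(a) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracleGlobalEfficiency(a[nb, nb, drop = FALSE])
  }, numeric(1))
}

# Newman-Girvan modularity of a given membership vector, straight from the
# double-sum formula
oracleModularity <- function(a, memb) {
  k <- rowSums(a)
  m2 <- sum(a)                       # 2m
  if (m2 == 0) return(0)
  same <- outer(memb, memb, `==`)
  sum((a - outer(k, k) / m2) * same) / m2
}

# exhaustive search over all set partitions (restricted growth strings);
# feasible up to n = 8 (Bell(8) = 4140)
oracleOptimalModularity <- function(a) {
  n <- nrow(a)
  best <- -Inf
  memb <- integer(n)
  recurse <- function(i, maxLab) {
    if (i > n) {
      q <- oracleModularity(a, memb)
      if (q > best) best <<- q
      return(invisible(NULL))
    }
    for (lab in seq_len(maxLab + 1L)) {
      memb[i] <<- lab
      recurse(i + 1L, max(maxLab, lab))
    }
  }
  recurse(1L, 0L)
  best
}

oracleSegregation <- function(a, memb) {
  nets <- unique(memb)
  withinDens <- vapply(nets, function(s) {
    idx <- which(memb == s)
    sum(a[idx, idx]) / (length(idx) * (length(idx) - 1))
  }, numeric(1))
  zw <- mean(withinDens)
  withinEdges <- sum(vapply(nets, function(s) {
    idx <- which(memb == s); sum(a[idx, idx]) / 2
  }, numeric(1)))
  sizes <- table(memb)
  possBetween <- nrow(a) * (nrow(a) - 1) / 2 - sum(sizes * (sizes - 1) / 2)
  zb <- (sum(a) / 2 - withinEdges) / possBetween
  (zw - zb) / zw
}

oracleBHMask <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ok <- which(p[o] <= q * seq_len(m) / m)
  mask <- rep(FALSE, m)
  if (length(ok)) mask[o[seq_len(max(ok))]] <- TRUE
  mask
}

# AUC as the Mann-Whitney concordance probability, ties counting one half
oracleAUC <- function(scores, labels, positive = "high") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  conc <- 0
  for (sp in pos) conc <- conc + sum(sp > neg) + 0.5 * sum(sp == neg)
  conc / (length(pos) * length(neg))
}
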