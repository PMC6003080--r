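# Independent oracles used across tests. Deliberately naive and written
# against the definitions, not against the package internals.

# Shannon entropy in bits of a label vector (or of a count vector when
# counts = TRUE)
oracleEntropy <- function(x, counts = FALSE) {
  p <- if (counts) x else as.vector(table(x))
  p <- p[p > 0] / sum(p)
  -sum(p * log2(p))
}

# Information gain of a fixed binning, straight from the definition
oracleIG <- function(bins, labels) {
  n <- length(labels)
  cond <- 0
  for (b in unique(bins)) {
    sel <- bins == b
    cond <- cond + sum(sel) / n * oracleEntropy(labels[sel])
  }
  oracleEntropy(labels) - cond
}

# Brute-force recursive MDL discretization: every midpoint between
# adjacent distinct sorted values is evaluated by direct subsetting;
# the best-gain cut (smallest value on ties) is tested against the MDL
# acceptance inequality and recursion continues on both sides.
oracleMdlp <- function(values, labels) {
  labels <- droplevels(factor(labels))
  rec <- function(v, y) {
    o <- order(v); v <- v[o]; y <- y[o]
    n <- length(v)
    if (n < 2L) return(numeric(0))
    cand <- unique((v[-n] + v[-1L])[v[-n] != v[-1L]] / 2)
    if (!length(cand)) return(numeric(0))
    entS <- oracleEntropy(y)
    gains <- vapply(cand, function(cp) {
      L <- y[v <= cp]; R <- y[v > cp]
      entS - length(L) / n * oracleEntropy(L) -
        length(R) / n * oracleEntropy(R)
    }, numeric(1))
    best <- which.max(gains)   # midpoints ascend, so first max = smallest
    cp <- cand[best]
    L <- y[v <= cp]; R <- y[v > cp]
    k <- length(unique(y)); k1 <- length(unique(L)); k2 <- length(unique(R))
    delta <- log2(3^k - 2) -
      (k * entS - k1 * oracleEntropy(L) - k2 * oracleEntropy(R))
    if (gains[best] > (log2(n - 1) + delta) / n)
      sort(c(cp, rec(v[v <= cp], y[v <= cp]), rec(v[v > cp], y[v > cp])))
    else numeric(0)
  }
  rec(as.numeric(values), labels)
}
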