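#' Shannon entropy (bits) of a class-count vector
#' @noRd
.entropyCounts <- function(cnt) {
  n <- sum(cnt)
  if (n == 0) return(0)
  p <- cnt[cnt > 0] / n
  -sum(p * log2(p))
}

#' Row-wise entropy of a counts matrix (bits)
#' @noRd
.rowEntropy <- function(M) {
  n <- rowSums(M)
  P <- M / pmax(n, 1)
  E <- P * log2(P)
  E[P == 0] <- 0
  -rowSums(E)
}

#' Supervised multi-interval discretization (Fayyad-Irani MDL)
#'
#' Recursively splits a continuous feature on the class-boundary midpoint
#' that maximizes information gain, accepting a split only when
#' `gain > (log2(N - 1) + delta) / N` with
#' `delta = log2(3^k - 2) - (k*Ent(S) - k1*Ent(S1) - k2*Ent(S2))`,
#' where `k`, `k1`, `k2` count the classes present in the segment and its
#' two halves. Accepted splits are applied recursively to both sides.
#' Candidate cut points are midpoints between adjacent distinct values;
#' ties on gain resolve to the smallest cut value. The procedure is
#' deterministic; a constant feature (or one where no split passes the
#' MDL test) yields an empty cut list, which downstream means a single
#' bin and an information gain of exactly zero.
#'
#' @param values numeric vector, one value per sample.
#' @param labels factor (or coercible) of per-sample classes, same length.
#' @return A `DiscretizationScheme`: list with `cutPoints`, a strictly
#'   increasing numeric vector (possibly empty).
#' @examples
#' mdlpDiscretize(c(1, 2, 3, 10, 11, 12), rep(c("A", "B"), each = 3))
#' @export
mdlpDiscretize <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 1)
  y <- as.integer(droplevels(factor(labels)))
  K <- max(y)
  ord <- order(values)
  v <- as.numeric(values)[ord]
  y <- y[ord]

  cuts <- numeric(0)
  recurse <- function(v, y) {
    n <- length(v)
    if (n < 2L || v[1] == v[n]) return()
    # cumulative class counts after each position
    C <- vapply(seq_len(K), function(k) cumsum(y == k), numeric(n))
    tot <- C[n, ]
    cand <- which(v[-n] != v[-1L])
    if (!length(cand)) return()
    L <- C[cand, , drop = FALSE]
    R <- rep(tot, each = length(cand)) - L
    dim(R) <- dim(L)
    nL <- rowSums(L); nR <- n - nL
    entS <- .entropyCounts(tot)
    entL <- .rowEntropy(L); entR <- .rowEntropy(R)
    gain <- entS - (nL / n) * entL - (nR / n) * entR
    best <- which.max(gain)  # first max = smallest cut value
    i <- cand[best]
    k  <- sum(tot > 0)
    k1 <- sum(L[best, ] > 0)
    k2 <- sum(R[best, ] > 0)
    delta <- log2(3^k - 2) - (k * entS - k1 * entL[best] - k2 * entR[best])
    if (gain[best] > (log2(n - 1) + delta) / n) {
      cuts <<- c(cuts, (v[i] + v[i + 1L]) / 2)
      recurse(v[seq_len(i)], y[seq_len(i)])
      recurse(v[(i + 1L):n], y[(i + 1L):n])
    }
  }
  recurse(v, y)
  structure(list(cutPoints = sort(cuts)), class = "DiscretizationScheme")
}

#' Information gain of a discretized feature (bits)
#'
#' `IG = H(L) - sum_b (n_b / n) * H(L | bin b)` with base-2 entropy,
#' where a value `v` falls in bin `sum(cutPoints < v)`. A scheme with no
#' cut points puts everything in one bin and returns exactly 0. Supports
#' any number of classes; `0 <= IG <= log2(#classes)`.
#'
#' @param scheme a `DiscretizationScheme` from [mdlpDiscretize()].
#' @param values numeric vector the scheme applies to.
#' @param labels factor (or coercible) of per-sample classes.
#' @return numeric scalar, non-negative.
#' @export
informationGain <- function(scheme, values, labels) {
  stopifnot(inherits(scheme, "DiscretizationScheme"),
            length(values) == length(labels))
  cuts <- scheme$cutPoints
  if (!length(cuts)) return(0)
  y <- droplevels(factor(labels))
  bins <- findInterval(values, cuts, left.open = TRUE)
  tab <- table(bins, y)
  n <- length(values)
  condEnt <- sum(rowSums(tab) / n * .rowEntropy(unclass(tab)))
  max(0, .entropyCounts(table(y)) - condEnt)
}

#' Fit-and-score helper: MDL discretization followed by IG
#' @noRd
.featureIG <- function(values, labels) {
  informationGain(mdlpDiscretize(values, labels), values, labels)
}
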