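# Exhaustive enumeration of small discretization inputs: all
# non-decreasing value sequences of length n over at most `maxDistinct`
# distinct values (canonical up to monotone relabeling), crossed with all
# k-class label assignments.
compositions <- function(n, maxParts) {
  out <- list()
  recurse <- function(remaining, parts) {
    if (remaining == 0L) { out[[length(out) + 1L]] <<- parts; return() }
    if (length(parts) == maxParts) return()
    for (p in seq_len(remaining)) recurse(remaining - p, c(parts, p))
  }
  recurse(n, integer())
  out
}

enumValueVectors <- function(n, maxDistinct = 4) {
  lapply(compositions(n, maxDistinct), function(cp) rep(seq_along(cp), cp))
}

enumLabelMatrix <- function(n, k) {
  # k^n rows of label assignments 1..k
  as.matrix(do.call(expand.grid, rep(list(seq_len(k)), n)))
}
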