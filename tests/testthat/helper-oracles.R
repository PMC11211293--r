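# Independent brute-force oracles used to cross-check the implementations.

# Voxel-by-voxel enumeration of overlap counts on tiny grids.
oracle_overlap <- function(pred, truth) {
  np <- 0L; ng <- 0L; ni <- 0L
  for (i in seq_along(pred)) {
    p <- pred[[i]] != 0
    g <- truth[[i]] != 0
    if (p) np <- np + 1L
    if (g) ng <- ng + 1L
    if (p && g) ni <- ni + 1L
  }
  list(dsc = if (np + ng == 0) 1 else 2 * ni / (np + ng),
       vs = if (np + ng == 0) 1 else 1 - abs(ng - np) / (ng + np))
}

# O(n^2) all-pairs scan for the longest contiguous covered arc.
oracle_longest_run <- function(covered, arc) {
  best <- 0
  n <- length(covered)
  for (i in seq_len(n)) {
    if (!covered[i]) next
    for (j in i:n) {
      if (!covered[j]) break
      best <- max(best, arc[j] - arc[i])
    }
  }
  best
}
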