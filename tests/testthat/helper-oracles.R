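# Brute-force oracles, independent of the package's implementations.

# Mann-Whitney U by direct pair enumeration (min of the two conventions).
oracle_u <- function(x, y) {
  gt <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  min(gt, length(x) * length(y) - gt)
}

# Pearson chi-square by direct summation over cells.
oracle_chisq <- function(counts) {
  n <- sum(counts)
  total <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      total <- total + (counts[i, j] - e)^2 / e
    }
  }
  total
}

# One-way F from explicit sums of squares.
oracle_f <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in unique(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  k <- length(unique(groups))
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# Pooled-variance t from first principles.
oracle_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Does a garment ordering respect every dependency edge?
oracle_order_ok <- function(ordering, edges) {
  all(apply(edges, 1, function(e)
    match(e[1], ordering) < match(e[2], ordering)))
}

# All permutations of a small vector.
permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Build a simple click-only log for a game.
make_log <- function(game, t, kind = rep("click", length(t)),
                     target = rep("", length(t)), meta = list()) {
  event_log(game, "test", t = t, kind = kind, target = target, meta = meta)
}
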