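# Independent brute-force oracles shared across test files.

# naive agglomeration: repeatedly merge the closest pair under the linkage
brute_hclust_heights <- function(d, linkage = "complete") {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dij <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      v <- if (linkage == "complete") max(dij) else mean(dij)
      if (v < best[1]) best <- c(v, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# two-group log-rank by direct observed-minus-expected accumulation
logrank_oracle <- function(time, event, grp) {
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    n <- sum(time >= t); n1 <- sum(time >= t & grp == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# all permutations of a vector (exhaustive assignment search)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}
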