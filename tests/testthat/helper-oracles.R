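## Independent oracles and small fixture builders used across the suite.

## Brute-force agglomerative clustering on a distance matrix. Tracks the
## merge heights and the partition after every merge; independent of
## stats::hclust.
naive_agglomerate <- function(D, method = "complete") {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  ids <- seq_len(n)
  next_id <- n
  heights <- numeric(0)
  partitions <- list()
  memb <- seq_len(n)
  cdist <- function(a, b) {
    d <- D[members[[a]], members[[b]], drop = FALSE]
    switch(method, complete = max(d), average = mean(d), single = min(d))
  }
  while (length(ids) > 1) {
    k <- length(ids)
    best <- c(Inf, NA, NA)
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      dd <- cdist(ids[i], ids[j])
      if (dd < best[1]) best <- c(dd, ids[i], ids[j])
    }
    next_id <- next_id + 1
    members[[next_id]] <- c(members[[best[2]]], members[[best[3]]])
    ids <- c(setdiff(ids, best[2:3]), next_id)
    heights <- c(heights, best[1])
    memb[members[[next_id]]] <- next_id
    partitions[[length(partitions) + 1]] <- match(memb, unique(memb))
  }
  list(heights = heights, partitions = partitions)
}

## TRUE iff two label vectors describe the same partition.
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

## Small annotation handy for unit tests.
tiny_annotation <- function(n = 200, seed = 42) {
  simulateAnnotation(n, max(10, n %/% 10), seed = seed)
}
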