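# Shared fixtures and independent oracles used across the suite.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

kmers_of <- function(s, k) {
  n <- nchar(s) - k + 1L
  substring(s, seq_len(n), seq_len(n) + k - 1L)
}

# quadratic brute force for the one-sided LRD partial sum: for each k-mer
# of x, scan every position of y for an identical k-mer and take the
# nearest; k-mers containing N match nothing
delta_brute <- function(x, y, k, m) {
  kx <- kmers_of(x, k)
  ky <- kmers_of(y, k)
  total <- 0
  for (p in seq_along(kx)) {
    if (grepl("N", kx[p], fixed = TRUE)) {
      total <- total + m
      next
    }
    q <- which(ky == kx[p] & !grepl("N", ky, fixed = TRUE))
    d <- if (length(q)) min(abs(q - p)) else Inf
    total <- total + min(d, m)
  }
  total
}

# same brute force but with the nearest-occurrence search restricted to a
# window of radius m around each k-mer (cap-equivalence oracle)
delta_brute_windowed <- function(x, y, k, m) {
  kx <- kmers_of(x, k)
  ky <- kmers_of(y, k)
  total <- 0
  for (p in seq_along(kx)) {
    lo <- max(1L, p - m); hi <- min(length(ky), p + m)
    q <- if (lo <= hi) {
      win <- lo:hi
      win[ky[win] == kx[p] & !grepl("N", kx[p], fixed = TRUE) &
            !grepl("N", ky[win], fixed = TRUE)]
    } else integer()
    d <- if (length(q)) min(abs(q - p)) else Inf
    total <- total + min(d, m)
  }
  total
}

# brute-force best window: delta_one_sided(window, read) at every start
align_brute <- function(read, reference, k, m) {
  L <- nchar(read)
  n_win <- nchar(reference) - L + 1L
  dists <- vapply(seq_len(n_win) - 1L, function(i) {
    delta_one_sided(substr(reference, i + 1L, i + L), read, k, m)
  }, numeric(1L))
  best <- which.min(dists) # first minimum = leftmost
  list(position = best - 1L, distance = dists[best], all = dists)
}

# Mann-Whitney pair-counting AUC: wins + half-ties over all
# positive x negative pairs (lower distance ranks better)
auc_pairwise <- function(distances, labels) {
  d <- ifelse(is.na(distances), Inf, distances)
  dp <- d[labels == "positive"]
  dn <- d[labels == "negative"]
  total <- 0
  for (p in dp) total <- total + sum(p < dn) + 0.5 * sum(p == dn)
  total / (length(dp) * length(dn))
}

# small parameter set used by toy alignment tests (short reads, so the
# default m = 24 would violate m <= read length)
toy_params <- function(...) {
  align_params(k = 2, m = 4, threshold = 1e9, ...)
}

mutate_positions <- function(s, idx) {
  # deterministic point mutations at the given 1-based positions
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in idx) b[i] <- setdiff(c("A", "C", "G", "T"), b[i])[1L]
  paste(b, collapse = "")
}
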