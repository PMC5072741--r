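# Shared fixtures: random adenine-centered contexts, motif instances, and
# an independent Levenshtein oracle (full dynamic-programming table, no
# shortcuts) used to check the C++ implementation.

BASES <- c("A", "C", "G", "T")

rand_context <- function(n, L = 41L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  center <- (L + 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    b <- sample(BASES, L, replace = TRUE)
    b[center] <- "A"
    paste(b, collapse = "")
  }, character(1))
}

# mutate exactly k non-center positions of a context
mutate_context <- function(s, k) {
  b <- strsplit(s, "")[[1L]]
  center <- (nchar(s) + 1L) %/% 2L
  idx <- sample(setdiff(seq_along(b), center), k)
  for (i in idx) b[i] <- sample(setdiff(BASES, b[i]), 1L)
  paste(b, collapse = "")
}

# n noisy instances of one consensus (per-position mutation prob p)
motif_contexts <- function(n, L = 41L, p = 0.05, seed = 1L) {
  set.seed(seed)
  center <- (L + 1L) %/% 2L
  cons <- sample(BASES, L, replace = TRUE)
  cons[center] <- "A"
  vapply(seq_len(n), function(i) {
    b <- cons
    hit <- setdiff(which(runif(L) < p), center)
    for (j in hit) b[j] <- sample(setdiff(BASES, b[j]), 1L)
    paste(b, collapse = "")
  }, character(1))
}

# independent full-table Levenshtein (unit costs)
lev_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1L]]; b <- strsplit(b, "")[[1L]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n; d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1L, j + 1L] <- min(d[i, j] + (a[i] != b[j]),
                             d[i, j + 1L] + 1L, d[i + 1L, j] + 1L)
  d[n + 1L, m + 1L]
}

rand_string <- function(len, alphabet = BASES) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a small test genome with a known adenine at a known place
toy_genome <- function() c(c1 = "CCCACCC", c2 = "CCCTCCC", c3 = "CCCGCCC")
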