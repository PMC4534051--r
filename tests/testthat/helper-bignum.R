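# Minimal exact big-integer arithmetic (base 1e4, little-endian numeric
# digit vectors) used only as an independent oracle for the hypergeometric
# tail. Binomials come from a cached Pascal triangle built by addition, so
# the oracle shares no code path with the package implementation.

BIG_BASE <- 1e4

big_norm <- function(s) {
  repeat {
    carry <- floor(s / BIG_BASE)
    if (all(carry == 0)) break
    s <- s - carry * BIG_BASE
    s <- c(s, 0) + c(0, carry)
  }
  while (length(s) > 1 && s[length(s)] == 0) s <- s[-length(s)]
  s
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  s <- numeric(n)
  s[seq_along(a)] <- a
  s[seq_along(b)] <- s[seq_along(b)] + b
  big_norm(s)
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (j in seq_along(b)) {
    idx <- j:(j + length(a) - 1)
    res[idx] <- res[idx] + a * b[j]
  }
  big_norm(res)
}

big_to_double <- function(a) sum(a * BIG_BASE^(seq_along(a) - 1))

.pascal_cache <- new.env(parent = emptyenv())
.pascal_cache$rows <- list(list(1))  # row for n = 0

big_choose <- function(n, k) {
  if (k < 0 || k > n) return(0)
  rows <- .pascal_cache$rows
  while (length(rows) < n + 1) {
    prev <- rows[[length(rows)]]
    m <- length(rows)              # building row for n = m
    row <- vector("list", m + 1)
    row[[1]] <- 1
    row[[m + 1]] <- 1
    if (m > 1) {
      for (k2 in 2:m) row[[k2]] <- big_add(prev[[k2 - 1]], prev[[k2]])
    }
    rows[[m + 1]] <- row
  }
  .pascal_cache$rows <- rows
  rows[[n + 1]][[k + 1]]
}

# Exact upper-tail hypergeometric probability via big-integer summation.
hyper_tail_oracle <- function(N, K, n, n_f) {
  if (n_f == 0) return(1)
  num <- 0
  for (k in n_f:min(n, K)) {
    if (n - k > N - K) next
    term <- big_mul(big_choose(K, k), big_choose(N - K, n - k))
    num <- big_add(num, term)
  }
  big_to_double(num) / big_to_double(big_choose(N, n))
}
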