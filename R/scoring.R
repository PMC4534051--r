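#' Exact right-tailed hypergeometric network p-value
#'
#' Probability of finding `n_f` or more focus genes in a set of `n` genes
#' drawn at random (without replacement) from a knowledge base of `N` genes
#' of which `K` are focus genes:
#' \deqn{p = \sum_{k=n_f}^{\min(n,K)} \binom{K}{k}\binom{N-K}{n-k} / \binom{N}{n}.}
#' The tail is computed exactly — terms are evaluated in log space via
#' `lchoose()` to avoid underflow and summed smallest-first with compensated
#' (Kahan) summation; no normal approximation is used.
#'
#' @param N population size (genes in the knowledge base).
#' @param K number of focus genes in the population.
#' @param n network size.
#' @param n_f number of focus genes in the network.
#' @return p-value in (0, 1].
#' @examples
#' network_pvalue(100, 10, 10, 5)
#' network_pvalue(100, 10, 10, 0)  # tail includes everything: 1
#' @export
network_pvalue <- function(N, K, n, n_f) {
  if (length(N) != 1 || length(K) != 1 || length(n) != 1 || length(n_f) != 1)
    stop("network_pvalue is not vectorized")
  if (anyNA(c(N, K, n, n_f))) stop("arguments must be non-missing")
  if (K > N || n > N) stop("K and n must not exceed N")
  if (n_f < 0 || n_f > min(n, K)) {
    stop("n_f must satisfy 0 <= n_f <= min(n, K)")
  }
  if (n_f == 0) return(1)
  ks <- seq.int(n_f, min(n, K))
  # a term is zero when n - k > N - K; lchoose returns -Inf there already
  logterms <- lchoose(K, ks) + lchoose(N - K, n - ks) - lchoose(N, n)
  terms <- sort(exp(logterms))          # ascending: add small terms first
  s <- 0; c <- 0
  for (t in terms) {                    # Kahan compensated summation
    y <- t - c
    tt <- s + y
    c <- (tt - s) - y
    s <- tt
  }
  min(1, max(s, 0))
}

#' Network score
#'
#' The score used to rank networks: `-log10(p value)`. A significance level
#' of p < 1e-5 corresponds to score > 5.
#'
#' @param p p-value in (0, 1].
#' @return Non-negative score, vectorized over `p`.
#' @examples
#' network_score(1e-12)  # 12
#' network_score(1)      # 0
#' @export
network_score <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p must lie in (0, 1]")
  }
  -log10(p)
}

# attach n, n_f, p and score to a grown network
score_network <- function(kb, net, focus_ids, config) {
  genes_only <- !isTRUE(config$count_nongene_nodes)
  kinds <- kb$molecules$kind[match(kb$ids, kb$molecules$id)]
  in_pop <- if (genes_only) kinds == "gene" else rep(TRUE, length(kb$ids))
  N <- sum(in_pop)
  pop_ids <- kb$ids[in_pop]
  K <- length(intersect(focus_ids, pop_ids))
  member <- intersect(net$genes, pop_ids)
  n <- length(member)
  n_f <- length(intersect(net$focus_genes, member))
  p <- if (n == 0) 1 else network_pvalue(N, K, n, n_f)
  net$n <- n
  net$n_f <- n_f
  net$p_value <- p
  net$score <- network_score(p)
  net$significant <- p < config$significance_p
  class(net) <- c("scored_network", class(net))
  net
}

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("<scored_network: n = %d genes (%d focus), p = %.3g, score = %.2f%s>\n",
              x$n, x$n_f, x$p_value, x$score,
              if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Keep significant networks
#'
#' Filters scored networks at a nominal p-value threshold (no
#' multiple-testing correction) and orders them by descending score.
#'
#' @param nets list of scored networks (e.g. from [core_analysis()]).
#' @param threshold p-value threshold in (0, 1); default `1e-5`.
#' @return List of the networks with `p_value < threshold`, best first.
#' @export
filter_significant <- function(nets, threshold = 1e-5) {
  stopifnot(threshold > 0, threshold < 1)
  keep <- vapply(nets, function(x) x$p_value < threshold, logical(1))
  nets <- nets[keep]
  nets[order(-vapply(nets, `[[`, 0, "score"))]
}
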