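#' Connection counts within a network
#'
#' Simple-view degree of every gene inside a network (the induced subgraph
#' on the network's genes), the quantity used to rank genes and call hubs.
#'
#' @param kb a `knowledge_base`; either a full knowledge base (supply
#'   `genes`) or an already-induced subnetwork.
#' @param genes optional character vector of network member ids; when given,
#'   counts are computed on [induced_network()] of these genes.
#' @return Named integer vector, sorted by descending count then id.
#' @export
count_connections <- function(kb, genes = NULL) {
  if (!is.null(genes)) kb <- induced_network(kb, genes)
  counts <- lengths(kb$adj)
  names(counts) <- kb$ids
  counts[order(-counts, names(counts), method = "radix")]
}

#' Detect hub genes
#'
#' Hubs are genes with at least `min_connections` connections inside a
#' network; highly connected molecules are commonly taken as markers of
#' biological importance. The report is sorted by descending connection
#' count and flags focus genes.
#'
#' @param counts named integer vector of connection counts (from
#'   [count_connections()] or a packaged hub table).
#' @param min_connections hub threshold; the published analyses use 15.
#' @param focus character vector of focus-gene ids, used to flag entries.
#' @return A `hub_report`: data.frame with columns `gene`, `connections`,
#'   `is_focus`, threshold stored in attribute `"min_connections"`.
#' @export
find_hubs <- function(counts, min_connections = 15, focus = character()) {
  stopifnot(min_connections >= 0)
  if (length(counts) == 0) {
    out <- data.frame(gene = character(), connections = integer(),
                      is_focus = logical(), stringsAsFactors = FALSE)
  } else {
    keep <- counts >= min_connections
    gene <- names(counts)[keep]
    cc <- unname(counts[keep])
    o <- order(-cc, gene, method = "radix")
    out <- data.frame(gene = gene[o], connections = as.integer(cc[o]),
                      is_focus = gene[o] %in% focus,
                      stringsAsFactors = FALSE)
  }
  attr(out, "min_connections") <- min_connections
  class(out) <- c("hub_report", class(out))
  out
}

#' Log-log power-law diagnostic
#'
#' The classic scale-free check: plot log10 degree against log10 frequency
#' and look for a decaying straight line. This function performs the
#' ordinary least-squares fit behind that plot and reports slope, intercept
#' and R-squared — no scale-free yes/no verdict is emitted, because a raw
#' log-log fit cannot justify one. Only degrees >= 1 enter the fit. The
#' default uses raw degree frequencies; `mode = "ccdf"` fits the
#' complementary cumulative distribution instead, which is less noisy.
#'
#' @param degrees integer vector of degrees (e.g. [degree_sequence()]).
#' @param mode `"frequency"` (raw degree-frequency points) or `"ccdf"`.
#' @return A `powerlaw_fit`: list with `slope`, `intercept`, `r_squared`,
#'   `mode` and `points` (data.frame of the log10 pairs used).
#' @examples
#' # an exact power law freq(k) = 64 * k^-2 at k = 1, 2, 4, 8
#' fit <- loglog_powerlaw_fit(rep(c(1, 2, 4, 8), c(64, 16, 4, 1)))
#' fit$slope  # -2
#' @export
loglog_powerlaw_fit <- function(degrees, mode = c("frequency", "ccdf")) {
  mode <- match.arg(mode)
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  f <- as.numeric(tab)
  if (length(k) < 3) {
    stop("insufficient data: need at least 3 distinct positive degrees")
  }
  if (mode == "ccdf") {
    # P(degree >= k), scaled by n so the intercept stays comparable
    f <- rev(cumsum(rev(f)))
  }
  x <- log10(k)
  y <- log10(f)
  fit <- stats::lm(y ~ x)
  # R^2 computed directly; summary.lm warns on exact fits
  tss <- sum((y - mean(y))^2)
  rsq <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = rsq,
                 mode = mode,
                 points = data.frame(log10_degree = x, log10_frequency = y)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit (%s): slope = %.4f, intercept = %.4f, R^2 = %.4f, %d points>\n",
              x$mode, x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Plot a log-log degree-distribution fit
#'
#' @param x a `powerlaw_fit`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.powerlaw_fit <- function(x, ...) {
  plot(x$points$log10_degree, x$points$log10_frequency,
       xlab = "log10 degree",
       ylab = if (x$mode == "frequency") "log10 frequency" else "log10 CCDF count",
       ...)
  graphics::abline(x$intercept, x$slope, lty = 2)
  invisible(x)
}
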