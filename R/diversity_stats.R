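#' Estimate the empirical null over cluster-formation trajectories
#'
#' The indicator `X_n` that the nth target of an anchor/direction opened a
#' new cluster is modelled as Bernoulli(`p_n`).  Pooling all trajectories
#' (upstream and downstream; ragged lengths allowed), the per-rank success
#' probability is estimated as
#' \deqn{\hat p_n = \sum_m x_{m,n} / \sum_m 1\{N_m \ge n\}.}
#' Trajectories shorter than the testing threshold still contribute to the
#' ranks they reach.  The estimate is valid because the overwhelming
#' majority of anchors sit nowhere near a hyper-variable region; any
#' hyper-diverse trajectories included only make the downstream test more
#' conservative.
#'
#' @param x Either a list of binary (0/1) trajectory vectors, or an
#'   `anchor_store` (whose pooled per-rank sums are used directly).
#' @return An object of class `null_model`: list with `p_hat`, `numer`,
#'   `denom` (per rank `n = 1..max N`).
#' @export
#' @examples
#' estimate_null(list(c(1, 1, 0), c(1, 0)))$p_hat  # 1, 1/2, 0
estimate_null <- function(x) {
  if (inherits(x, "anchor_store")) {
    numer <- x$null_numer
    denom <- x$null_denom
  } else {
    if (!is.list(x) || length(x) == 0)
      stop("no trajectories: cannot calibrate the null model")
    lens <- lengths(x)
    x <- x[lens > 0]
    lens <- lens[lens > 0]
    if (length(x) == 0)
      stop("no non-empty trajectories: cannot calibrate the null model")
    max_n <- max(lens)
    m <- vapply(x, function(t) c(t, rep(NA_real_, max_n - length(t))),
                numeric(max_n))
    m <- matrix(m, nrow = max_n)  # ranks x trajectories
    numer <- rowSums(m, na.rm = TRUE)
    denom <- rowSums(!is.na(m))
  }
  keep <- which(denom > 0)
  if (length(keep) == 0)
    stop("no trajectories: cannot calibrate the null model")
  max_n <- max(keep)
  numer <- numer[seq_len(max_n)]
  denom <- denom[seq_len(max_n)]
  p_hat <- ifelse(denom > 0, numer / denom, NA_real_)
  structure(list(p_hat = p_hat, numer = numer, denom = denom),
            class = "null_model")
}

#' @export
print.null_model <- function(x, ...) {
  cat("null_model over", length(x$p_hat), "ranks;",
      "p_hat[1] =", x$p_hat[1],
      " mean p_hat[-1] =", mean(x$p_hat[-1], na.rm = TRUE), "\n")
  invisible(x)
}

# All upper-tail probabilities P[C >= c], c = 1..N, of the
# Poisson-Binomial(p_1..p_N) via discrete-Fourier inversion of the
# characteristic function with R = exp(2*pi*i/(N+1)):
#   P[C = j] = (N+1)^-1 sum_l R^{-lj} prod_n (1 + (R^l - 1) p_n)
# The product is evaluated as a sum of complex logs for N > 30 (each
# factor has modulus <= 1, so the direct product only shrinks; the log
# path guards long products against underflow).
pb_tail_table <- function(p_hat) {
  N <- length(p_hat)
  stopifnot(N >= 1, all(p_hat >= 0), all(p_hat <= 1))
  w <- exp(2i * pi * (0:N) / (N + 1))          # R^l, l = 0..N
  fac <- 1 + outer(w - 1, p_hat)               # (N+1) x N
  if (N > 30) z <- exp(rowSums(log(fac))) else z <- apply(fac, 1, prod)
  pmf <- Re(fft(z)) / (N + 1)                  # fft gives sum_l z_l R^{-lj}
  pmf <- pmax(pmf, 0)
  tails <- rev(cumsum(rev(pmf)))[-1]           # P[C >= c], c = 1..N
  pmin(1, pmax(0, tails))
}

#' Poisson-Binomial upper-tail p-value for an observed cluster count
#'
#' Probability that the number of clusters `C_N`, distributed as
#' Poisson-Binomial(`p_hat[1..N]`), is at least `c` -- i.e. that the
#' observed diversity is explained by background biological (point
#' mutations) and technical (sequencing error) variability.  Computed by
#' roots-of-unity inversion of the characteristic function (see
#' `vignette("flankdiv-methods")`), real part taken, clamped to `[0, 1]`.
#'
#' @param c Observed number of clusters (`1 <= c <= N`).
#' @param p_hat Per-rank new-cluster probabilities; the first `N` entries
#'   are used.
#' @param N Number of targets observed (default `length(p_hat)`).
#' @return The p-value `P[C_N >= c]`.
#' @export
#' @examples
#' poisson_binomial_tail(1, c(1, 0.3, 0.3))  # 1: one cluster is certain
poisson_binomial_tail <- function(c, p_hat, N = length(p_hat)) {
  if (c < 1 || c > N) stop("c must satisfy 1 <= c <= N")
  if (length(p_hat) < N) stop("p_hat must provide at least N entries")
  pb_tail_table(p_hat[seq_len(N)])[c]
}

#' Memory-efficient Benjamini-Hochberg correction
#'
#' The streaming pipeline records only the total number of tests `m` and
#' the p-values at most `p_drop` (default 0.1); larger p-values are dropped
#' before ranking and never assigned a q-value.  Retained p-values are
#' sorted ascending and adjusted as `q(i) = p(i) * m / i`.  By default the
#' standard step-up monotone enforcement `q(i) := min_{j>=i} p(j) m / j` is
#' applied (capped at 1); set `monotone = FALSE` for the raw ratios.
#'
#' @param p Numeric vector of p-values (any order).
#' @param m Total number of tests performed (`>= sum(p <= p_drop)`).
#' @param p_drop Drop threshold (default 0.1); entries with `p > p_drop`
#'   get `NA`.
#' @param monotone Apply step-up monotone enforcement (default `TRUE`).
#' @return q-values aligned with `p` (`NA` where dropped).
#' @export
#' @examples
#' bh_correct(c(0.01, 0.04), m = 2)  # 0.02 0.04
bh_correct <- function(p, m, p_drop = 0.1, monotone = TRUE) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  keep <- which(!is.na(p) & p <= p_drop)
  if (m < length(keep)) stop("m must be at least the number of retained tests")
  q <- rep(NA_real_, length(p))
  if (length(keep) == 0) return(q)
  ord <- keep[order(p[keep])]
  qi <- p[ord] * m / seq_along(ord)
  if (monotone) qi <- rev(cummin(rev(qi)))
  q[ord] <- pmin(1, qi)
  q
}

#' Effect size: log2 observed over expected cluster count
#'
#' \eqn{\alpha = \log_2(C_N / E[C_N \mid N])} with
#' \eqn{E[C_N \mid N] = \sum_{n=1}^N \hat p_n}, the mean of the
#' Poisson-Binomial null.  A positive value means more target clusters than
#' background variability explains; `alpha` can rank hits by diversity.
#'
#' @param C Observed cluster counts (vectorised).
#' @param N Targets observed (vectorised, same length as `C`).
#' @param p_hat Per-rank null probabilities covering `max(N)` ranks.
#' @return Numeric vector of effect sizes.
#' @export
#' @examples
#' effect_size(5, 5, c(1, .2, .2, .2, .2))  # log2(5 / 1.8)
effect_size <- function(C, N, p_hat) {
  stopifnot(length(C) == length(N), all(N >= 1), length(p_hat) >= max(N))
  expected <- cumsum(p_hat)[N]
  if (any(expected <= 0)) stop("expected cluster count is zero")
  log2(C / expected)
}

#' Test every anchor/direction for target hyper-diversity
#'
#' For each anchor and direction with at least `Nmin` targets, computes the
#' Poisson-Binomial tail p-value of the observed cluster count under the
#' empirical null, applies the memory-efficient BH correction (`m` counts
#' both directions), and attaches the effect size.  Tail tables are cached
#' per distinct `N`, so the cost is O(distinct N * Nmax^2) plus a lookup
#' per test.
#'
#' @param store An `anchor_store`.
#' @param null A `null_model`; fitted from the store itself when `NULL`.
#' @param config A [flankdiv_config()]; `Nmin`, `p_drop`, `q_cutoff` and
#'   `monotone_bh` are used.
#' @return A data.frame of class `diversity_results` with columns `anchor`,
#'   `direction`, `N`, `C_N`, `p_value`, `q_value` (`NA` where dropped),
#'   `alpha`, `max_within_read`, `significant` (`q < q_cutoff`), sorted by
#'   anchor then direction; attributes `m` (total tests), `n_retained`, and
#'   `null` carry the test ledger.
#' @export
test_diversity <- function(store, null = NULL, config = store$config) {
  stopifnot(inherits(store, "anchor_store"))
  if (is.null(null)) null <- estimate_null(store)
  a <- store$anchors
  rows <- rbind(
    data.frame(anchor = a$anchor, direction = "up", N = a$up_N, C_N = a$up_C,
               max_within_read = a$max_within_read, stringsAsFactors = FALSE),
    data.frame(anchor = a$anchor, direction = "down", N = a$down_N,
               C_N = a$down_C, max_within_read = a$max_within_read,
               stringsAsFactors = FALSE))
  rows <- rows[rows$N >= config$Nmin, , drop = FALSE]
  m <- nrow(rows)
  if (m == 0) {
    res <- data.frame(anchor = character(0), direction = character(0),
                      N = integer(0), C_N = integer(0),
                      p_value = numeric(0), q_value = numeric(0),
                      alpha = numeric(0), max_within_read = integer(0),
                      significant = logical(0))
    attr(res, "m") <- 0L
    attr(res, "n_retained") <- 0L
    attr(res, "null") <- null
    class(res) <- c("diversity_results", "data.frame")
    return(res)
  }
  if (length(null$p_hat) < max(rows$N))
    stop("null model covers fewer ranks than the largest N observed")
  p <- numeric(m)
  for (n in unique(rows$N)) {
    idx <- rows$N == n
    tails <- pb_tail_table(null$p_hat[seq_len(n)])
    p[idx] <- tails[rows$C_N[idx]]
  }
  q <- bh_correct(p, m = m, p_drop = config$p_drop,
                  monotone = config$monotone_bh)
  alpha <- effect_size(rows$C_N, rows$N, null$p_hat)
  res <- data.frame(anchor = rows$anchor, direction = rows$direction,
                    N = rows$N, C_N = rows$C_N, p_value = p, q_value = q,
                    alpha = alpha, max_within_read = rows$max_within_read,
                    significant = !is.na(q) & q < config$q_cutoff,
                    stringsAsFactors = FALSE)
  res <- res[order(res$anchor, res$direction), ]
  rownames(res) <- NULL
  attr(res, "m") <- m
  attr(res, "n_retained") <- sum(!is.na(q))
  attr(res, "null") <- null
  class(res) <- c("diversity_results", "data.frame")
  res
}

#' Write diversity results as TSV
#'
#' Deterministic column order; dropped q-values are written as `NA`.
#'
#' @param results A `diversity_results` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  cols <- c("anchor", "direction", "N", "C_N", "p_value", "q_value",
            "alpha", "max_within_read")
  out <- as.data.frame(results)[, cols]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
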