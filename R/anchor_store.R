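#' Jaccard similarity between two k-mers over their sub-k-mer sets
#'
#' Each k-mer is decomposed into the set of all overlapping sub-k-mers of
#' length `sub_k` (duplicates collapsed; `k - sub_k + 1` positions, e.g. 21
#' for `k = 27`, `sub_k = 7`), and the Jaccard similarity
#' \eqn{|X_1 \cap X_2| / |X_1 \cup X_2|} of the two sets is returned.
#'
#' @param t1,t2 DNA k-mers over `{A,C,G,T}` (equal length).
#' @param sub_k Sub-k-mer length (default 7).
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' jaccard_similarity(strrep("A", 27), strrep("A", 27))  # 1
#' jaccard_similarity(strrep("A", 27), strrep("C", 27))  # 0
jaccard_similarity <- function(t1, t2, sub_k = 7) {
  if (nchar(t1) != nchar(t2)) stop("t1 and t2 must have equal length")
  if (sub_k > nchar(t1)) stop("sub_k must not exceed the k-mer length")
  cpp_jaccard(t1, t2, as.integer(sub_k))
}

#' Create an empty target dictionary
#'
#' A target dictionary holds, for one anchor and one direction, the ordered
#' list of target clusters (`keys`, `counts`), the binary cluster-formation
#' trajectory `X_1..X_N` (1 = a new cluster was created on the nth target),
#' and the totals `N` (targets observed) and `C` (clusters formed).
#'
#' @return An object of class `target_dictionary`.
#' @export
target_dictionary <- function() {
  structure(list(keys = character(0), counts = integer(0),
                 trajectory = integer(0)),
            class = "target_dictionary")
}

#' Route one target into a target dictionary
#'
#' Scans existing clusters in insertion order; the first cluster whose key
#' has Jaccard similarity strictly greater than `js_threshold` with the
#' target gains a count, and with probability `replace_prob` its key is
#' replaced by the new target.  If no cluster matches, a new cluster is
#' appended.  Uses the session RNG, so wrap calls in `set.seed()` for
#' reproducibility.
#'
#' @param dict A `target_dictionary`.
#' @param target DNA k-mer.
#' @param js_threshold Similarity threshold (strict `>`; default 0.2).
#' @param sub_k Sub-k-mer length for the similarity (default 7).
#' @param replace_prob Probability of key replacement on recruitment
#'   (default 0.5; 0 keeps first-observed keys, a deterministic fixture).
#' @param Nmax Maximum targets per dictionary; when `N >= Nmax` the
#'   dictionary is closed and the call is a no-op flagged by the `"noop"`
#'   attribute on the returned object.
#' @return The updated `target_dictionary`.
#' @export
update_target_dictionary <- function(dict, target, js_threshold = 0.2,
                                     sub_k = 7, replace_prob = 0.5,
                                     Nmax = Inf) {
  stopifnot(inherits(dict, "target_dictionary"))
  if (length(dict$trajectory) >= Nmax) {
    attr(dict, "noop") <- TRUE
    return(dict)
  }
  res <- cpp_td_update(dict$keys, dict$counts, target, js_threshold,
                       as.integer(sub_k), replace_prob)
  dict$keys <- res$keys
  dict$counts <- res$counts
  dict$trajectory <- c(dict$trajectory, as.integer(res$new_cluster))
  dict
}

#' Probability of having observed zero targets after l records
#'
#' Under a per-read observation probability `p_min = Nmin / L`, the chance
#' that an anchor first seen now has produced no targets in the `l` records
#' already processed is `(1 - p_min)^l` (evaluated in log space).
#'
#' @param l Records processed so far.
#' @param p_min Per-read target observation probability.
#' @return Probability in `[0, 1]`.
#' @export
admission_zero_prob <- function(l, p_min) {
  stopifnot(l >= 0, p_min >= 0, p_min <= 1)
  if (p_min >= 1) return(as.numeric(l == 0))
  exp(l * log1p(-p_min))
}

#' Should the anchor dictionary stop admitting new anchors?
#'
#' Admission closes at the first record index `l` where an anchor appearing
#' for the first time would have less than a 1% chance of producing `Nmin`
#' targets by the end of the file, i.e. when `(1 - Nmin/L)^l < 0.01`.
#' Anchors already in the dictionary keep accumulating targets.
#'
#' @param l Records processed so far.
#' @param L Total records in the sample (after the cap).
#' @param Nmin Minimum targets required to test an anchor (default 25).
#' @param alpha Closing threshold (default 0.01).
#' @return `TRUE` once admission is closed.
#' @export
close_admission <- function(l, L, Nmin = 25, alpha = 0.01) {
  p_min <- min(1, Nmin / L)
  admission_zero_prob(l, p_min) < alpha
}

#' Probability that an anchor reaches Nmin targets by end of file
#'
#' With `x` targets seen in `l` records, the end-of-file target count is
#' modelled as Binomial(`L`, `x/l`).  For efficiency the binomial survival
#' function at `Nmin` is computed with the normal approximation
#' (mean `L x/l`, variance `L (x/l)(1 - x/l)`, continuity correction -0.5),
#' clamped to `[0, 1]`.  Anchors scoring below the retention cutoff (0.5)
#' are evicted from the store during the periodic sweep.
#'
#' @param x Targets observed so far (per direction).
#' @param l Records processed so far (must be positive).
#' @param L Total records in the sample.
#' @param Nmin Minimum target count (default 25).
#' @return Probability in `[0, 1]`.
#' @export
retention_probability <- function(x, l, L, Nmin = 25) {
  if (l <= 0) stop("l must be positive: the observation rate x/l is undefined")
  stopifnot(x >= 0, x <= l, l <= L)
  if (x == 0) return(if (Nmin <= 0) 1 else 0)
  rate <- min(1, x / l)
  mu <- L * rate
  v <- L * rate * (1 - rate)
  if (v <= 0) return(as.numeric(mu >= Nmin))
  min(1, max(0, pnorm(Nmin - 0.5, mean = mu, sd = sqrt(v),
                      lower.tail = FALSE)))
}

#' Build the anchor store by streaming a sample's reads
#'
#' Single pass over the reads: every valid anchor window is looked up in
#' the anchor dictionary; new anchors are admitted only while
#' [close_admission()] is `FALSE`; each upstream/downstream target is routed
#' into the matching directional dictionary (capped at `Nmax`) via
#' [update_target_dictionary()] semantics; a retention sweep
#' ([retention_probability()], cutoff 0.5, eviction on the max over the two
#' directions) runs every `sweep_every` records once admission has closed.
#' Anchors with `Nmax` targets in both directions are skipped entirely.
#'
#' @param reads Character vector of read sequences (one sample), e.g. from
#'   [stream_reads()]; multiple files can be concatenated.  Truncated to
#'   `config$max_records`.
#' @param config A [flankdiv_config()] list.
#' @param keep_trajectories Return per-anchor binary trajectories (default
#'   `TRUE`; needed by [estimate_null()] on small runs and for debugging --
#'   the pooled null numerators/denominators are always returned).
#' @param keep_clusters Return per-anchor cluster keys and counts (default
#'   `FALSE`; needed for across-sample target clustering).
#' @return An object of class `anchor_store`: a list with `anchors` (a
#'   data.frame with one row per surviving anchor: `anchor`, `up_N`, `up_C`,
#'   `down_N`, `down_C`, `max_within_read`, `first_seen`), pooled
#'   `null_numer` / `null_denom` per rank, `L`, `l_close`, `n_evicted`, and
#'   optionally trajectory and cluster lists.
#' @export
build_anchor_store <- function(reads, config = flankdiv_config(),
                               keep_trajectories = TRUE,
                               keep_clusters = FALSE) {
  reads <- as.character(reads)
  if (length(reads) > config$max_records)
    reads <- reads[seq_len(config$max_records)]
  res <- cpp_stream(reads, config$k, config$g, config$Nmin, config$Nmax,
                    config$js_threshold, as.integer(config$sub_k),
                    config$replace_prob, config$admission_alpha,
                    config$retention_cutoff, as.integer(config$sweep_every),
                    keep_trajectories, keep_clusters)
  anchors <- data.frame(anchor = res$anchor, up_N = res$up_N, up_C = res$up_C,
                        down_N = res$down_N, down_C = res$down_C,
                        max_within_read = res$max_within_read,
                        first_seen = res$first_seen, stringsAsFactors = FALSE)
  out <- list(anchors = anchors, null_numer = res$null_numer,
              null_denom = res$null_denom, L = res$L, l_close = res$l_close,
              n_evicted = res$n_evicted, config = config)
  if (keep_trajectories) {
    out$up_traj <- res$up_traj
    out$down_traj <- res$down_traj
  }
  if (keep_clusters) {
    out$up_keys <- res$up_keys; out$up_counts <- res$up_counts
    out$down_keys <- res$down_keys; out$down_counts <- res$down_counts
  }
  structure(out, class = "anchor_store")
}

#' @export
print.anchor_store <- function(x, ...) {
  cat("anchor_store:", nrow(x$anchors), "anchors from", x$L, "reads",
      "(admission closed at record", paste0(x$l_close, ";"),
      x$n_evicted, "evicted)\n")
  invisible(x)
}

#' Dump an anchor store as a TSV (debug aid)
#'
#' One row per anchor and direction with `N`, `C_N`, and (when the store
#' was built with `keep_clusters = TRUE`) the cluster keys and counts.
#'
#' @param store An `anchor_store`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
dump_anchor_store <- function(store, path) {
  a <- store$anchors
  fmt <- function(keys, counts) {
    if (is.null(keys)) return(rep(NA_character_, nrow(a)))
    vapply(seq_len(nrow(a)), function(i)
      paste(sprintf("%s:%d", keys[[i]], counts[[i]]), collapse = ","), "")
  }
  out <- rbind(
    data.frame(anchor = a$anchor, direction = "up", N = a$up_N, C_N = a$up_C,
               clusters = fmt(store$up_keys, store$up_counts)),
    data.frame(anchor = a$anchor, direction = "down", N = a$down_N,
               C_N = a$down_C, clusters = fmt(store$down_keys,
                                              store$down_counts)))
  out <- out[order(out$anchor, out$direction), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
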