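# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths (string sets instead
# of bit-packed k-mers, DP convolution instead of DFT inversion, BFS instead
# of igraph) so implementation and check cannot share a bug.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

write_fastq_fixture <- function(seqs, path, ids = sprintf("r%d", seq_along(seqs))) {
  lines <- as.vector(rbind(paste0("@", ids), seqs, "+",
                           strrep("I", nchar(seqs))))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  writeLines(lines, con)
  close(con)
  path
}

# Explicit string-set Jaccard over overlapping sub-k-mers.
js_oracle <- function(t1, t2, sub_k = 7) {
  subs <- function(t) unique(substring(t, seq_len(nchar(t) - sub_k + 1),
                                       seq_len(nchar(t) - sub_k + 1) + sub_k - 1))
  a <- subs(t1); b <- subs(t2)
  length(intersect(a, b)) / length(union(a, b))
}

# Poisson-Binomial upper tail by direct DP convolution of the PMF.
pb_dp_tail <- function(c, p) {
  pmf <- 1
  for (pn in p) pmf <- c(pmf * (1 - pn), 0) + c(0, pmf * pn)
  sum(pmf[(c + 1):length(pmf)])
}

# Levenshtein distance, plain DP (independent of utils::adist).
lev_oracle <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  prev <- 0:length(b)
  for (i in seq_along(a)) {
    cur <- c(i, rep(0L, length(b)))
    for (j in seq_along(b)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[length(b) + 1]
}

# Connected components of the <=eps edit-distance graph by BFS.
components_oracle <- function(anchors, eps = 2) {
  n <- length(anchors)
  comp <- rep(NA_integer_, n)
  nxt <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    nxt <- nxt + 1L
    queue <- s
    comp[s] <- nxt
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(n)) {
        if (is.na(comp[j]) && lev_oracle(anchors[i], anchors[j]) <= eps) {
          comp[j] <- nxt
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# Greedy count-ranked target clustering, re-implemented naively.
greedy_oracle <- function(targets, counts, js_threshold = 0.2, sub_k = 7) {
  ord <- order(-counts, targets)
  targets <- targets[ord]; counts <- counts[ord]
  cluster <- rep(NA_integer_, length(targets))
  cl <- 0L
  while (anyNA(cluster)) {
    cl <- cl + 1L
    seedi <- which(is.na(cluster))[1]
    for (j in which(is.na(cluster))) {
      if (j == seedi || js_oracle(targets[seedi], targets[j], sub_k) > js_threshold)
        cluster[j] <- cl
    }
  }
  data.frame(target = targets, cluster = cluster)
}

# All-pairs ROC AUC with half credit for ties.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# A mutated copy of a k-mer at a given number of substitutions.
mutate_kmer <- function(x, n_sub) {
  pos <- sample(nchar(x), n_sub)
  for (p in pos) {
    old <- substr(x, p, p)
    substr(x, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  x
}
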