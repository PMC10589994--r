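#' Cluster significant anchors by edit distance
#'
#' Density clustering with every point a core point (DBSCAN with
#' `min_samples = 1`) over Levenshtein edit distance reduces to the
#' connected components of the graph joining anchors at distance
#' `<= eps`: no noise points, transitive chaining.  Edit distances come
#' from `utils::adist()`; components from igraph.
#'
#' @param anchors Character vector of (significant) anchor sequences.
#' @param eps Edit-distance radius (default 2).
#' @return A data.frame (`anchor`, `cluster`); cluster ids are integers
#'   numbered by first appearance in the input.  Empty input gives an
#'   empty data.frame.
#' @export
cluster_anchors <- function(anchors, eps = 2) {
  anchors <- unique(as.character(anchors))
  if (length(anchors) == 0)
    return(data.frame(anchor = character(0), cluster = integer(0)))
  d <- adist(anchors)
  adj <- d <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  # renumber by first appearance for determinism across igraph versions
  memb <- match(memb, unique(memb))
  data.frame(anchor = anchors, cluster = memb, stringsAsFactors = FALSE)
}

#' Pick per-direction representative anchors for each cluster
#'
#' Within each anchor cluster and for each direction, the representative is
#' the member with the largest effect size among members tested in that
#' direction; exact ties break lexicographically by anchor sequence.  A
#' direction with no tested member has no representative (`NA`).
#'
#' @param clusters Output of [cluster_anchors()].
#' @param results A `diversity_results` data.frame.
#' @return A data.frame with one row per cluster: `cluster`, `rep_up`,
#'   `alpha_up`, `sig_up`, `rep_down`, `alpha_down`, `sig_down`,
#'   `bidirectional` (some member significant in each direction),
#'   `n_members`.
#' @export
select_representatives <- function(clusters, results) {
  res <- as.data.frame(results)
  pick <- function(members, dir) {
    sub <- res[res$anchor %in% members & res$direction == dir, , drop = FALSE]
    if (nrow(sub) == 0)
      return(list(rep = NA_character_, alpha = NA_real_, sig = FALSE))
    sub <- sub[order(-sub$alpha, sub$anchor), , drop = FALSE]
    list(rep = sub$anchor[1], alpha = sub$alpha[1],
         sig = any(sub$significant))
  }
  ids <- unique(clusters$cluster)
  rows <- lapply(ids, function(id) {
    members <- clusters$anchor[clusters$cluster == id]
    u <- pick(members, "up")
    d <- pick(members, "down")
    data.frame(cluster = id, rep_up = u$rep, alpha_up = u$alpha,
               sig_up = u$sig, rep_down = d$rep, alpha_down = d$alpha,
               sig_down = d$sig, bidirectional = u$sig && d$sig,
               n_members = length(members), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Flag CRISPR-repeat candidate clusters
#'
#' A cluster is a direct-repeat candidate when it is significant in both
#' directions (spacer diversity flanks the repeat on both sides), the mean
#' representative effect size satisfies `0.5 * (alpha_up + alpha_down) >=
#' min_mean_alpha` (default 3.5), and a representative anchor occurred more
#' than once within a single read (tandem array structure).
#'
#' @param reps Output of [select_representatives()].
#' @param results A `diversity_results` data.frame (supplies
#'   `max_within_read` per anchor).
#' @param min_mean_alpha Effect-size threshold (default 3.5, inclusive).
#' @return `reps` with a logical `crispr_flag` column.
#' @export
crispr_filter <- function(reps, results, min_mean_alpha = 3.5) {
  res <- as.data.frame(results)
  mwr <- tapply(res$max_within_read, res$anchor, max)
  rep_mwr <- function(up, down) {
    v <- c(if (!is.na(up)) mwr[[up]], if (!is.na(down)) mwr[[down]])
    if (length(v) == 0) 0L else max(v)
  }
  mm <- mapply(rep_mwr, reps$rep_up, reps$rep_down)
  mean_alpha <- 0.5 * (reps$alpha_up + reps$alpha_down)
  reps$crispr_flag <- reps$bidirectional &
    !is.na(mean_alpha) & mean_alpha >= min_mean_alpha & mm >= 2
  reps
}

#' Read a tabular alignment file (BLAST outfmt 6)
#'
#' Standard 12-column tab-separated alignment output.  Rows with a
#' non-numeric e-value are skipped with a warning.
#'
#' @param path Path to the tabular file.
#' @return A data.frame with the standard column names (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
read_blast_table <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 12) stop("expected 12 tab-separated columns in ", path)
  x <- x[, 1:12]
  names(x) <- cols
  ev <- suppressWarnings(as.numeric(x$evalue))
  if (anyNA(ev)) {
    warning("skipping ", sum(is.na(ev)), " malformed alignment row(s)")
    x <- x[!is.na(ev), , drop = FALSE]
    ev <- ev[!is.na(ev)]
  }
  x$evalue <- ev
  x
}

#' Classify anchors by their best alignment e-value
#'
#' Each anchor is labelled from the minimum e-value over its alignment
#' rows: `annotated` when `e <= 0.01`, `questionable` when
#' `0.01 < e < 0.25`, `unannotated` otherwise (including no hits).  The
#' boundary `e = 0.01` is annotated; `e = 0.25` is unannotated.
#'
#' @param blast A data.frame from [read_blast_table()] (or with columns
#'   `qseqid`, `sseqid`, `evalue`).
#' @param anchors Character vector of anchors to classify; defaults to the
#'   query ids present in `blast`.
#' @return A data.frame: `anchor`, `best_evalue` (`NA` if no hits),
#'   `label`, `source_db` (subject of the best hit).
#' @export
classify_annotation <- function(blast, anchors = unique(blast$qseqid)) {
  rows <- lapply(anchors, function(a) {
    sub <- blast[blast$qseqid == a, , drop = FALSE]
    if (nrow(sub) == 0)
      return(data.frame(anchor = a, best_evalue = NA_real_,
                        label = "unannotated", source_db = NA_character_,
                        stringsAsFactors = FALSE))
    i <- which.min(sub$evalue)
    e <- sub$evalue[i]
    label <- if (e <= 0.01) "annotated"
             else if (e < 0.25) "questionable"
             else "unannotated"
    data.frame(anchor = a, best_evalue = e, label = label,
               source_db = as.character(sub$sseqid[i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binomial regression of target diversity on sample covariates
#'
#' Models per-sample cluster counts as `C ~ Binomial(N, p(x))` with a
#' logistic link `p(x) = 1 / (1 + exp(-beta' x))`, fitted by maximum
#' likelihood (`stats::glm`).  Character/factor covariates are one-hot
#' encoded by the model matrix; set `interactions = TRUE` for first-order
#' interactions.
#'
#' @param C Integer vector: clusters per sample.
#' @param N Integer vector: targets per sample (`C <= N`).
#' @param covariates data.frame of covariates (one row per sample), or
#'   `NULL` for an intercept-only fit.
#' @param interactions Include pairwise interactions (default `FALSE`).
#' @return A list of class `regression_fit`: `beta` (named, log-odds
#'   scale), `se`, `p_values` (Wald), `converged`, and the underlying
#'   `glm` object as `fit`.
#' @export
fit_binomial_regression <- function(C, N, covariates = NULL,
                                    interactions = FALSE) {
  stopifnot(length(C) == length(N), all(C >= 0), all(C <= N))
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    dat <- data.frame(row.names = seq_along(C))
    form <- cbind(C, N - C) ~ 1
  } else {
    dat <- as.data.frame(covariates)
    form <- if (interactions) cbind(C, N - C) ~ .^2 else cbind(C, N - C) ~ .
  }
  dat$C <- C
  dat$N <- N
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  # glm's own warning misses separation on aggregated binomial data; a
  # fitted log-odds beyond +-15 (p within 3e-7 of 0/1) means the MLE is
  # diverging along a separating direction
  if (max(abs(stats::predict(fit, type = "link"))) > 15) separated <- TRUE
  sm <- summary(fit)$coefficients
  converged <- fit$converged && !fit$boundary && !separated
  if (!converged)
    warning("binomial regression did not converge cleanly ",
            "(possible separation); coefficients reported anyway")
  structure(list(beta = sm[, "Estimate"], se = sm[, "Std. Error"],
                 p_values = sm[, "Pr(>|z|)"], converged = converged,
                 fit = fit),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat("binomial regression fit (converged:", x$converged, ")\n")
  print(data.frame(beta = x$beta, se = x$se, p = x$p_values))
  invisible(x)
}

#' Greedy across-sample clustering of target sequences
#'
#' Targets are ranked by total count across samples.  The highest-count
#' unassigned target seeds a cluster and recruits every unassigned target
#' with Jaccard similarity strictly above `js_threshold`; the procedure
#' repeats on the remainder until no targets are left.  Count ties break
#' lexicographically by sequence for determinism.
#'
#' @param targets Character vector of target k-mers (aggregated across
#'   samples).
#' @param counts Total count per target.
#' @param js_threshold Recruitment threshold (strict `>`; default 0.2).
#' @param sub_k Sub-k-mer length (default 7).
#' @return A data.frame (`target`, `count`, `cluster`, `seed`) where
#'   `cluster` numbers clusters in seed order and `seed` is the seeding
#'   sequence.
#' @export
greedy_cluster_targets <- function(targets, counts, js_threshold = 0.2,
                                   sub_k = 7) {
  stopifnot(length(targets) == length(counts))
  ord <- order(-counts, targets)
  targets <- targets[ord]
  counts <- counts[ord]
  n <- length(targets)
  cluster <- rep(NA_integer_, n)
  seed <- rep(NA_character_, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!is.na(cluster[i])) next
    cl <- cl + 1L
    open <- which(is.na(cluster))
    js <- vapply(open, function(j)
      cpp_jaccard(targets[i], targets[j], as.integer(sub_k)), numeric(1))
    take <- open[js > js_threshold | open == i]
    cluster[take] <- cl
    seed[take] <- targets[i]
  }
  data.frame(target = targets, count = counts, cluster = cluster,
             seed = seed, stringsAsFactors = FALSE)
}

#' Write assembly-seed FASTA of single-direction hits
#'
#' Mobile-element termini show hyper-variability in exactly one direction,
#' so clusters significant in a single direction are emitted (their
#' representative for that direction) as seeds for external seed-based
#' assembly.  Bidirectionally significant clusters (repeat-like) are
#' excluded.  Headers carry anchor, direction, effect size and q-value.
#'
#' @param reps Output of [select_representatives()] (optionally with the
#'   CRISPR flag).
#' @param results A `diversity_results` data.frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly; an empty result set writes a valid empty
#'   file.
#' @export
emit_seed_fasta <- function(reps, results, path) {
  res <- as.data.frame(results)
  seqs <- character(0)
  headers <- character(0)
  for (i in seq_len(nrow(reps))) {
    r <- reps[i, ]
    if (r$bidirectional) next
    dir <- if (r$sig_up) "up" else if (r$sig_down) "down" else next
    anchor <- if (dir == "up") r$rep_up else r$rep_down
    if (is.na(anchor)) next
    row <- res[res$anchor == anchor & res$direction == dir, , drop = FALSE]
    q <- if (nrow(row)) row$q_value[1] else NA
    a <- if (dir == "up") r$alpha_up else r$alpha_down
    seqs <- c(seqs, anchor)
    headers <- c(headers, sprintf("%s|direction=%s|alpha=%.4f|q=%.3g",
                                  anchor, dir, a, q))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
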