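#' Pipeline configuration
#'
#' Defaults follow the reference operating point for bacterial whole-genome
#' and metagenomic samples: 27-mers with no anchor-target gap, 25--75
#' targets per anchor/direction, a 2.5M-record cap per sample, Jaccard
#' clustering threshold 0.2 over 7-mer sets with 50% key replacement, a
#' p-value drop threshold of 0.1 and an FDR cutoff of 0.1.
#'
#' @param k Anchor/target k-mer length (default 27; max 31).
#' @param g Gap between anchor and target (default 0).
#' @param Nmin Minimum targets per anchor/direction to test (default 25).
#' @param Nmax Maximum targets collected per anchor/direction (default 75).
#' @param max_records Cap on FASTQ records per sample (default 2.5e6).
#' @param js_threshold Jaccard recruitment threshold, strict `>`
#'   (default 0.2).
#' @param sub_k Sub-k-mer length for the Jaccard similarity (default 7).
#' @param replace_prob Cluster-key replacement probability (default 0.5).
#' @param admission_alpha Admission-closing probability threshold
#'   (default 0.01).
#' @param retention_cutoff Retention-probability eviction cutoff
#'   (default 0.5).
#' @param sweep_every Records between retention sweeps once admission has
#'   closed (default 1e5).
#' @param p_drop BH drop threshold: p-values above it are never assigned a
#'   q-value (default 0.1).
#' @param q_cutoff FDR significance cutoff, strict `<` (default 0.1).
#' @param monotone_bh Apply step-up monotone enforcement in the BH
#'   correction (default `TRUE`).
#' @param dbscan_eps Edit-distance radius for anchor clustering
#'   (default 2).
#' @param crispr_alpha Mean effect-size threshold of the CRISPR-candidate
#'   filter (default 3.5).
#' @return A list of class `flankdiv_config`.
#' @export
flankdiv_config <- function(k = 27, g = 0, Nmin = 25, Nmax = 75,
                            max_records = 2.5e6, js_threshold = 0.2,
                            sub_k = 7, replace_prob = 0.5,
                            admission_alpha = 0.01, retention_cutoff = 0.5,
                            sweep_every = 1e5, p_drop = 0.1, q_cutoff = 0.1,
                            monotone_bh = TRUE, dbscan_eps = 2,
                            crispr_alpha = 3.5) {
  stopifnot(k >= 1, k <= 31, g >= 0, Nmin >= 1, Nmax >= Nmin,
            js_threshold > 0, js_threshold < 1, sub_k >= 1, sub_k < k,
            replace_prob >= 0, replace_prob <= 1)
  structure(list(k = k, g = g, Nmin = Nmin, Nmax = Nmax,
                 max_records = max_records, js_threshold = js_threshold,
                 sub_k = sub_k, replace_prob = replace_prob,
                 admission_alpha = admission_alpha,
                 retention_cutoff = retention_cutoff,
                 sweep_every = sweep_every, p_drop = p_drop,
                 q_cutoff = q_cutoff, monotone_bh = monotone_bh,
                 dbscan_eps = dbscan_eps, crispr_alpha = crispr_alpha),
            class = "flankdiv_config")
}

#' Run the full single-sample pipeline
#'
#' One streaming pass builds the anchor store; then the empirical null is
#' fitted, every anchor/direction with at least `Nmin` targets is tested,
#' q-values and effect sizes are attached, significant anchors are
#' deduplicated by edit-distance clustering, per-direction representatives
#' are picked, CRISPR-repeat candidates are flagged, and (optionally)
#' representative anchors are classified from a supplied alignment table.
#'
#' @param fastq Character vector of FASTQ paths (one sample; paired-end
#'   mates are simply two files, jointly capped at
#'   `config$max_records`).
#' @param config A [flankdiv_config()].
#' @param output_prefix If non-`NULL`, writes `<prefix>.results.tsv`,
#'   `<prefix>.clusters.tsv`, `<prefix>.seeds.fasta`, `<prefix>.log` and
#'   `<prefix>.config`.
#' @param seed Optional integer seed (`set.seed`) covering the whole run.
#' @param blast Optional path to a 12-column tabular alignment file used to
#'   classify representative anchors.
#' @param keep_clusters Keep per-anchor target-cluster keys/counts in the
#'   store (needed for across-sample target clustering; default `FALSE`).
#' @return A list of class `flankdiv_run`: `store`, `results`, `clusters`
#'   (anchor-cluster membership), `representatives` (with `crispr_flag`),
#'   `annotation` (or `NULL`), and `log` (record counts, admission close
#'   index, test ledger).
#' @export
flankdiv_run <- function(fastq, config = flankdiv_config(),
                         output_prefix = NULL, seed = NULL, blast = NULL,
                         keep_clusters = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  reads <- character(0)
  for (f in fastq) {
    remaining <- config$max_records - length(reads)
    if (remaining <= 0) break
    reads <- c(reads, stream_reads(f, max_records = remaining))
  }
  store <- build_anchor_store(reads, config, keep_trajectories = FALSE,
                              keep_clusters = keep_clusters)
  empty <- nrow(store$anchors) == 0 ||
    max(store$anchors$up_N, store$anchors$down_N) < config$Nmin
  if (empty) {
    message("no anchor reached Nmin = ", config$Nmin,
            " targets; results are empty")
    results <- structure(
      data.frame(anchor = character(0), direction = character(0),
                 N = integer(0), C_N = integer(0), p_value = numeric(0),
                 q_value = numeric(0), alpha = numeric(0),
                 max_within_read = integer(0), significant = logical(0)),
      m = 0L, n_retained = 0L, class = c("diversity_results", "data.frame"))
  } else {
    results <- test_diversity(store, config = config)
  }
  sig <- unique(results$anchor[results$significant])
  clusters <- cluster_anchors(sig, eps = config$dbscan_eps)
  if (nrow(clusters) > 0) {
    reps <- select_representatives(clusters, results)
    reps <- crispr_filter(reps, results, min_mean_alpha = config$crispr_alpha)
  } else {
    reps <- data.frame(cluster = integer(0), rep_up = character(0),
                       alpha_up = numeric(0), sig_up = logical(0),
                       rep_down = character(0), alpha_down = numeric(0),
                       sig_down = logical(0), bidirectional = logical(0),
                       n_members = integer(0), crispr_flag = logical(0))
  }
  annotation <- NULL
  if (!is.null(blast)) {
    tab <- read_blast_table(blast)
    rep_anchors <- unique(stats::na.omit(c(reps$rep_up, reps$rep_down)))
    annotation <- classify_annotation(tab, rep_anchors)
  }
  log <- list(n_reads = store$L, l_close = store$l_close,
              n_evicted = store$n_evicted, n_anchors = nrow(store$anchors),
              m = attr(results, "m"), n_retained = attr(results, "n_retained"),
              n_significant = sum(results$significant),
              n_clusters = length(unique(clusters$cluster)),
              n_crispr = sum(reps$crispr_flag))
  out <- structure(list(store = store, results = results,
                        clusters = clusters, representatives = reps,
                        annotation = annotation, log = log, config = config),
                   class = "flankdiv_run")
  if (!is.null(output_prefix)) write_run_outputs(out, output_prefix)
  out
}

#' @export
print.flankdiv_run <- function(x, ...) {
  l <- x$log
  cat("flankdiv run:", l$n_reads, "reads;", l$m, "tests;",
      l$n_retained, "retained (p <=", x$config$p_drop, ");",
      l$n_significant, "significant (q <", x$config$q_cutoff, ") in",
      l$n_clusters, "anchor clusters;", l$n_crispr,
      "CRISPR candidate cluster(s)\n")
  invisible(x)
}

write_run_outputs <- function(run, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(run$results, paste0(prefix, ".results.tsv"))
  cl <- run$clusters
  reps <- run$representatives
  members <- vapply(reps$cluster, function(id)
    paste(sort(cl$anchor[cl$cluster == id]), collapse = ","), "")
  ctab <- cbind(data.frame(cluster = reps$cluster, members = members),
                reps[, setdiff(names(reps), "cluster")])
  write.table(ctab, paste0(prefix, ".clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  emit_seed_fasta(reps, run$results, paste0(prefix, ".seeds.fasta"))
  l <- run$log
  writeLines(c(
    sprintf("reads_processed\t%d", l$n_reads),
    sprintf("admission_close_index\t%d", as.integer(l$l_close)),
    sprintf("anchors_evicted\t%d", as.integer(l$n_evicted)),
    sprintf("anchors_surviving\t%d", l$n_anchors),
    sprintf("tests_m\t%d", l$m),
    sprintf("retained_p_le_drop\t%d", l$n_retained),
    sprintf("significant_q_lt_cutoff\t%d", l$n_significant),
    sprintf("anchor_clusters\t%d", l$n_clusters),
    sprintf("crispr_candidates\t%d", l$n_crispr)),
    paste0(prefix, ".log"))
  cfg <- run$config
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE),
                            "")),
             paste0(prefix, ".config"))
  invisible(prefix)
}

#' Merge per-sample runs
#'
#' Concatenates per-sample results (adding a `sample` column) and, when the
#' runs were built with `keep_clusters = TRUE`, clusters the pooled target
#' sequences across samples with the greedy count-ranked procedure.
#' Per-anchor covariate regressions can then be fitted with
#' [fit_binomial_regression()] on the merged table.
#'
#' @param runs Named list of `flankdiv_run` objects.
#' @param js_threshold,sub_k Passed to [greedy_cluster_targets()].
#' @return A list: `results` (row-bound with `sample`), `target_clusters`
#'   (or `NULL` when no run kept its cluster keys).
#' @export
flankdiv_merge <- function(runs, js_threshold = 0.2, sub_k = 7) {
  if (is.null(names(runs))) names(runs) <- paste0("sample", seq_along(runs))
  res <- do.call(rbind, lapply(names(runs), function(nm) {
    r <- as.data.frame(runs[[nm]]$results)
    if (nrow(r) > 0) r$sample <- nm else r$sample <- character(0)
    r
  }))
  targets <- list()
  for (r in runs) {
    st <- r$store
    if (is.null(st$up_keys)) next
    for (fld in c("up", "down")) {
      keys <- unlist(st[[paste0(fld, "_keys")]], use.names = FALSE)
      cnts <- unlist(st[[paste0(fld, "_counts")]], use.names = FALSE)
      if (length(keys)) targets[[length(targets) + 1L]] <-
        data.frame(target = keys, count = cnts)
    }
  }
  target_clusters <- NULL
  if (length(targets)) {
    tab <- do.call(rbind, targets)
    agg <- tapply(tab$count, tab$target, sum)
    target_clusters <- greedy_cluster_targets(names(agg), as.integer(agg),
                                              js_threshold, sub_k)
  }
  list(results = res, target_clusters = target_clusters)
}
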