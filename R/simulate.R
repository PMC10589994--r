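#' Configuration for the planted-MGE read simulator
#'
#' Defines the generative model used as the desk-scale benchmark: one
#' random ancestral genome carrying copies of a random element, descendant
#' genomes diverged by a per-base mutation+indel rate (MIR), and fixed
#' length single-end reads sampled uniformly from both strands with
#' uniform substitution errors.  Mutation events are 9:1
#' substitutions:indels; indel lengths are geometric with mean 2.
#'
#' @param genome_len Genome length in bp (default 1e5).
#' @param element_len Element length in bp (default 1500).
#' @param copy_number Copies of the element in the ancestor (ancestral
#'   scenario; default 5).
#' @param activity New insertions per descendant genome (active scenario;
#'   default 20).
#' @param n_genomes Number of descendant genomes (default 10).
#' @param mir Per-base mutation+indel rate applied between genomes
#'   (default 0.001).
#' @param indel_frac Fraction of mutation events that are indels
#'   (default 0.1, i.e. indel:substitution 1:9).
#' @param indel_geom_p Geometric parameter for indel lengths
#'   (`rgeom(p) + 1`, default 0.5: mean length 2).
#' @param coverage Per-genome sequencing depth in X (default 30).
#' @param read_len Read length in bp (default 150).
#' @param error_rate Per-base sequencing substitution error rate
#'   (default 0.001).
#' @param k Anchor k-mer length used to define truth terminus k-mers
#'   (default 27).
#' @param seed Optional integer seed applied at the start of a simulation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 1e5, element_len = 1500,
                       copy_number = 5, activity = 20, n_genomes = 10,
                       mir = 0.001, indel_frac = 0.1, indel_geom_p = 0.5,
                       coverage = 30, read_len = 150, error_rate = 0.001,
                       k = 27, seed = NULL) {
  stopifnot(element_len < genome_len, coverage > 0,
            mir >= 0, mir < 1, error_rate >= 0, error_rate < 1)
  structure(list(genome_len = genome_len, element_len = element_len,
                 copy_number = copy_number, activity = activity,
                 n_genomes = n_genomes, mir = mir, indel_frac = indel_frac,
                 indel_geom_p = indel_geom_p, coverage = coverage,
                 read_len = read_len, error_rate = error_rate, k = k,
                 seed = seed),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Apply MIR mutations (substitutions + indels) and return the mutated
# sequence plus a map from 0-based boundary coordinates in the input to
# coordinates in the output (boundaries inside a deletion collapse to its
# left edge).
mutate_sequence <- function(seq, mir, indel_frac = 0.1, indel_geom_p = 0.5) {
  n <- nchar(seq)
  n_mut <- rbinom(1, n, mir)
  if (n_mut == 0)
    return(list(seq = seq, map = identity))
  pos <- sort(sample.int(n, n_mut))
  is_indel <- runif(n_mut) < indel_frac
  is_ins <- is_indel & runif(n_mut) < 0.5
  lens <- rgeom(n_mut, indel_geom_p) + 1L
  bases <- c("A", "C", "G", "T")
  pieces <- character(0)
  events <- list()  # (pos, delta, del_len) for the coordinate map
  cur <- 1L
  for (i in seq_len(n_mut)) {
    p <- pos[i]
    if (p < cur) next  # swallowed by a previous deletion
    pieces <- c(pieces, substr(seq, cur, p - 1L))
    if (!is_indel[i]) {
      old <- substr(seq, p, p)
      pieces <- c(pieces, sample(setdiff(bases, old), 1))
      cur <- p + 1L
    } else if (is_ins[i]) {
      pieces <- c(pieces, random_dna(lens[i]))
      events[[length(events) + 1L]] <- c(p, lens[i], 0L)
      cur <- p
    } else {
      del <- min(lens[i], n - p + 1L)
      events[[length(events) + 1L]] <- c(p, -del, del)
      cur <- p + del
    }
  }
  pieces <- c(pieces, substr(seq, cur, n))
  new_seq <- paste(pieces, collapse = "")
  map <- function(coords) {
    vapply(coords, function(c0) {
      shift <- 0L
      for (ev in events) {
        p0 <- ev[1] - 1L  # 0-based boundary of the event site
        if (ev[2] > 0) {            # insertion before base ev[1]
          if (c0 >= p0) shift <- shift + ev[2]
        } else {                    # deletion of ev[3] bases from ev[1]
          if (c0 >= p0 + ev[3]) shift <- shift - ev[3]
          else if (c0 > p0) { c0 <- p0 }  # inside the deletion
        }
      }
      c0 + shift
    }, numeric(1))
  }
  list(seq = new_seq, map = map)
}

# Sample insertion points (0-based boundaries) in [k, len - k] with
# pairwise separation >= min_sep and distance >= min_sep from `avoid`.
sample_insertion_points <- function(len, n_points, min_sep, avoid = numeric(0),
                                    tries = 1000) {
  if (n_points == 0) return(numeric(0))
  lo <- min_sep
  hi <- len - min_sep
  if (hi <= lo) stop("element copies cannot be placed without overlap")
  for (t in seq_len(tries)) {
    p <- sort(sample(seq(lo, hi), n_points))
    ok <- (n_points < 2 || min(diff(p)) >= min_sep) &&
      (length(avoid) == 0 || min(abs(outer(p, avoid, "-"))) >= min_sep)
    if (ok) return(p)
  }
  stop("element copies cannot be placed without overlap")
}

# Insert the element at each 0-based boundary point (sorted ascending).
# Returns the new sequence, the final [start, end) junctions of the new
# copies, and a map for coordinates that existed before insertion.
insert_elements <- function(seq, element, points) {
  points <- sort(points)
  elen <- nchar(element)
  if (length(points) == 0)
    return(list(seq = seq, junctions = cbind(start = numeric(0),
                                             end = numeric(0)),
                map = identity))
  pieces <- character(0)
  cur <- 0L
  for (p in points) {
    pieces <- c(pieces, substr(seq, cur + 1L, p), element)
    cur <- p
  }
  pieces <- c(pieces, substr(seq, cur + 1L, nchar(seq)))
  starts <- points + elen * (seq_along(points) - 1L)
  map <- function(coords) {
    vapply(coords, function(c0) c0 + elen * sum(points <= c0), numeric(1))
  }
  list(seq = paste(pieces, collapse = ""),
       junctions = cbind(start = starts, end = starts + elen), map = map)
}

# Terminus truth k-mers of one genome: the k-mer occupying the terminal k
# bases at each junction-adjacent element end, plus reverse complements
# (the simulator samples both strands and the detector does not
# canonicalise).
terminus_kmers <- function(genome, junctions, k, proximal = FALSE) {
  if (nrow(junctions) == 0) return(character(0))
  grab <- function(from0, to0) {  # 0-based half-open window
    n <- nchar(genome)
    if (from0 < 0 || to0 > n) return(NA_character_)
    substr(genome, from0 + 1, to0)
  }
  out <- character(0)
  for (i in seq_len(nrow(junctions))) {
    s <- junctions[i, "start"]; e <- junctions[i, "end"]
    if (!proximal) {
      out <- c(out, grab(s, s + k), grab(e - k, e))
    } else {
      for (p in seq(s - k, s + k)) out <- c(out, grab(p, p + k))
      for (p in seq(e - 2 * k, e)) out <- c(out, grab(p, p + k))
    }
  }
  out <- out[!is.na(out) & nchar(out) == k & !grepl("[^ACGT]", out)]
  unique(c(out, revcomp(out)))
}

# Uniformly sampled single-end reads from both strands with substitution
# errors; returns a named character vector.
sample_reads <- function(genome, coverage, read_len, error_rate, prefix) {
  glen <- nchar(genome)
  if (glen < read_len) stop("genome shorter than the read length")
  n <- round(coverage * glen / read_len)
  starts <- sample.int(glen - read_len + 1L, n, replace = TRUE)
  seqs <- substring(genome, starts, starts + read_len - 1L)
  minus <- runif(n) < 0.5
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  nerr <- rbinom(n, read_len, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0)) {
    for (p in sample.int(read_len, nerr[i])) {
      old <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(bases, old), 1)
    }
  }
  names(seqs) <- sprintf("%s_r%06d_%d_%s", prefix, seq_len(n), starts,
                         ifelse(minus, "-", "+"))
  seqs
}

#' Write reads as a FASTQ file
#'
#' Constant quality `I` (Phred 40); `.gz` paths are written gzip-compressed.
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path (gzip when it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  lines <- character(4L * n)
  if (n > 0) {
    idx <- 4L * (seq_len(n) - 1L)
    lines[idx + 1L] <- paste0("@", names(reads))
    lines[idx + 2L] <- unname(reads)
    lines[idx + 3L] <- "+"
    lines[idx + 4L] <- strrep("I", nchar(reads))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

sim_finish <- function(cfg, out_dir, genomes, junctions_list, element) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- character(length(genomes))
  jrows <- list()
  kmers <- character(0)
  proximal <- character(0)
  for (i in seq_along(genomes)) {
    reads <- sample_reads(genomes[[i]], cfg$coverage, cfg$read_len,
                          cfg$error_rate, sprintf("g%d", i))
    fastq[i] <- file.path(out_dir, sprintf("genome%d.fastq", i))
    write_fastq(reads, fastq[i])
    j <- junctions_list[[i]]
    if (nrow(j) > 0)
      jrows[[i]] <- data.frame(genome = i, start = j[, "start"],
                               end = j[, "end"],
                               copy = seq_len(nrow(j)))
    kmers <- c(kmers, terminus_kmers(genomes[[i]], j, cfg$k))
    proximal <- c(proximal, terminus_kmers(genomes[[i]], j, cfg$k,
                                           proximal = TRUE))
  }
  junctions <- if (length(jrows)) do.call(rbind, jrows)
               else data.frame(genome = integer(0), start = numeric(0),
                               end = numeric(0), copy = integer(0))
  truth <- structure(list(junctions = junctions, kmers = unique(kmers),
                          proximal_kmers = unique(proximal), k = cfg$k),
                     class = "sim_truth")
  list(fastq = fastq, truth = truth, genomes = genomes,
       element = element)
}

#' Simulate an ancestral multi-copy element
#'
#' One ancestral genome receives `copy_number` element copies at random
#' well-separated loci; each descendant genome is the ancestor diverged at
#' the configured MIR (so all genomes share the same insertion loci, up to
#' coordinate shifts from indels).  Reads are sampled per genome.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Directory receiving one FASTQ per genome.
#' @return A list: `fastq` (paths), `truth` (a `sim_truth`: `junctions`
#'   data.frame with 0-based half-open coordinates, terminus `kmers`,
#'   `proximal_kmers`), `genomes` (sequences).
#' @export
simulate_ancestral <- function(cfg, out_dir = tempfile("sim_anc")) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  base <- random_dna(cfg$genome_len)
  element <- random_dna(cfg$element_len)
  pts <- sample_insertion_points(cfg$genome_len, cfg$copy_number,
                                 min_sep = 2 * cfg$k)
  anc <- insert_elements(base, element, pts)
  genomes <- vector("list", cfg$n_genomes)
  junctions <- vector("list", cfg$n_genomes)
  for (i in seq_len(cfg$n_genomes)) {
    mu <- mutate_sequence(anc$seq, cfg$mir, cfg$indel_frac, cfg$indel_geom_p)
    genomes[[i]] <- mu$seq
    junctions[[i]] <- cbind(start = mu$map(anc$junctions[, "start"]),
                            end = mu$map(anc$junctions[, "end"]))
  }
  sim_finish(cfg, out_dir, genomes, junctions, element)
}

#' Simulate an active element (recent independent insertions)
#'
#' The ancestor carries a single element copy.  Each descendant genome is
#' the ancestor diverged at the configured MIR, plus `activity` additional
#' element copies at loci drawn independently per genome -- the signature
#' of an element that has been mobilising within the sample.
#'
#' @inheritParams simulate_ancestral
#' @return Same structure as [simulate_ancestral()].
#' @export
simulate_active <- function(cfg, out_dir = tempfile("sim_act")) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  base <- random_dna(cfg$genome_len)
  element <- random_dna(cfg$element_len)
  pt <- sample_insertion_points(cfg$genome_len, 1, min_sep = 2 * cfg$k)
  anc <- insert_elements(base, element, pt)
  genomes <- vector("list", cfg$n_genomes)
  junctions <- vector("list", cfg$n_genomes)
  for (i in seq_len(cfg$n_genomes)) {
    mu <- mutate_sequence(anc$seq, cfg$mir, cfg$indel_frac, cfg$indel_geom_p)
    anc_j <- cbind(start = mu$map(anc$junctions[, "start"]),
                   end = mu$map(anc$junctions[, "end"]))
    avoid <- as.numeric(anc_j)
    pts <- sample_insertion_points(nchar(mu$seq), cfg$activity,
                                   min_sep = 2 * cfg$k, avoid = avoid)
    ins <- insert_elements(mu$seq, element, pts)
    genomes[[i]] <- ins$seq
    junctions[[i]] <- rbind(cbind(start = ins$map(anc_j[, "start"]),
                                  end = ins$map(anc_j[, "end"])),
                            ins$junctions)
  }
  sim_finish(cfg, out_dir, genomes, junctions, element)
}

#' Rank-based ROC AUC for recovering planted terminus anchors
#'
#' Anchors tested by the pipeline are labelled positive when their sequence
#' is in the truth terminus k-mer set (exact match; set
#' `positive = "proximal"` for the looser window-overlap labelling) and
#' scored either by significance (`-log10 q`, with dropped q-values scored
#' as `q = 1`, the minimum over the two directions) or by effect size
#' (maximum `alpha` over directions).  The AUC is the Mann-Whitney
#' statistic with mid-ranks for ties.
#'
#' @param results A `diversity_results` data.frame.
#' @param truth A `sim_truth` (or a character vector of truth k-mers).
#' @param score `"qvalue"` (default) or `"alpha"`.
#' @param positive `"terminal"` (default) or `"proximal"`.
#' @return A list: `auc`, `n_pos`, `n_neg`, and the per-anchor `table`
#'   (anchor, score, label).
#' @export
evaluate_auc <- function(results, truth, score = c("qvalue", "alpha"),
                         positive = c("terminal", "proximal")) {
  score <- match.arg(score)
  positive <- match.arg(positive)
  kmers <- if (inherits(truth, "sim_truth")) {
    if (positive == "terminal") truth$kmers else truth$proximal_kmers
  } else as.character(truth)
  res <- as.data.frame(results)
  if (nrow(res) == 0) stop("no tested anchors to evaluate")
  if (score == "qvalue") {
    q <- ifelse(is.na(res$q_value), 1, res$q_value)
    s <- -log10(pmax(q, 1e-300))
  } else {
    s <- res$alpha
  }
  agg <- tapply(s, res$anchor, max)
  anchors <- names(agg)
  scores <- as.numeric(agg)
  label <- anchors %in% kmers
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: need at least one positive and one negative anchor")
  r <- rank(scores)
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  list(auc = auc, n_pos = n_pos, n_neg = n_neg,
       table = data.frame(anchor = anchors, score = scores, label = label,
                          stringsAsFactors = FALSE))
}
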