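test_that("anchor clustering is transitive single-linkage within eps", {
  a <- strrep("A", 27)
  expect_equal(nrow(cluster_anchors(c(a, a))), 1)
  withr::with_seed(30, {
    b3 <- mutate_kmer(a, 3)
    cl <- cluster_anchors(c(a, b3))
    expect_equal(length(unique(cl$cluster)), 2)  # distance 3 > eps = 2
    # chain a-b at 2, b-c at 2, a-c at 4: one cluster by chaining
    x <- rand_dna(27)
    y <- mutate_kmer(x, 2)
    z <- y
    repeat {
      z <- mutate_kmer(y, 2)
      if (lev_oracle(x, z) == 4) break
    }
    cl <- cluster_anchors(c(x, y, z))
    expect_equal(length(unique(cl$cluster)), 1)
  })
})

test_that("anchor clustering equals BFS connected components on random anchors", {
  withr::with_seed(31, {
    seeds <- replicate(8, rand_dna(27))
    anchors <- unique(unlist(lapply(seeds, function(s)
      c(s, replicate(4, mutate_kmer(s, sample(1:3, 1)))))))
  })
  cl <- cluster_anchors(anchors, eps = 2)
  oracle <- components_oracle(cl$anchor, eps = 2)
  # same partition up to labels
  expect_equal(length(unique(cl$cluster)), length(unique(oracle)))
  expect_true(all(tapply(oracle, cl$cluster, function(v) length(unique(v))) == 1))
})

test_that("representatives maximise effect size per direction with lexicographic ties", {
  res <- structure(data.frame(
    anchor = c("AAA", "AAC", "AAA", "AAC", "AAG"),
    direction = c("down", "down", "up", "up", "down"),
    N = 30, C_N = 20,
    p_value = 1e-4, q_value = 1e-3,
    alpha = c(1.0, 2.5, 3.0, 3.0, 2.5),
    max_within_read = 1, significant = TRUE),
    class = c("diversity_results", "data.frame"))
  cl <- data.frame(anchor = c("AAA", "AAC", "AAG"), cluster = 1L)
  reps <- select_representatives(cl, res)
  expect_equal(reps$rep_down, "AAC")  # 2.5 tie with AAG: lexicographic
  expect_equal(reps$rep_up, "AAA")    # 3.0 tie with AAC: lexicographic
  expect_true(reps$bidirectional)
  # singleton cluster: itself in every tested direction
  cl1 <- data.frame(anchor = "AAA", cluster = 1L)
  r1 <- select_representatives(cl1, res)
  expect_equal(r1$rep_up, "AAA")
  expect_equal(r1$rep_down, "AAA")
  # direction never tested: representative absent
  res_up <- res[res$direction == "up", ]
  class(res_up) <- class(res)
  r2 <- select_representatives(cl1, res_up)
  expect_true(is.na(r2$rep_down))
})

test_that("CRISPR candidate filter applies all three criteria with >= boundary", {
  base <- data.frame(cluster = 1L, rep_up = "AAA", alpha_up = 4.0,
                     sig_up = TRUE, rep_down = "AAA", alpha_down = 3.0,
                     sig_down = TRUE, bidirectional = TRUE, n_members = 1L)
  res <- structure(data.frame(
    anchor = "AAA", direction = c("up", "down"), N = 75, C_N = 70,
    p_value = 1e-10, q_value = 1e-8, alpha = c(4.0, 3.0),
    max_within_read = 2, significant = TRUE),
    class = c("diversity_results", "data.frame"))
  # mean alpha exactly 3.5 passes (inclusive boundary), multiplicity 2 passes
  expect_true(crispr_filter(base, res)$crispr_flag)
  # significant in one direction only
  uni <- base; uni$bidirectional <- FALSE; uni$sig_down <- FALSE
  expect_false(crispr_filter(uni, res)$crispr_flag)
  # mean alpha below the threshold
  weak <- base; weak$alpha_up <- 3.3; weak$alpha_down <- 3.3
  expect_false(crispr_filter(weak, res)$crispr_flag)
  # never observed twice within a read
  res1 <- res; res1$max_within_read <- 1
  expect_false(crispr_filter(base, res1)$crispr_flag)
})

test_that("annotation labels partition anchors by best e-value with fixed boundaries", {
  blast <- data.frame(qseqid = c("a", "a", "b", "c", "d"),
                      sseqid = paste0("db", 1:5),
                      evalue = c(1e-5, 0.5, 0.05, 0.01, 0.25))
  ann <- classify_annotation(blast, anchors = c("a", "b", "c", "d", "e"))
  expect_equal(ann$label,
               c("annotated", "questionable", "annotated", "unannotated",
                 "unannotated"))
  expect_equal(ann$best_evalue[1], 1e-5)
  expect_true(is.na(ann$best_evalue[5]))
})

test_that("tabular alignment input tolerates malformed rows with a warning", {
  path <- tempfile(fileext = ".tsv")
  rows <- c(paste(c("a", "s1", 100, 27, 0, 0, 1, 27, 5, 31, "1e-8", 50),
                  collapse = "\t"),
            paste(c("b", "s2", 100, 27, 0, 0, 1, 27, 5, 31, "not_a_number", 50),
                  collapse = "\t"))
  writeLines(rows, path)
  expect_warning(tab <- read_blast_table(path), "malformed")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$qseqid, "a")
})

test_that("binomial regression recovers closed forms and planted coefficients", {
  # intercept-only MLE is logit of the pooled rate
  C <- c(10, 20, 15); N <- c(50, 50, 50)
  fit <- fit_binomial_regression(C, N)
  expect_equal(unname(fit$beta[1]), qlogis(sum(C) / sum(N)), tolerance = 1e-6)
  # C = N/2 everywhere gives a zero intercept
  fit0 <- fit_binomial_regression(rep(25, 4), rep(50, 4))
  expect_equal(unname(fit0$beta[1]), 0, tolerance = 1e-8)
  # parameter recovery within 3 standard errors
  withr::with_seed(32, {
    n <- 200; Nn <- rep(50, n)
    x <- rnorm(n)
    beta <- c(-1, 0.8)
    p <- plogis(beta[1] + beta[2] * x)
    Cc <- rbinom(n, Nn, p)
  })
  fit2 <- fit_binomial_regression(Cc, Nn, data.frame(x = x))
  expect_true(fit2$converged)
  expect_true(all(abs(fit2$beta - beta) <= 3 * fit2$se))
})

test_that("perfect separation is flagged as non-converged with a warning", {
  x <- c(rep(0, 5), rep(1, 5))
  C <- c(rep(0, 5), rep(20, 5))
  N <- rep(20, 10)
  expect_warning(fit <- fit_binomial_regression(C, N, data.frame(x = x)),
                 "converge")
  expect_false(fit$converged)
})

test_that("greedy target clustering follows the count-ranked recruitment rule", {
  t1 <- strrep("A", 27)
  expect_equal(length(unique(
    greedy_cluster_targets(c(t1, t1), c(3, 2))$cluster)), 1)
  t2 <- strrep("C", 27)
  g <- greedy_cluster_targets(c(t1, t2), c(1, 5))
  expect_equal(g$target[1], t2)  # higher count seeds first
  expect_equal(g$cluster, c(1L, 2L))
  withr::with_seed(33, {
    seeds <- replicate(3, rand_dna(27))
    targets <- unique(unlist(lapply(seeds, function(s)
      c(s, replicate(2, mutate_kmer(s, sample(1:2, 1)))))))
    counts <- sample(1:50, length(targets))
  })
  got <- greedy_cluster_targets(targets, counts)
  oracle <- greedy_oracle(targets, counts)
  expect_equal(got$target, oracle$target)
  expect_equal(got$cluster, oracle$cluster)
})

test_that("seed FASTA contains exactly the single-direction significant representatives", {
  reps <- data.frame(cluster = 1:3,
                     rep_up = c("AAAA", "CCCC", "GGGG"),
                     alpha_up = c(2, 3, 1), sig_up = c(TRUE, TRUE, FALSE),
                     rep_down = c("AAAT", "CCCG", "GGGT"),
                     alpha_down = c(1, 2, 3), sig_down = c(FALSE, TRUE, TRUE),
                     bidirectional = c(FALSE, TRUE, FALSE),
                     n_members = 1L)
  res <- structure(data.frame(
    anchor = c("AAAA", "GGGT"), direction = c("up", "down"),
    N = 30, C_N = 25, p_value = 1e-5, q_value = 1e-4,
    alpha = c(2, 3), max_within_read = 1, significant = TRUE),
    class = c("diversity_results", "data.frame"))
  path <- tempfile(fileext = ".fasta")
  emit_seed_fasta(reps, res, path)
  out <- Biostrings::readDNAStringSet(path)
  expect_equal(length(out), 2)  # cluster 2 (bidirectional) excluded
  expect_equal(unname(as.character(out)), c("AAAA", "GGGT"))
  expect_true(grepl("direction=up", names(out)[1]))
  # empty input still writes a valid (empty) FASTA
  empty <- reps[0, ]
  path2 <- tempfile(fileext = ".fasta")
  emit_seed_fasta(empty, res, path2)
  expect_equal(length(Biostrings::readDNAStringSet(path2)), 0)
})
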