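test_that("jaccard similarity matches identity, disjointness, and a set-enumeration oracle", {
  expect_equal(jaccard_similarity(strrep("A", 27), strrep("A", 27)), 1.0)
  expect_equal(jaccard_similarity(strrep("A", 27), strrep("C", 27)), 0.0)
  withr::with_seed(10, {
    for (i in 1:25) {
      # two 27-mers sharing one 20-base block, otherwise random
      block <- rand_dna(20)
      t1 <- paste0(block, rand_dna(7))
      t2 <- paste0(rand_dna(7), block)
      expect_equal(jaccard_similarity(t1, t2), js_oracle(t1, t2))
      # and fully random pairs
      r1 <- rand_dna(27); r2 <- rand_dna(27)
      expect_equal(jaccard_similarity(r1, r2), js_oracle(r1, r2))
    }
  })
  expect_error(jaccard_similarity("ACGTACG", "ACGTACG", sub_k = 8), "sub_k")
})

test_that("dictionary updates recruit, replace, and open clusters per the rules", {
  # empty dictionary: first target always opens a cluster
  d <- target_dictionary()
  d <- update_target_dictionary(d, strrep("A", 27))
  expect_equal(d$keys, strrep("A", 27))
  expect_equal(d$counts, 1L)
  expect_equal(d$trajectory, 1L)

  # identical target recruits; the key is replaced iff the draw says so
  d1 <- update_target_dictionary(d, strrep("A", 27), replace_prob = 1)
  expect_equal(d1$counts, 2L)
  expect_equal(d1$trajectory, c(1L, 0L))

  withr::with_seed(17, {
    key <- rand_dna(27)
    near <- mutate_kmer(key, 1)  # JS(key, near) = 14/28 = 0.5 > 0.2
  })
  dk <- target_dictionary()
  dk <- update_target_dictionary(dk, key)
  d0 <- update_target_dictionary(dk, near, replace_prob = 0)
  expect_equal(d0$keys, key)   # recruited, key kept
  expect_equal(d0$counts, 2L)
  # with replace_prob = 1 a recruited target always takes over the key
  dr <- update_target_dictionary(dk, near, replace_prob = 1)
  expect_equal(dr$keys, near)
  expect_equal(dr$counts, 2L)
})

test_that("a similarity of exactly the threshold opens a new cluster (strict >)", {
  # find target pairs whose set Jaccard is exactly 0.2 and check routing
  found <- 0
  withr::with_seed(11, {
    for (i in 1:3000) {
      block <- rand_dna(13)  # 13-base shared block -> 7 shared 7-mers
      t1 <- paste0(block, rand_dna(14))
      t2 <- paste0(rand_dna(14), block)
      if (js_oracle(t1, t2) == 0.2) {
        found <- found + 1
        d <- target_dictionary()
        d <- update_target_dictionary(d, t1)
        d <- update_target_dictionary(d, t2)
        expect_equal(length(d$keys), 2L)
        expect_equal(d$trajectory, c(1L, 1L))
        if (found >= 3) break
      }
    }
  })
  expect_gte(found, 1)
})

test_that("recruitment scans clusters in insertion order and takes the first match", {
  withr::with_seed(12, t <- rand_dna(27))
  d <- target_dictionary()
  d <- update_target_dictionary(d, t, replace_prob = 0)
  d <- update_target_dictionary(d, strrep("G", 27), replace_prob = 0)
  # a target similar to both existing keys must credit the first
  d2 <- update_target_dictionary(d, t, replace_prob = 0)
  expect_equal(d2$counts, c(2L, 1L))
})

test_that("closed dictionaries signal a no-op", {
  d <- target_dictionary()
  d <- update_target_dictionary(d, strrep("A", 27))
  d2 <- update_target_dictionary(d, strrep("C", 27), Nmax = 1)
  expect_true(isTRUE(attr(d2, "noop")))
  expect_equal(d2$counts, d$counts)
})

test_that("admission probability and closing rule match a log-domain oracle", {
  expect_equal(admission_zero_prob(0, 0.3), 1.0)
  expect_equal(admission_zero_prob(1, 1), 0.0)
  # smallest l with (1 - 1e-5)^l < 0.01, solved independently in log space
  p_min <- 25 / 2.5e6
  l_star <- ceiling(log(0.01) / log(1 - p_min))
  if ((1 - p_min)^(l_star - 1) < 0.01) l_star <- l_star - 1
  expect_lt(admission_zero_prob(l_star, p_min), 0.01)
  expect_gte(admission_zero_prob(l_star - 1, p_min), 0.01)
  expect_false(close_admission(l_star - 1, L = 2.5e6, Nmin = 25))
  expect_true(close_admission(l_star, L = 2.5e6, Nmin = 25))
  expect_false(close_admission(0, L = 100, Nmin = 25))
  expect_true(close_admission(1e6, L = 1e6, Nmin = 25))
})

test_that("retention probability approximates the exact binomial within 0.05", {
  expect_equal(retention_probability(10, 10, 100, Nmin = 25), 1.0)
  expect_equal(retention_probability(0, 10, 100, Nmin = 25), 0.0)
  expect_error(retention_probability(0, 0, 100), "l must be positive")
  exact <- pbinom(24, 2.5e6, 1e-5, lower.tail = FALSE)
  approx <- retention_probability(10, 1e6, 2.5e6, Nmin = 25)
  expect_lt(abs(approx - exact), 0.05)
  # a few more exact-vs-approximation spot checks
  withr::with_seed(13, {
    for (i in 1:10) {
      l <- sample(1e4:1e6, 1); L <- l + sample(1e4:1e6, 1)
      x <- sample(1:60, 1)
      exact <- pbinom(24, L, x / l, lower.tail = FALSE)
      expect_lt(abs(retention_probability(x, l, L, 25) - exact), 0.05)
    }
  })
  # an anchor that already reached Nmin can never score below the cutoff
  for (x in c(25, 30, 60)) {
    expect_gte(retention_probability(x, 1e5, 1e5, Nmin = 25), 0.5)
  }
})

test_that("the store honours admission, Nmax, multiplicity and count invariants", {
  withr::with_seed(14, {
    # 120 reads; a repeated junction-like context drives one anchor's N
    anchor <- rand_dna(27)
    reads <- vapply(1:120, function(i)
      paste0(rand_dna(27), anchor, rand_dna(27)), "")
    # one read carries the anchor twice
    reads[5] <- paste0(anchor, rand_dna(10), anchor, rand_dna(27))
    # a late-arriving anchor, first seen only after admission closes
    late <- rand_dna(27)
    reads[110] <- paste0(rand_dna(27), late, rand_dna(27))
  })
  cfg <- flankdiv_config(Nmin = 25, Nmax = 30, sweep_every = 0)
  set.seed(99)
  st <- build_anchor_store(reads, cfg, keep_trajectories = TRUE,
                           keep_clusters = TRUE)
  a <- st$anchors
  i <- which(a$anchor == anchor)
  expect_length(i, 1)
  # within-read multiplicity recorded
  expect_gte(a$max_within_read[i], 2)
  # N capped at Nmax even though the anchor occurs ~120 times
  expect_equal(a$up_N[i], 30)
  expect_equal(a$down_N[i], 30)
  # late anchor absent: admission closed before read 110
  expect_true(close_admission(109, L = 120, Nmin = 25))
  expect_false(late %in% a$anchor)
  # per-direction invariants: sum of cluster counts = N, C = clusters formed
  for (j in seq_len(nrow(a))) {
    expect_equal(sum(st$up_counts[[j]]), a$up_N[j])
    expect_equal(length(st$up_keys[[j]]), a$up_C[j])
    expect_equal(sum(st$up_traj[[j]]), a$up_C[j])
    expect_lte(a$up_C[j], a$up_N[j])
    expect_lte(a$up_N[j], 30)
    if (a$up_N[j] > 0) expect_equal(st$up_traj[[j]][1], 1L)
  }
})

test_that("replaying the same reads with the same seed reproduces the store", {
  withr::with_seed(15, {
    core <- rand_dna(27)
    reads <- vapply(1:60, function(i) paste0(rand_dna(27), core, rand_dna(27)), "")
  })
  cfg <- flankdiv_config(Nmin = 10, Nmax = 20)
  set.seed(7); st1 <- build_anchor_store(reads, cfg, keep_clusters = TRUE)
  set.seed(7); st2 <- build_anchor_store(reads, cfg, keep_clusters = TRUE)
  expect_identical(st1, st2)
})

test_that("with replace_prob = 0 cluster keys are the first-observed targets", {
  withr::with_seed(16, first <- rand_dna(27))
  near <- mutate_kmer(first, 1)  # 1 substitution: JS well above 0.2
  d <- target_dictionary()
  d <- update_target_dictionary(d, first, replace_prob = 0)
  d <- update_target_dictionary(d, near, replace_prob = 0)
  expect_equal(d$keys, first)
  expect_equal(d$counts, 2L)
})
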