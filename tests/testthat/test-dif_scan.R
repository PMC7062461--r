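g <- dif_grammar()

test_that("build_pwm reproduces a hand-computed two-motif matrix", {
  m1 <- g$canonical
  m2 <- gokuphage:::mutate_k(withr::with_seed(90, m1), 0)  # identical copy
  withr::with_seed(91, m2 <- gokuphage:::mutate_k(m1, 6))
  pwm <- build_pwm(c(m1, m2), g, pseudocount = 0.5)
  # with 2 motifs and pseudocount 0.5: count 2 -> (2 + 0.5)/(2 + 2) = 0.625,
  # count 1 -> 0.375, count 0 -> 0.125; log2 odds vs uniform background
  lo2 <- log2(0.625 / 0.25); lo1 <- log2(0.375 / 0.25); lo0 <- log2(0.125 / 0.25)
  c1 <- strsplit(m1, "")[[1]]; c2 <- strsplit(m2, "")[[1]]
  for (j in seq_len(28)) {
    for (b in c("A", "C", "G", "T")) {
      n_b <- sum(c(c1[j], c2[j]) == b)
      expected <- c(lo0, lo1, lo2)[n_b + 1L]
      expect_equal(unname(pwm$mat[b, j]), expected, tolerance = 1e-12)
    }
  }
  expect_true(all(abs(colSums(pwm$prob) - 1) < 1e-12))
})

test_that("a single-motif PWM is uniquely maximised by its training sequence", {
  pwm <- build_pwm(g$canonical, g, pseudocount = 0.5)
  top <- pwm_score(pwm, g$canonical)
  # every single-substitution neighbour scores strictly lower
  for (j in seq_len(28)) {
    for (b in setdiff(c("A", "C", "G", "T"),
                      substr(g$canonical, j, j))) {
      mut <- g$canonical
      substr(mut, j, j) <- b
      expect_lt(pwm_score(pwm, mut), top)
    }
  }
})

test_that("an evenly split column contributes zero log-odds", {
  motifs <- vapply(c("A", "C", "G", "T"), function(b) {
    m <- g$canonical; substr(m, 5, 5) <- b; m
  }, "")
  pwm <- build_pwm(unname(motifs), g, pseudocount = 0.5)
  expect_equal(unname(pwm$mat[, 5]), rep(0, 4), tolerance = 1e-12)
  expect_error(build_pwm(c(g$canonical, "ACGT"), g), "grammar length")
})

test_that("scan_pwm equals the brute-force sliding-window scorer", {
  pwm <- build_pwm(g$canonical, g)
  cfg <- scan_config(score_floor = -Inf)
  for (s in 1:8) {
    n <- sample(200:900, 1)
    seq <- oracle_random_seq(n, seed = 7000 + s)
    rec <- seq_record("r", seq, "linear")
    hits <- scan_pwm(rec, pwm, cfg)
    fwd_scores <- oracle_pwm_scores(seq, pwm)
    rev_scores <- oracle_pwm_scores(oracle_revcomp(seq), pwm)
    for (i in seq_len(nrow(hits))) {
      expected <- if (hits$strand[i] == "+") {
        fwd_scores[hits$start[i]]
      } else {
        rev_scores[n - hits$end[i] + 1L]
      }
      expect_equal(hits$score[i], expected, tolerance = 1e-10)
    }
    # the best reported hit carries the global maximum score
    expect_equal(max(hits$score), max(c(fwd_scores, rev_scores)),
                 tolerance = 1e-10)
  }
})

test_that("planted motifs are found at their positions on both strands", {
  pwm <- build_pwm(g$canonical, g)
  withr::with_seed(95, {
    bg <- oracle_random_seq(2000, seed = 96)
    seq <- bg
    substr(seq, 501, 528) <- g$canonical
    rc_insert <- revcomp(g$canonical)
    substr(seq, 1201, 1228) <- rc_insert
  })
  rec <- seq_record("m", seq, "linear")
  hits <- scan_pwm(rec, pwm, scan_config(score_floor = 20))
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$start, c(501L, 1201L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$score[1], hits$score[2])  # strand symmetry
  expect_equal(unique(hits$seq), g$canonical)
  # circular wrap: motif across the origin is still found
  rot <- paste0(substr(seq, 515, 2000), substr(seq, 1, 514))
  chits <- scan_pwm(seq_record("c", rot, "circular"), pwm,
                    scan_config(score_floor = 20))
  expect_equal(nrow(chits), 2L)
  expect_true(any(chits$end > 2000L | chits$start > 1973L | chits$start < 29L |
                    (chits$start + 27L) %% 2000L == chits$end %% 2000L))
})

test_that("the auto threshold matches its per-window tail target", {
  pwm <- build_pwm(g$canonical, g)
  cfg <- scan_config()
  thr <- pwm_threshold(pwm, cfg)
  target <- cfg$null_fpr / (2 * 5000)
  # Monte-Carlo check of the DP distribution
  withr::with_seed(97, {
    scores <- replicate(50000, {
      pwm_score(pwm, paste(sample(c("A", "C", "G", "T"), 28, TRUE),
                           collapse = ""))
    })
  })
  expect_lte(mean(scores >= thr), 10 * target)  # loose MC bound
  # one bin lower must violate the target (minimality of the threshold)
  imat_tail <- mean(scores >= thr - 2)
  expect_gt(thr, 0)
})

test_that("filter_hits applies the identity and coding-context rules", {
  cfg <- scan_config(primary_threshold = 22)
  genes <- tibble::tibble(start = c(201L, 1001L), end = c(700L, 1600L),
                          strand = c("+", "+"), role = c("VP4", "VP1"))
  mk_hit <- function(start, seq, score) {
    tibble::tibble(record_id = "m", start = start, end = start + 27L,
                   strand = "+", seq = seq, score = score)
  }
  near <- gokuphage:::mutate_k(withr::with_seed(98, g$canonical), 0)
  withr::with_seed(99, near <- gokuphage:::mutate_k(g$canonical, 12))  # 16 identical
  far <- withr::with_seed(100, gokuphage:::mutate_k(g$canonical, 16))  # 12 identical
  hits <- dplyr::bind_rows(
    mk_hit(50L, g$canonical, 28),     # intergenic, above threshold
    mk_hit(800L, near, 10),           # intergenic, sub-threshold, 16 bp identity
    mk_hit(1200L, near, 10),          # mid-VP1, must be rejected
    mk_hit(205L, near, 10),           # VP4 N-terminus (bases 5-32): retained
    mk_hit(900L, far, 5))             # intergenic, 12 bp identity: rejected
  out <- filter_hits(hits, genes, confirmed = g$canonical, cfg = cfg)
  expect_equal(out$status,
               c("confirmed", "potential", "rejected", "potential", "rejected"))
  expect_equal(out$reject_reason[3], "coding_internal")
  expect_equal(out$reject_reason[5], "below_identity")
  expect_equal(out$best_identity[2], 16L)
  # the filter never changes coordinates or scores
  expect_equal(out$start, hits$start)
  expect_equal(out$score, hits$score)
  # a high-scoring mid-gene hit is still removed
  hot <- filter_hits(mk_hit(1200L, g$canonical, 28), genes,
                     confirmed = g$canonical, cfg = cfg)
  expect_equal(hot$status, "rejected")
})

test_that("iterative search chains discoveries through new motifs", {
  # MAG 1 carries a motif findable from the seed; MAG 2 carries a motif too
  # divergent from the seed (13 identical bases) but close to MAG 1's motif
  withr::with_seed(101, {
    m1 <- gokuphage:::mutate_k(g$canonical, 4)
  })
  m2 <- m1
  # mutate 11 positions of m1 that were untouched vs canonical, leaving
  # m2 with >= 15 identity to m1 but <= 14 to the canonical seed
  diff_pos <- which(strsplit(m1, "")[[1]] == strsplit(g$canonical, "")[[1]])
  withr::with_seed(102, {
    for (p in sample(diff_pos, 11)) {
      substr(m2, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(m2, p, p))[1]
    }
  })
  expect_gte(28 - gokuphage:::hamming(m2, m1), 15)
  expect_lte(28 - gokuphage:::hamming(m2, g$canonical), 14)
  bg1 <- oracle_random_seq(1500, seed = 103)
  bg2 <- oracle_random_seq(1500, seed = 104)
  substr(bg1, 701, 728) <- m1
  substr(bg2, 901, 928) <- m2
  mags <- seq_record(c("magA", "magB"), c(bg1, bg2), "circular")
  # gene-free annotation: this fixture tests the identity chaining rule,
  # not the context filter
  no_genes <- list(magA = find_orfs(mags[1, ])[0, ],
                   magB = find_orfs(mags[2, ])[0, ])
  cfg <- scan_config(score_floor = -15, primary_threshold = 15)
  res <- iterative_search(mags, g$canonical, no_genes, g, cfg)
  # round 1: m1 is close enough to the seed to be found and score-confirmed;
  # round 2: m2, invisible to the seed, is rescued by identity to m1
  expect_true(m1 %in% res$confirmed)
  expect_true(m2 %in% res$motifs)
  expect_gte(nrow(res$log), 2L)
  found <- res$hits %>%
    dplyr::filter(status %in% c("confirmed", "potential"))
  expect_setequal(found$record_id, c("magA", "magB"))
  expect_true(all(found$best_identity >= 15))
})

test_that("iterative search converges immediately with nothing planted", {
  mags <- seq_record(c("n1", "n2"),
                     c(oracle_random_seq(1200, seed = 105),
                       oracle_random_seq(1200, seed = 106)), "circular")
  genes <- list(n1 = find_orfs(mags[1, ]), n2 = find_orfs(mags[2, ]))
  # a stringent scan floor: nothing in the background resembles the motif
  res <- iterative_search(mags, g$canonical, genes, g,
                          scan_config(score_floor = 15))
  expect_equal(nrow(res$log), 1L)
  expect_equal(res$motifs, g$canonical)
  expect_equal(nrow(dplyr::filter(res$hits,
                                  status %in% c("confirmed", "potential"))), 0L)
})

test_that("planted MAG motifs are recovered and negatives removed", {
  sc <- scan_config()
  for (s in c(110, 111)) {
    m <- make_mag_set(sim_config(seed = s, mag_count = 6))
    res <- iterative_search(m$records, g$canonical, NULL, g, sc)
    accepted <- res$hits %>%
      dplyr::filter(status %in% c("confirmed", "potential"))
    truth <- m$truth$mag_motifs
    keep <- truth %>%
      dplyr::filter(context %in% c("non_coding", "coding_VP4_Nterm"))
    drop <- truth %>% dplyr::filter(context == "coding_internal")
    for (i in seq_len(nrow(keep))) {
      expect_true(any(accepted$record_id == keep$record_id[i] &
                        accepted$start == keep$start[i]),
                  info = sprintf("seed %d motif %d", s, i))
    }
    for (i in seq_len(nrow(drop))) {
      expect_false(any(accepted$record_id == drop$record_id[i] &
                         accepted$start == drop$start[i]))
    }
    for (i in seq_len(nrow(m$truth$decoys))) {
      expect_false(any(accepted$record_id == m$truth$decoys$record_id[i] &
                         accepted$start == m$truth$decoys$start[i]))
    }
  }
})
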