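g <- dif_grammar()

test_that("find_capsid_loci recovers a planted capsid ORF on either strand", {
  refs <- vp_reference_proteins()
  withr::with_seed(41, {
    vp1_nt <- gokuphage:::back_translate(refs[["VP1"]])
    bg <- oracle_random_seq(8000, seed = 42)
    seq <- paste0(substr(bg, 1, 3000), vp1_nt, substr(bg, 3001, 8000))
  })
  rec <- seq_record("h", seq, "linear")
  loci <- find_capsid_loci(rec, refs[["VP1"]])
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$strand, "+")
  expect_lte(abs(loci$start - 3001L), 3L)
  expect_lte(abs(loci$end - (3000L + nchar(vp1_nt))), 3L)
  # reverse-complemented plant: same locus, minus strand
  rc <- seq_record("h_rc", revcomp(seq), "linear")
  loci_rc <- find_capsid_loci(rc, refs[["VP1"]])
  expect_equal(nrow(loci_rc), 1L)
  expect_equal(loci_rc$strand, "-")
  expect_equal(loci_rc$end - loci_rc$start, loci$end - loci$start)
  expect_error(find_capsid_loci(rec, "MKV"), "50 aa")
})

test_that("null genomes yield no capsid loci at the calibrated threshold", {
  refs <- vp_reference_proteins()
  for (s in 1:5) {
    rec <- seq_record("n", oracle_random_seq(15000, seed = 600 + s), "linear")
    expect_equal(nrow(find_capsid_loci(rec, refs[["VP1"]])), 0L)
  }
})

test_that("flanking repeats bracket a planted integration", {
  # construct a host whose bacterial and phage dif copies share >= 17 bp
  cfg <- small_sim(45, phage_dif_spacer_mut = 0, bacterial_dif_mut_max = 0L)
  h <- make_host(cfg); p <- make_phage(cfg)
  truth <- gokuphage:::merge_truth(h$truth, p$truth)
  pl <- plant_integration(h$record, p$record, truth)
  vp1 <- pl$truth$genes %>% dplyr::filter(role == "VP1")
  pairs <- find_flanking_repeats(pl$record, vp1)
  expect_gt(nrow(pairs), 0L)
  pro <- pl$truth$prophages
  # identical 28-bp copies: the top pair covers the two dif sites (maximal
  # extension may run a few matching bases past the site itself)
  bac <- pl$truth$dif_sites %>% dplyr::filter(type == "bacterial")
  expect_lte(pairs$up_start[1], unname(bac$start))
  expect_gte(pairs$up_end[1], unname(bac$end))
  expect_lte(pairs$down_start[1], pro$end - 27L)
  expect_gte(pairs$down_end[1], pro$end)
  expect_gte(pairs$length[1], 28L)
})

test_that("repeat search returns nothing without a shared 17-mer", {
  rec <- seq_record("r", oracle_random_seq(9000, seed = 48), "linear")
  locus <- tibble::tibble(start = 4400L, end = 4600L)
  expect_equal(nrow(find_flanking_repeats(rec, locus)), 0L)
})

test_that("a nearer repeat pair outranks a farther decoy pair", {
  withr::with_seed(49, {
    bg <- oracle_random_seq(9000, seed = 50)
    rep1 <- oracle_random_seq(19, seed = 51)  # true pair, encloses less
    rep2 <- oracle_random_seq(19, seed = 52)  # decoy pair, farther out
    seq <- bg
    substr(seq, 1000, 1018) <- rep2
    substr(seq, 2000, 2018) <- rep1
    substr(seq, 6000, 6018) <- rep1
    substr(seq, 7000, 7018) <- rep2
  })
  rec <- seq_record("d", seq, "linear")
  locus <- tibble::tibble(start = 4000L, end = 4500L)
  pairs <- find_flanking_repeats(rec, locus)
  expect_gte(nrow(pairs), 2L)
  expect_equal(pairs$up_start[1], 2000L)
  expect_equal(pairs$down_start[1], 6000L)
})

test_that("repeat pairs are invariant under reverse-complementing the contig", {
  sim <- make_integration(53)
  vp1 <- sim$planted$truth$genes %>% dplyr::filter(role == "VP1")
  n <- nchar(sim$planted$record$seq)
  fwd_pairs <- find_flanking_repeats(sim$planted$record, vp1)
  rc_rec <- seq_record("rc", revcomp(sim$planted$record$seq), "linear")
  rc_locus <- tibble::tibble(start = n - vp1$end + 1L, end = n - vp1$start + 1L)
  rc_pairs <- find_flanking_repeats(rc_rec, rc_locus)
  expect_equal(nrow(fwd_pairs), nrow(rc_pairs))
  if (nrow(fwd_pairs)) {
    # the top pair maps onto itself under coordinate reflection
    expect_equal(sort(c(n - fwd_pairs$down_end[1] + 1L,
                        n - fwd_pairs$down_start[1] + 1L)),
                 c(rc_pairs$up_start[1], rc_pairs$up_end[1]))
  }
})

test_that("call_prophage recovers the exact truth region and gene order", {
  sim <- make_integration(55)
  vp1 <- sim$planted$truth$genes %>% dplyr::filter(role == "VP1")
  pairs <- find_flanking_repeats(sim$planted$record, vp1)
  if (nrow(pairs) == 0L) {
    pairs <- gokuphage:::pwm_fallback_pair(sim$planted$record, vp1, g,
                                           miner_config(),
                                           build_pwm(g$canonical, g))
  }
  call <- call_prophage(sim$planted$record, vp1, pairs[1, ])
  expect_equal(call$status, "ok")
  pro <- sim$planted$truth$prophages
  expect_equal(c(call$start, call$end), c(pro$start, pro$end))
  expect_equal(call$upstream_dif$site_class, "bacterial_like")
  expect_equal(call$downstream_dif$site_class, "phage_like")
  # gene roles on the excised genome, rotated to the dif anchor, read
  # VP4, VP5, VP3, VP1, VP2, VP8 as a circular order
  anchor <- call$downstream_dif$seq
  rot <- canonical_rotation(call$excised, anchor)
  genes <- assign_roles(find_orfs(rot), vp_reference_proteins())
  roles <- genes$role[genes$role != "unknown"]
  expect_setequal(roles, c("VP4", "VP5", "VP3", "VP1", "VP2", "VP8"))
  i0 <- which(roles == "VP4")
  circ_order <- roles[((seq_along(roles) + i0 - 2L) %% length(roles)) + 1L]
  expect_equal(circ_order, c("VP4", "VP5", "VP3", "VP1", "VP2", "VP8"))
})

test_that("a swapped construct with a phage-like upstream site is rejected", {
  sim <- make_integration(57)
  pro <- sim$planted$truth$prophages
  pair <- tibble::tibble(up_start = pro$end - g$total + 1L,
                         up_end = pro$end,
                         down_start = pro$start - g$total,
                         down_end = pro$start - 1L, length = g$total)
  # upstream copy anchored on the phage dif: must be rejected with a reason
  call <- call_prophage(sim$planted$record,
                        tibble::tibble(start = pro$start, end = pro$end),
                        pair)
  expect_equal(call$status, "rejected")
  expect_match(call$reason, "not bacterial_like")
})

test_that("excision returns the planted phage and restores the host", {
  for (s in c(60, 61)) {
    sim <- make_integration(s)
    vp1 <- sim$planted$truth$genes %>% dplyr::filter(role == "VP1")
    pairs <- find_flanking_repeats(sim$planted$record, vp1)
    if (nrow(pairs) == 0L) {
      pairs <- gokuphage:::pwm_fallback_pair(sim$planted$record, vp1, g,
                                             miner_config(),
                                             build_pwm(g$canonical, g))
    }
    call <- call_prophage(sim$planted$record, vp1, pairs[1, ])
    out <- excise(sim$planted$record, call)
    # round trip up to rotation
    anchor <- sim$phage$truth$dif_sites$seq
    expect_equal(canonical_rotation(out$phage, anchor)$seq,
                 canonical_rotation(sim$phage$record, anchor)$seq)
    expect_equal(out$host_restored$seq, sim$host$record$seq)
    # length conservation
    expect_equal(nchar(out$phage$seq) + nchar(out$host_restored$seq),
                 nchar(sim$planted$record$seq))
    # the phage dif travels with the phage; the bacterial dif stays behind
    expect_equal(nrow(find_dif_sites(out$phage, g, max_mm = 13,
                                     exact_xerC_arm = TRUE)), 1L)
    expect_equal(nrow(find_dif_sites(out$phage, g, max_mm = 1)), 0L)
    expect_equal(nrow(find_dif_sites(out$host_restored, g, max_mm = 1)), 1L)
  }
})

test_that("integration requires active XerC, active XerD and a phage-like dif", {
  sim <- make_integration(63)
  h <- sim$host$record
  p <- sim$phage$record
  psite <- sim$phage$truth$dif_sites
  wt <- host_state()

  ok <- integrate_phage(h, p, wt, phage_dif = psite)
  expect_true(ok$integrated)
  expect_equal(nchar(ok$record$seq), nchar(h$seq) + nchar(p$seq))

  no_d <- integrate_phage(h, p, host_state(xerD_active = FALSE),
                          phage_dif = psite)
  expect_false(no_d$integrated)
  expect_match(no_d$reason, "xerD")

  no_c <- integrate_phage(h, p, host_state(xerC_active = FALSE),
                          phage_dif = psite)
  expect_false(no_c$integrated)
  expect_match(no_c$reason, "xerC")

  dC <- delete_dif_arm(p, psite, "C")
  rC <- integrate_phage(h, dC$record, wt, phage_dif = dC$dif_site)
  expect_false(rC$integrated)
  expect_match(rC$reason, "partial_C_missing")

  dD <- delete_dif_arm(p, psite, "D")
  rD <- integrate_phage(h, dD$record, wt, phage_dif = dD$dif_site)
  expect_false(rD$integrated)
  expect_match(rD$reason, "partial_D_missing")

  dCD <- delete_dif_arm(p, psite, "CD")
  rCD <- integrate_phage(h, dCD$record, wt, phage_dif = dCD$dif_site)
  expect_false(rCD$integrated)
  expect_match(rCD$reason, "no phage dif")
})

test_that("auto-detection of the phage dif matches the planted site", {
  sim <- make_integration(65)
  res <- integrate_phage(sim$host$record, sim$phage$record, host_state())
  expect_true(res$integrated)
  expect_equal(res$record$seq, sim$planted$record$seq)
})

test_that("the complementation model reproduces the lysogeny truth table", {
  # ten strain/phage/plasmid conditions; only wild type and induced-xerC
  # complementation permit integration
  states <- list(
    wt           = host_state(),
    dC           = host_state(xerC_active = FALSE),
    dC_ind       = apply_complementation(host_state(xerC_active = FALSE),
                                         "xerC", induced = TRUE),
    dC_unind     = apply_complementation(host_state(xerC_active = FALSE),
                                         "xerC", induced = FALSE),
    dD           = host_state(xerD_active = FALSE),
    dD_ind       = apply_complementation(host_state(xerD_active = FALSE),
                                         "xerD", induced = TRUE),
    dD_unind     = apply_complementation(host_state(xerD_active = FALSE),
                                         "xerD", induced = FALSE))
  expect_true(states$wt$xerC_active && states$wt$xerD_active)
  expect_true(states$dC_ind$xerC_active)
  expect_false(states$dC_unind$xerC_active)
  # plasmid-borne xerD does not restore activity (non-complementable)
  expect_false(states$dD_ind$xerD_active)
  sim <- make_integration(67)
  psite <- sim$phage$truth$dif_sites
  outcomes <- vapply(states, function(st) {
    integrate_phage(sim$host$record, sim$phage$record, st,
                    phage_dif = psite)$integrated
  }, logical(1))
  expect_equal(unname(outcomes),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("integration errors on hosts without a unique bacterial dif", {
  sim <- make_integration(69)
  p <- sim$phage$record
  psite <- sim$phage$truth$dif_sites
  bare <- seq_record("bare", oracle_random_seq(4000, seed = 70), "linear")
  expect_error(integrate_phage(bare, p, host_state(), phage_dif = psite),
               "exactly one bacterial-like dif")
  g2 <- dif_grammar()
  two <- seq_record("two", paste0(oracle_random_seq(1000, seed = 71),
                                  g2$canonical,
                                  oracle_random_seq(1000, seed = 72),
                                  g2$canonical,
                                  oracle_random_seq(1000, seed = 73)),
                    "linear")
  expect_error(integrate_phage(two, p, host_state(), phage_dif = psite),
               "exactly one bacterial-like dif")
})

test_that("mine recovers planted prophages end to end, including multi-call", {
  refs <- vp_reference_proteins()
  genomes <- list(); truths <- list()
  for (s in c(81, 82, 83)) {
    sim <- make_integration(s)
    rec <- sim$planted$record
    rec$id <- paste0("lysogen_", s)
    tr <- sim$planted$truth
    tr$prophages$record_id <- rec$id
    genomes[[length(genomes) + 1L]] <- rec
    truths[[length(truths) + 1L]] <- tr$prophages
  }
  # one genome with no prophage at all
  genomes[[4]] <- seq_record("empty_host",
                             oracle_random_seq(12000, seed = 84), "linear")
  calls <- mine(dplyr::bind_rows(genomes), refs[["VP1"]])
  truth_tbl <- dplyr::bind_rows(truths)
  expect_equal(nrow(calls), 3L)
  expect_false("empty_host" %in% calls$host_id)
  merged <- dplyr::left_join(calls, truth_tbl,
                             by = c(host_id = "record_id"),
                             suffix = c("", "_truth"))
  expect_equal(merged$start, merged$start_truth)
  expect_equal(merged$end, merged$end_truth)
})

test_that("mine reports two prophages inserted at two dif-like sites", {
  # one contig carrying two insertion sites, each with its own prophage
  s1 <- make_integration(86)
  s2 <- make_integration(88)
  fused <- seq_record("double",
                      paste0(s1$planted$record$seq, s2$planted$record$seq),
                      "linear")
  offset <- nchar(s1$planted$record$seq)
  calls <- mine(fused, vp_reference_proteins()[["VP1"]])
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$upstream_class, rep("bacterial_like", 2))
  t1 <- s1$planted$truth$prophages
  t2 <- s2$planted$truth$prophages
  expect_setequal(calls$start, c(t1$start, offset + t2$start))
  expect_setequal(calls$end, c(t1$end, offset + t2$end))
})
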