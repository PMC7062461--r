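# Independent brute-force oracles used across the suite. These deliberately
# use different code paths (string splitting, plain loops) than the package
# implementations they check.

oracle_random_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

oracle_revcomp <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# all ORFs (start..stop, no internal in-frame stop) on both strands of a
# short sequence, then the greedy longest-first filter
oracle_find_orfs <- function(seq, topology = "linear",
                             min_len = 110L, max_overlap = 50L,
                             starts = c("ATG", "GTG", "TTG")) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  cand <- list()
  scan_strand <- function(s, strand) {
    work <- if (topology == "circular") paste0(s, s) else s
    ch <- strsplit(work, "")[[1]]
    for (f in 0:2) {
      i <- f + 1L
      codon_pos <- seq(i, length(ch) - 2L, by = 3L)
      codons <- vapply(codon_pos, function(p) paste(ch[p:(p + 2)], collapse = ""), "")
      last_stop <- 0L
      for (k in seq_along(codons)) {
        if (codons[k] %in% stops) {
          for (m in seq_len(k - 1L)) {
            if (m <= last_stop) next
            if (!codons[m] %in% starts) next
            st <- codon_pos[m]; en <- codon_pos[k] + 2L
            len <- en - st + 1L
            if (len < min_len) next
            if (topology == "circular" && (len > n || st > n)) next
            if (topology == "linear" && en > n) next
            if (strand == "+") {
              cand[[length(cand) + 1L]] <<- c(st, en, 1L)
            } else {
              if (topology == "circular") {
                fs <- ((n - ((en - 1L) %% n) - 1L) %% n) + 1L
              } else {
                fs <- n - en + 1L
              }
              cand[[length(cand) + 1L]] <<- c(fs, fs + len - 1L, -1L)
            }
          }
          last_stop <- k
        }
      }
    }
  }
  scan_strand(seq, "+")
  scan_strand(oracle_revcomp(seq), "-")
  if (!length(cand)) {
    return(data.frame(start = integer(), end = integer(), strand = character()))
  }
  m <- unique(do.call(rbind, cand))
  df <- data.frame(start = m[, 1], end = m[, 2],
                   strand = ifelse(m[, 3] > 0, "+", "-"))
  df$len <- df$end - df$start + 1L
  df <- df[order(-df$len, df$start, df$strand), ]
  ov <- function(a1, b1, a2, b2) {
    o <- max(0L, min(b1, b2) - max(a1, a2) + 1L)
    if (topology == "circular") {
      o <- max(o, max(0L, min(b1, b2 - n) - max(a1, a2 - n) + 1L),
               max(0L, min(b1, b2 + n) - max(a1, a2 + n) + 1L))
    }
    o
  }
  keep <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in keep) {
      if (ov(df$start[i], df$end[i], df$start[j], df$end[j]) > max_overlap) {
        ok <- FALSE; break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  out <- df[keep, c("start", "end", "strand")]
  out[order(out$start, out$end), ]
}

# per-window PWM scores on one strand via plain substring loops
oracle_pwm_scores <- function(seq, pwm) {
  w <- pwm$width
  n <- nchar(seq)
  vapply(seq_len(n - w + 1L), function(p) {
    win <- strsplit(substr(seq, p, p + w - 1L), "")[[1]]
    total <- 0
    for (j in seq_len(w)) {
      b <- win[j]
      total <- total + if (b %in% rownames(pwm$mat)) pwm$mat[b, j] else
        min(pwm$mat[, j])
    }
    total
  }, numeric(1))
}

# connected components of ANI > threshold via repeated flood fill
oracle_components <- function(mat, threshold) {
  n <- nrow(mat)
  adj <- mat > threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# mean pairwise identity per column via explicit pair loops
oracle_identity_profile <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  vapply(seq_len(ncol(mat)), function(j) {
    same <- 0L; valid <- 0L
    nr <- nrow(mat)
    for (a in seq_len(nr - 1L)) {
      for (b in seq.int(a + 1L, nr)) {
        if (mat[a, j] == "-" || mat[b, j] == "-") next
        valid <- valid + 1L
        if (mat[a, j] == mat[b, j]) same <- same + 1L
      }
    }
    if (valid == 0L) NA_real_ else same / valid
  }, numeric(1))
}

# small simulation configuration used across miner tests: generator study
# conditions, scaled-down chromosome
small_sim <- function(seed, host_len = 12000L, ...) {
  sim_config(seed = seed, host_len = host_len, ...)
}

# convenience: host + phage + planted integration for one seed
make_integration <- function(seed, host_len = 12000L) {
  cfg <- small_sim(seed, host_len)
  h <- make_host(cfg)
  p <- make_phage(cfg)
  truth <- gokuphage:::merge_truth(h$truth, p$truth)
  pl <- plant_integration(h$record, p$record, truth)
  list(host = h, phage = p, planted = pl, cfg = cfg)
}
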