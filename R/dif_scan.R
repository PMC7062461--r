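#' Scan configuration
#'
#' Controls the PWM-based dif-motif search in phage genomes and MAGs: the
#' rescue rule for sub-threshold hits (at least `min_identity` bases
#' identical to a confirmed motif, in a non-coding or VP4-N-terminal
#' context), the primary score threshold (`"auto"` calibrates it from the
#' exact null score distribution so that the expected number of false hits
#' per 5 kb scanned on both strands is `null_fpr`), the scan floor below
#' which windows are not reported, and the iterative-search round cap.
#'
#' @param min_identity Minimum identical bases to a confirmed motif for
#'   the rescue rule.
#' @param primary_threshold Numeric log-odds threshold, or `"auto"`.
#' @param null_fpr Expected false hits per 5 kb (both strands) under the
#'   background model, used by `"auto"` calibration.
#' @param max_rounds Iterative search round cap.
#' @param score_floor Minimum log-odds score for a window to be reported
#'   by [scan_pwm()].
#' @param pseudocount PWM pseudocount.
#' @param background Background base frequencies.
#' @return List of class `scan_config`.
#' @export
scan_config <- function(min_identity = 15L, primary_threshold = "auto",
                        null_fpr = 0.05, max_rounds = 10L, score_floor = 0,
                        pseudocount = 0.5,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  structure(list(min_identity = as.integer(min_identity),
                 primary_threshold = primary_threshold,
                 null_fpr = null_fpr, max_rounds = as.integer(max_rounds),
                 score_floor = score_floor, pseudocount = pseudocount,
                 background = background),
            class = "scan_config")
}

BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix from aligned motifs
#'
#' Column counts plus a pseudocount give per-column base probabilities,
#' converted to log2 odds against the background. dif sites are
#' fixed-length and ungapped, so an ungapped PWM of the grammar width is
#' the site model.
#'
#' @param motifs Character vector of motifs, all of the grammar length.
#' @param grammar A [dif_grammar()].
#' @param pseudocount Added to every base count per column.
#' @param background Background base frequencies.
#' @return Object of class `goku_pwm`: log-odds `mat` (4 x width),
#'   probability matrix `prob`, `background`, `pseudocount`, `training`.
#' @export
build_pwm <- function(motifs, grammar = dif_grammar(), pseudocount = 0.5,
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  motifs <- normalize_seq(motifs)
  if (length(motifs) < 1L) abort("at least one motif required")
  w <- grammar$total
  if (any(nchar(motifs) != w)) {
    abort(sprintf("all motifs must have grammar length %d", w))
  }
  if (any(grepl("N", motifs, fixed = TRUE))) abort("motifs must not contain N")
  chars <- do.call(rbind, strsplit(motifs, ""))
  counts <- vapply(seq_len(w), function(j) {
    tab <- table(factor(chars[, j], levels = BASES))
    as.integer(tab)
  }, integer(4))
  prob <- (counts + pseudocount) / (length(motifs) + 4 * pseudocount)
  rownames(prob) <- BASES
  mat <- log2(prob / background[BASES])
  structure(list(mat = mat, prob = prob, background = background[BASES],
                 pseudocount = pseudocount, training = motifs, width = w),
            class = "goku_pwm")
}

#' @export
print.goku_pwm <- function(x, ...) {
  cat(sprintf("PWM: width %d, %d training motif(s), pseudocount %g\nconsensus: %s\n",
              x$width, length(x$training), x$pseudocount, pwm_consensus(x)))
  invisible(x)
}

pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$mat, 2, which.max)], collapse = "")
}

#' Score a single sequence against a PWM
#'
#' @param pwm A `goku_pwm`.
#' @param seq Sequence of the PWM width.
#' @return Log-odds score (sum of per-column entries; `N` contributes the
#'   column minimum).
#' @export
pwm_score <- function(pwm, seq) {
  seq <- normalize_seq(seq)
  stopifnot(nchar(seq) == pwm$width)
  pwm_window_scores(seq, pwm)
}

# log-odds score of every window of seq (vectorized); N scores the column min
pwm_window_scores <- function(seq, pwm) {
  n <- nchar(seq)
  w <- pwm$width
  if (n < w) return(numeric(0))
  code <- match(strsplit(seq, "")[[1L]], BASES)
  mat5 <- rbind(pwm$mat, apply(pwm$mat, 2, min))
  code[is.na(code)] <- 5L
  k <- n - w + 1L
  sc <- numeric(k)
  for (j in seq_len(w)) {
    sc <- sc + mat5[cbind(code[j:(j + k - 1L)], j)]
  }
  sc
}

#' Calibrated primary score threshold
#'
#' Computes the exact distribution of PWM scores under the background model
#' by per-column convolution on a discretised score lattice, and returns
#' the smallest threshold whose per-window tail probability keeps the
#' expected number of false hits per 5 kb (both strands) at or below
#' `null_fpr`.
#'
#' @param pwm A `goku_pwm`.
#' @param cfg A [scan_config()].
#' @param bin Score discretisation step.
#' @return Numeric threshold.
#' @export
pwm_threshold <- function(pwm, cfg = scan_config(), bin = 0.01) {
  if (is.numeric(cfg$primary_threshold)) return(cfg$primary_threshold)
  imat <- round(pwm$mat / bin)
  lo <- sum(apply(imat, 2, min)); hi <- sum(apply(imat, 2, max))
  probs <- numeric(hi - lo + 1L)
  offs <- -lo + 1L
  probs[0L + offs] <- 1
  cur_lo <- 0L; cur_hi <- 0L
  bg <- pwm$background
  for (j in seq_len(ncol(imat))) {
    newp <- numeric(length(probs))
    for (b in seq_len(4L)) {
      s <- imat[b, j]
      idx <- (cur_lo:cur_hi) + offs
      newp[idx + s] <- newp[idx + s] + probs[idx] * bg[b]
    }
    probs <- newp
    cur_lo <- cur_lo + min(imat[, j]); cur_hi <- cur_hi + max(imat[, j])
  }
  tail_p <- rev(cumsum(rev(probs)))
  target <- cfg$null_fpr / (2 * 5000)
  vals <- (seq_along(probs) - offs) * bin
  ok <- which(tail_p <= target)
  if (!length(ok)) return(vals[length(vals)] + bin)
  vals[min(ok)]
}

#' Scan a record for dif-like motifs with a PWM
#'
#' Scores every position on both strands (wrapping the origin on circular
#' records); windows at or above the scan floor are reported, overlapping
#' same-strand hits are resolved to the local score maximum, and results
#' are sorted by decreasing score. Ties break to the `+` strand, then
#' leftmost.
#'
#' @param record One-row record tibble.
#' @param pwm A `goku_pwm`.
#' @param cfg A [scan_config()].
#' @return Hit tibble: `record_id`, `start`, `end` (forward-strand frame;
#'   `end` may exceed the record length for origin-spanning hits), `strand`,
#'   `seq` (motif orientation), `score`.
#' @export
scan_pwm <- function(record, pwm, cfg = scan_config()) {
  stopifnot(nrow(record) == 1L)
  n <- nchar(record$seq)
  w <- pwm$width
  if (n < w) abort("record shorter than PWM width")
  circular <- record$topology == "circular"
  one_strand <- function(seq, strand) {
    ext <- if (circular) paste0(seq, substr(seq, 1L, w - 1L)) else seq
    sc <- pwm_window_scores(ext, pwm)
    keep <- which(sc >= cfg$score_floor)
    keep <- keep[keep <= n]
    if (!length(keep)) return(NULL)
    start <- if (strand == "+") keep else ((n - (keep + w - 1L)) %% n) + 1L
    tibble(record_id = record$id, start = as.integer(start),
           end = as.integer(start + w - 1L), strand = strand,
           seq = substring(ext, keep, keep + w - 1L), score = sc[keep])
  }
  hits <- bind_rows(one_strand(record$seq, "+"),
                    one_strand(revcomp(record$seq), "-"))
  if (is.null(hits) || nrow(hits) == 0L) {
    return(tibble(record_id = character(), start = integer(), end = integer(),
                  strand = character(), seq = character(), score = numeric()))
  }
  hits <- hits %>% arrange(desc(.data$score), match(.data$strand, c("+", "-")),
                           .data$start)
  wrap_n <- if (circular) n else NULL
  acc <- integer(0)
  for (i in seq_len(nrow(hits))) {
    same <- acc[hits$strand[acc] == hits$strand[i]]
    if (!length(same) ||
          all(interval_overlap(hits$start[i], hits$end[i],
                               hits$start[same], hits$end[same], wrap_n) == 0L)) {
      acc <- c(acc, i)
    }
  }
  hits[acc, ]
}

#' Apply the confirmation and rescue filters to scan hits
#'
#' Implements the dif-motif acceptance rules. Every accepted hit must have
#' at least `min_identity` bases positionally identical (grammar frame, no
#' shifts) to a confirmed motif, and must lie in a non-coding region or
#' within the N-terminal window of a VP4 gene — hits elsewhere in coding
#' sequence are rejected as likely false positives, since an integration
#' there would interrupt the gene. Among accepted hits, those at or above
#' the primary score threshold are `confirmed` (and may later vouch for
#' other hits); the rest are `potential`. Coordinates and scores are never
#' altered, only the status.
#'
#' @param hits Hit tibble from [scan_pwm()].
#' @param genes Gene calls for the same record ([find_orfs()] +
#'   [assign_roles()]).
#' @param confirmed Character vector of confirmed dif motifs.
#' @param cfg A [scan_config()].
#' @param ann_cfg An [annotation_config()].
#' @param pwm Optional PWM used for `"auto"` threshold resolution.
#' @param record_len Record length for circular context handling.
#' @return `hits` with `best_identity`, `context`, `status`,
#'   `reject_reason` columns.
#' @export
filter_hits <- function(hits, genes, confirmed, cfg = scan_config(),
                        ann_cfg = annotation_config(), pwm = NULL,
                        record_len = NULL) {
  thr <- if (is.numeric(cfg$primary_threshold)) {
    cfg$primary_threshold
  } else {
    if (is.null(pwm)) abort("pwm required to resolve an 'auto' threshold")
    pwm_threshold(pwm, cfg)
  }
  if (nrow(hits) == 0L) {
    hits$best_identity <- integer(0); hits$context <- character(0)
    hits$status <- character(0); hits$reject_reason <- character(0)
    return(hits)
  }
  w <- nchar(hits$seq[1L])
  hits$best_identity <- map_int(hits$seq, function(s) {
    if (!length(confirmed)) return(0L)
    as.integer(max(vapply(confirmed, function(m) w - hamming(s, m), numeric(1))))
  })
  hits$context <- map_chr(seq_len(nrow(hits)), function(i) {
    coding_context(hits$start[i], hits$end[i], genes, ann_cfg, record_len)
  })
  ok_ctx <- hits$context %in% c("non_coding", "coding_VP4_Nterm")
  ok_id <- hits$best_identity >= cfg$min_identity
  status <- rep("rejected", nrow(hits))
  reason <- rep(NA_character_, nrow(hits))
  status[ok_ctx & ok_id & hits$score >= thr] <- "confirmed"
  status[ok_ctx & ok_id & hits$score < thr] <- "potential"
  rej <- status == "rejected"
  reason[rej & !ok_ctx] <- hits$context[rej & !ok_ctx]
  reason[rej & ok_ctx] <- "below_identity"
  hits$status <- status
  hits$reject_reason <- reason
  hits
}

#' Iterative PWM search for dif-like motifs across a MAG set
#'
#' Rounds of [build_pwm()] on the current motif set, [scan_pwm()] over
#' every MAG, and [filter_hits()]; the sequences of confirmed and
#' potential hits join the PWM training set, enabling discovery of motifs
#' too divergent from the seeds to be found in one pass. Only confirmed
#' motifs (seeds plus hits reaching the primary threshold) back the
#' identity-rescue comparison — a potential hit cannot vouch for further
#' hits. Stops when a round adds no new motif or after `max_rounds`.
#'
#' @param mags Record tibble of MAGs.
#' @param seed_motifs Character vector of seed (confirmed) motifs.
#' @param genes_by_mag Named list of gene-call tibbles (names = record
#'   ids); `NULL` annotates each MAG with [find_orfs()] +
#'   [assign_roles()].
#' @param grammar A [dif_grammar()].
#' @param cfg A [scan_config()].
#' @param ann_cfg An [annotation_config()].
#' @param references Reference proteins for role assignment when
#'   annotating internally.
#' @return List: `motifs` (final PWM training set), `confirmed` (seeds plus
#'   score-confirmed hit motifs), `hits` (accepted hits accumulated over
#'   all rounds — a discovery is never dropped by later PWM drift — plus
#'   the last round's rejected hits for diagnostics), `log` (per-round
#'   tibble).
#' @export
iterative_search <- function(mags, seed_motifs, genes_by_mag = NULL,
                             grammar = dif_grammar(), cfg = scan_config(),
                             ann_cfg = annotation_config(),
                             references = vp_reference_proteins()) {
  if (is.null(genes_by_mag)) {
    genes_by_mag <- map(seq_len(nrow(mags)), function(i) {
      g <- find_orfs(mags[i, ], ann_cfg)
      if (nrow(g)) assign_roles(g, references, ann_cfg) else g
    })
    names(genes_by_mag) <- mags$id
  }
  confirmed_motifs <- unique(normalize_seq(seed_motifs))
  training <- confirmed_motifs
  log_rows <- list()
  accepted_all <- NULL
  last_rejected <- NULL
  mags_with_hits <- character(0)
  for (round in seq_len(cfg$max_rounds)) {
    pwm <- build_pwm(training, grammar, cfg$pseudocount, cfg$background)
    round_hits <- map(seq_len(nrow(mags)), function(i) {
      rec <- mags[i, ]
      h <- scan_pwm(rec, pwm, cfg)
      filter_hits(h, genes_by_mag[[rec$id]], confirmed_motifs, cfg, ann_cfg,
                  pwm, record_len = nchar(rec$seq))
    }) %>% list_rbind()
    accepted <- round_hits %>% filter(.data$status %in% c("confirmed", "potential"))
    new_motifs <- setdiff(unique(accepted$seq), training)
    log_rows[[round]] <- tibble(round = round,
                                training_size = length(training),
                                n_hits = nrow(accepted),
                                n_new_motifs = length(new_motifs))
    accepted_all <- bind_rows(accepted_all, accepted) %>%
      distinct(.data$record_id, .data$start, .data$strand, .keep_all = TRUE)
    last_rejected <- round_hits %>% filter(.data$status == "rejected")
    confirmed_motifs <- union(confirmed_motifs,
                              accepted$seq[accepted$status == "confirmed"])
    training <- c(training, new_motifs)
    # stop when no MAG newly gains a hit (and nothing new would retrain)
    new_set <- union(mags_with_hits, unique(accepted$record_id))
    if (setequal(new_set, mags_with_hits) || !length(new_motifs)) break
    mags_with_hits <- new_set
  }
  if (!is.null(accepted_all) && nrow(accepted_all) && !is.null(last_rejected)) {
    last_rejected <- dplyr::anti_join(
      last_rejected, accepted_all, by = c("record_id", "start", "strand"))
  }
  list(motifs = training, confirmed = confirmed_motifs,
       hits = bind_rows(accepted_all, last_rejected),
       log = list_rbind(log_rows))
}
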