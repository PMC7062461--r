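#' Find capsid-protein loci by translated local alignment
#'
#' Six-frame translation of the record followed by local protein alignment
#' (BLOSUM62, affine gaps) of the query against each frame. Loci scoring at
#' least `capsid_score_min` are reported with nucleotide coordinates and
#' strand; detected regions are masked and the search repeated so multiple
#' non-overlapping loci (multi-prophage genomes) are recovered.
#'
#' @param record One-row record tibble.
#' @param query Capsid protein sequence (>= 50 aa), e.g. the VP1 entry of
#'   [vp_reference_proteins()].
#' @param cfg A [miner_config()].
#' @param max_loci Safety cap on reported loci.
#' @return Tibble of loci: `start`, `end`, `strand`, `score`.
#' @export
find_capsid_loci <- function(record, query, cfg = miner_config(),
                             max_loci = 5L) {
  stopifnot(nrow(record) == 1L)
  if (nchar(query) < 50L) abort("capsid query must be at least 50 aa")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", query)) {
    abort("query contains invalid residues")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  qry <- Biostrings::AAString(query)
  seq <- record$seq
  n <- nchar(seq)
  loci <- list()
  for (round in seq_len(max_loci)) {
    best <- NULL
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seq else revcomp(seq)
      for (f in 0:2) {
        sub_len <- floor((n - f) / 3) * 3
        if (sub_len < 150L) next
        frame_nt <- substr(s, f + 1L, f + sub_len)
        frame_nt <- gsub("N", "A", frame_nt, fixed = TRUE)
        aa <- Biostrings::translate(Biostrings::DNAString(frame_nt),
                                    if.fuzzy.codon = "X")
        al <- Biostrings::pairwiseAlignment(qry, aa, type = "local",
                                            substitutionMatrix = mat,
                                            gapOpening = 10, gapExtension = 0.5)
        sc <- Biostrings::score(al)
        if (is.null(best) || sc > best$score) {
          rng <- al@subject@range
          best <- list(score = sc, strand = strand, f = f,
                       aa_start = BiocGenerics::start(rng),
                       aa_end = BiocGenerics::end(rng))
        }
      }
    }
    if (is.null(best) || best$score < cfg$capsid_score_min) break
    nt_s <- best$f + 3L * (best$aa_start - 1L) + 1L
    nt_e <- best$f + 3L * best$aa_end
    if (best$strand == "-") {
      tmp <- nt_s
      nt_s <- n - nt_e + 1L
      nt_e <- n - tmp + 1L
    }
    loci[[length(loci) + 1L]] <- tibble(start = nt_s, end = nt_e,
                                        strand = best$strand,
                                        score = best$score)
    # mask the detected locus and search again
    substr(seq, nt_s, nt_e) <- paste(rep("N", nt_e - nt_s + 1L), collapse = "")
  }
  if (!length(loci)) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  score = numeric()))
  }
  list_rbind(loci) %>% arrange(.data$start)
}

#' Find identical flanking repeats around a capsid locus
#'
#' Searches the `flank_len` windows upstream and downstream of a locus for
#' maximal exact repeats seeded by shared `repeat_seed_len`-mers (same
#' orientation), the attachment-site signature of a dif-flanked insertion.
#' Each seed is extended to maximal identity; candidate pairs are ranked by
#' longer extended match, then smaller enclosed interval, then leftmost
#' upstream copy.
#'
#' @param record One-row record tibble.
#' @param locus One-row locus tibble (`start`, `end`) from
#'   [find_capsid_loci()].
#' @param cfg A [miner_config()].
#' @return Tibble of repeat pairs: `up_start`, `up_end`, `down_start`,
#'   `down_end`, `length`.
#' @export
find_flanking_repeats <- function(record, locus, cfg = miner_config()) {
  stopifnot(nrow(record) == 1L)
  n <- nchar(record$seq)
  k <- cfg$repeat_seed_len
  up_lo <- max(1L, locus$start - cfg$flank_len)
  up_hi <- locus$start - 1L
  dn_lo <- locus$end + 1L
  dn_hi <- min(n, locus$end + cfg$flank_len)
  if (up_hi - up_lo + 1L < k || dn_hi - dn_lo + 1L < k) {
    if (up_lo == 1L || dn_hi == n) {
      warning("flank window truncated at contig end")
    }
    return(empty_pairs())
  }
  if (up_lo == 1L || dn_hi == n) warning("flank window truncated at contig end")
  s <- strsplit(record$seq, "")[[1L]]
  up_kmers <- substring(record$seq, up_lo:(up_hi - k + 1L),
                        (up_lo + k - 1L):up_hi)
  dn_kmers <- substring(record$seq, dn_lo:(dn_hi - k + 1L),
                        (dn_lo + k - 1L):dn_hi)
  shared <- intersect(up_kmers, dn_kmers)
  if (!length(shared)) return(empty_pairs())
  pairs <- list()
  for (km in shared) {
    us <- up_lo - 1L + which(up_kmers == km)
    ds <- dn_lo - 1L + which(dn_kmers == km)
    for (u in us) for (d in ds) {
      # extend to maximal identity
      u1 <- u; d1 <- d
      while (u1 > 1L && d1 > 1L && s[u1 - 1L] == s[d1 - 1L] &&
               s[u1 - 1L] != "N") {
        u1 <- u1 - 1L; d1 <- d1 - 1L
      }
      u2 <- u + k - 1L; d2 <- d + k - 1L
      while (u2 < n && d2 < n && s[u2 + 1L] == s[d2 + 1L] &&
               s[u2 + 1L] != "N" && u2 + 1L < d1) {
        u2 <- u2 + 1L; d2 <- d2 + 1L
      }
      pairs[[length(pairs) + 1L]] <- c(u1, u2, d1, d2)
    }
  }
  m <- unique(do.call(rbind, pairs))
  out <- tibble(up_start = m[, 1], up_end = m[, 2], down_start = m[, 3],
                down_end = m[, 4], length = m[, 2] - m[, 1] + 1L)
  out %>% arrange(desc(.data$length),
                  .data$down_end - .data$up_start,
                  .data$up_start)
}

empty_pairs <- function() {
  tibble(up_start = integer(), up_end = integer(), down_start = integer(),
         down_end = integer(), length = integer())
}

# best-scoring grammar window near a repeat copy, as a classified dif site
anchor_dif_window <- function(record, copy_start, copy_end, grammar, cfg,
                              pwm) {
  w <- grammar$total
  lo <- max(1L, copy_start - w)
  hi <- min(nchar(record$seq), copy_end + w)
  region <- substr(record$seq, lo, hi)
  if (nchar(region) < w) return(NULL)
  sc <- pwm_window_scores(region, pwm)
  best <- which.max(sc)
  start <- lo + best - 1L
  dif_site_at(record, start, grammar, cfg)
}

#' Call a prophage from a capsid locus and a boundary repeat pair
#'
#' Anchors the dif grammar window at each repeat copy (best PWM-scoring
#' window near the copy), classifies both sites, and accepts the call when
#' the upstream site is bacterial-like. The prophage region runs from the
#' first base after the upstream dif through the last base of the
#' downstream dif, so the phage dif travels with the excised genome while
#' the bacterial dif stays behind. Genes are annotated on the excised
#' genome.
#'
#' @param record One-row record tibble.
#' @param locus One-row capsid locus tibble.
#' @param pair One-row repeat-pair tibble from [find_flanking_repeats()],
#'   or a pseudo-pair from the PWM fallback.
#' @param grammar A [dif_grammar()].
#' @param cfg A [miner_config()].
#' @param ann_cfg An [annotation_config()].
#' @param references Reference proteins for role assignment.
#' @param pwm Optional PWM for dif anchoring (default: canonical-trained).
#' @return A `prophage_call` object (status `"ok"`) or a rejection (status
#'   `"rejected"` with a reason).
#' @export
call_prophage <- function(record, locus, pair, grammar = dif_grammar(),
                          cfg = miner_config(),
                          ann_cfg = annotation_config(),
                          references = vp_reference_proteins(),
                          pwm = NULL) {
  if (is.null(pwm)) pwm <- build_pwm(grammar$canonical, grammar)
  up <- anchor_dif_window(record, pair$up_start, pair$up_end, grammar, cfg, pwm)
  down <- anchor_dif_window(record, pair$down_start, pair$down_end, grammar,
                            cfg, pwm)
  rejection <- function(reason) {
    structure(list(host_id = record$id, status = "rejected", reason = reason),
              class = "prophage_call")
  }
  if (is.null(up) || is.null(down)) return(rejection("boundary outside contig"))
  if (up$site_class == "bacterial_like" && down$site_class == "bacterial_like" &&
        up$seq == down$seq) {
    return(rejection("ambiguous boundary: two identical bacterial-like sites"))
  }
  if (up$site_class != "bacterial_like") {
    return(rejection(sprintf("upstream site not bacterial_like (%s)",
                             up$site_class)))
  }
  region_start <- up$end + 1L
  region_end <- down$end
  if (region_end <= region_start) return(rejection("empty region"))
  excised <- seq_record(paste0(record$id, "_prophage"),
                        substr(record$seq, region_start, region_end),
                        "circular")
  genes <- find_orfs(excised, ann_cfg)
  if (nrow(genes)) genes <- assign_roles(genes, references, ann_cfg)
  structure(list(host_id = record$id, status = "ok", reason = NA_character_,
                 start = region_start, end = region_end,
                 length = region_end - region_start + 1L,
                 upstream_dif = up, downstream_dif = down,
                 genes = genes, excised = excised),
            class = "prophage_call")
}

#' @export
print.prophage_call <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("prophage call on %s: REJECTED (%s)\n", x$host_id, x$reason))
    return(invisible(x))
  }
  cat(sprintf("prophage call on %s: %d-%d (%d bp), upstream %s / downstream %s, %d genes\n",
              x$host_id, x$start, x$end, x$length,
              x$upstream_dif$site_class, x$downstream_dif$site_class,
              nrow(x$genes)))
  invisible(x)
}

#' @importFrom generics tidy glance
#' @export
tidy.prophage_call <- function(x, ...) {
  if (x$status != "ok") {
    return(tibble(host_id = x$host_id, status = x$status, reason = x$reason))
  }
  tibble(host_id = x$host_id, status = x$status, start = x$start, end = x$end,
         length = x$length,
         upstream_class = x$upstream_dif$site_class,
         downstream_class = x$downstream_dif$site_class,
         n_genes = nrow(x$genes))
}

#' Excise a called prophage into its circular replicative form
#'
#' The excised genome is the prophage region circularised: it carries the
#' phage dif exactly once and the bacterial dif not at all, mirroring
#' amplification with primers that incorporate the phage dif but exclude
#' the bacterial one. The restored host retains its bacterial dif
#' unchanged, and lengths are conserved.
#'
#' @param record One-row record tibble the call refers to.
#' @param call A `prophage_call` with status `"ok"`, or one row of the
#'   tibble returned by [mine()].
#' @return List with `phage` (circular record) and `host_restored`.
#' @export
excise <- function(record, call) {
  if (is.data.frame(call)) {
    stopifnot(nrow(call) == 1L)
    call <- structure(c(as.list(call[, c("host_id", "status", "start",
                                         "end", "length")]),
                        list(genes = call$genes[[1L]],
                             upstream_dif = call$upstream_dif[[1L]],
                             downstream_dif = call$downstream_dif[[1L]],
                             excised = call$excised[[1L]])),
                      class = "prophage_call")
  }
  stopifnot(inherits(call, "prophage_call"), call$status == "ok")
  n <- nchar(record$seq)
  if (call$start < 1L || call$end > n) abort("region out of bounds")
  phage <- seq_record(paste0(record$id, "_phage"),
                      substr(record$seq, call$start, call$end), "circular")
  host <- seq_record(record$id,
                     paste0(substr(record$seq, 1L, call$start - 1L),
                            substr(record$seq, call$end + 1L, n)),
                     record$topology)
  list(phage = phage, host_restored = host)
}

#' Host recombination state
#'
#' Models the strain background of the lysogeny assays: which Xer
#' recombinases are active. `xerD_complementable` mirrors the observed
#' failure of plasmid-borne xerD to restore integration: unless set, a
#' xerD complementation (see [apply_complementation()]) does not
#' reactivate XerD.
#'
#' @param xerC_active,xerD_active Logical recombinase activity flags.
#' @param xerD_complementable Can xerD activity be restored from a plasmid?
#' @return List of class `host_state`.
#' @export
host_state <- function(xerC_active = TRUE, xerD_active = TRUE,
                       xerD_complementable = FALSE) {
  structure(list(xerC_active = isTRUE(xerC_active),
                 xerD_active = isTRUE(xerD_active),
                 xerD_complementable = isTRUE(xerD_complementable)),
            class = "host_state")
}

#' Apply a plasmid complementation to a host state
#'
#' An induced xerC plasmid restores XerC activity; an induced xerD plasmid
#' restores XerD only when the state is `xerD_complementable`. Uninduced
#' constructs change nothing.
#'
#' @param state A [host_state()].
#' @param gene `"xerC"` or `"xerD"`.
#' @param induced Was expression induced?
#' @return The updated `host_state`.
#' @export
apply_complementation <- function(state, gene = c("xerC", "xerD"),
                                  induced = TRUE) {
  gene <- match.arg(gene)
  if (!induced) return(state)
  if (gene == "xerC") {
    state$xerC_active <- TRUE
  } else if (state$xerD_complementable) {
    state$xerD_active <- TRUE
  }
  state
}

#' Model XerC/XerD-dependent phage integration
#'
#' Integration requires cooperative XerC/XerD binding: it refuses (with a
#' typed reason) unless both host recombinases are active and the phage
#' dif site is phage-like (both arms present, XerC arm within tolerance).
#' On success the phage is linearised at its dif and inserted immediately
#' downstream of the host dif, co-oriented with it; the host dif sequence
#' is unchanged and the phage dif becomes the downstream boundary.
#'
#' @param host One-row linear record with exactly one bacterial-like dif.
#' @param phage One-row circular record.
#' @param state A [host_state()].
#' @param grammar A [dif_grammar()].
#' @param cfg A [miner_config()].
#' @param phage_dif Optional known phage dif annotation: a one-row site
#'   tibble (columns `start`, `end`, `strand`, `seq`) as produced by the
#'   generator or [delete_dif_arm()]; a zero-row tibble means the site is
#'   known absent. `NULL` triggers de novo detection of a phage-like site.
#' @return List of class `goku_integration`: `integrated` flag, `reason`,
#'   and on success `record`, `region`, `host_dif_end`.
#' @export
integrate_phage <- function(host, phage, state = host_state(),
                            grammar = dif_grammar(), cfg = miner_config(),
                            phage_dif = NULL) {
  stopifnot(nrow(host) == 1L, nrow(phage) == 1L)
  if (phage$topology != "circular") abort("phage must be circular")
  refusal <- function(reason) {
    structure(list(integrated = FALSE, reason = reason, record = NULL),
              class = "goku_integration")
  }
  host_sites <- find_dif_sites(host, grammar, max_mm = cfg$bacterial_dif_max_mm)
  host_sites <- host_sites %>% filter(.data$site_class == "bacterial_like") %>%
    distinct(.data$start, .keep_all = TRUE)
  if (nrow(host_sites) != 1L) {
    abort(sprintf("host must carry exactly one bacterial-like dif (found %d)",
                  nrow(host_sites)))
  }
  hsite <- host_sites[1L, ]
  if (is.null(phage_dif)) {
    cand <- find_dif_sites(phage, grammar, max_mm = cfg$phage_dif_max_mm) %>%
      filter(.data$site_class %in% c("phage_like", "bacterial_like"))
    if (nrow(cand) == 0L) {
      phage_dif <- cand
    } else {
      phage_dif <- cand %>% arrange(.data$xerC_mm, .data$total_mm) %>% slice(1L)
    }
  }
  if (nrow(phage_dif) == 0L) return(refusal("no phage dif site"))
  pclass <- classify_dif(phage_dif$seq[1L], grammar, cfg)$site_class
  if (!state$xerC_active) return(refusal("xerC inactive"))
  if (!state$xerD_active) return(refusal("xerD inactive"))
  if (pclass != "phage_like" && pclass != "bacterial_like") {
    return(refusal(sprintf("phage dif not phage_like (%s)", pclass)))
  }
  # orient the phage so its dif reads co-oriented with the bacterial dif
  pseq <- phage$seq
  L <- nchar(pseq)
  ps <- phage_dif$start[1L]; pe_fwd <- phage_dif$end[1L]
  if (!is.null(phage_dif$strand) && phage_dif$strand[1L] == "-") {
    pseq <- revcomp(pseq)
    ps2 <- ((L - (pe_fwd - 1L) %% L - 1L) %% L) + 1L
    ps <- ps2
    pe_fwd <- ps + grammar$total - 1L
  }
  insert <- rotate_seq(pseq, pe_fwd %% L)
  he <- hsite$start + grammar$total - 1L
  if (hsite$strand == "-") {
    # flip the host so its dif reads forward; coordinates follow
    hn <- nchar(host$seq)
    host$seq <- revcomp(host$seq)
    hs <- hn - (hsite$start + grammar$total - 1L) + 1L
    he <- hs + grammar$total - 1L
  }
  product <- paste0(substr(host$seq, 1L, he), insert,
                    substr(host$seq, he + 1L, nchar(host$seq)))
  rec <- seq_record(host$id, product, host$topology)
  structure(list(integrated = TRUE, reason = NA_character_, record = rec,
                 region = c(start = he + 1L, end = he + L),
                 host_dif_end = he),
            class = "goku_integration")
}

#' @export
print.goku_integration <- function(x, ...) {
  if (x$integrated) {
    cat(sprintf("integration: success, prophage at %d-%d\n",
                x$region[["start"]], x$region[["end"]]))
  } else {
    cat(sprintf("integration: refused (%s)\n", x$reason))
  }
  invisible(x)
}

#' Delete an arm of the phage dif site
#'
#' Builds the arm-deletion constructs of the lysogeny assays: removes the
#' XerC-binding arm (`"C"`), the XerD-binding arm (`"D"`) or the entire
#' site (`"CD"`) from the phage genome, and returns the edited record
#' together with the remaining site annotation (zero rows for `"CD"`).
#'
#' @param phage One-row circular record.
#' @param site One-row site tibble (`start`, `end`, `strand`, `seq`) for
#'   the phage dif.
#' @param arm `"C"`, `"D"` or `"CD"`.
#' @param grammar A [dif_grammar()].
#' @return List with `record` and `dif_site`.
#' @export
delete_dif_arm <- function(phage, site, arm = c("C", "D", "CD"),
                           grammar = dif_grammar()) {
  arm <- match.arg(arm)
  stopifnot(nrow(phage) == 1L, nrow(site) == 1L)
  s <- site$start; e <- site$end
  keep <- switch(arm,
    "C" = c(s + grammar$xerC_arm_len, e),
    "D" = c(s, e - grammar$xerD_arm_len),
    "CD" = NULL)
  n <- nchar(phage$seq)
  if (is.null(keep)) {
    new_seq <- paste0(substr(phage$seq, 1L, s - 1L), substr(phage$seq, e + 1L, n))
    rec <- seq_record(phage$id, new_seq, "circular")
    return(list(record = rec, dif_site = goku_truth()$dif_sites[0, 1:5]))
  }
  drop <- if (arm == "C") c(s, keep[1L] - 1L) else c(keep[2L] + 1L, e)
  new_seq <- paste0(substr(phage$seq, 1L, drop[1L] - 1L),
                    substr(phage$seq, drop[2L] + 1L, n))
  rec <- seq_record(phage$id, new_seq, "circular")
  new_start <- if (arm == "C") s else s
  remaining <- substr(phage$seq, keep[1L], keep[2L])
  list(record = rec,
       dif_site = tibble(record_id = phage$id, start = new_start,
                         end = new_start + nchar(remaining) - 1L,
                         strand = site$strand, seq = remaining))
}

#' Mine genomes for dif-flanked prophages end to end
#'
#' Per genome: capsid loci ([find_capsid_loci()]), boundary repeat pairs
#' ([find_flanking_repeats()]) with a PWM fallback when no qualifying exact
#' repeat exists (the conserved XerC arm alone is shorter than the 17 bp
#' seed, so divergent phage difs can defeat the exact-repeat criterion),
#' then prophage calls and excision. Deterministic; every rejection is
#' logged with its reason.
#'
#' @param genomes Record tibble.
#' @param query Capsid query protein.
#' @param grammar A [dif_grammar()].
#' @param cfg A [miner_config()].
#' @param ann_cfg An [annotation_config()].
#' @param references Reference proteins for role assignment.
#' @return Tibble of accepted calls (one row per prophage, with list
#'   columns `upstream_dif`, `downstream_dif`, `genes`, `excised`); the
#'   rejection log is in `attr(, "rejections")`.
#' @export
mine <- function(genomes, query, grammar = dif_grammar(),
                 cfg = miner_config(), ann_cfg = annotation_config(),
                 references = vp_reference_proteins()) {
  pwm <- build_pwm(grammar$canonical, grammar)
  calls <- list(); rejects <- list()
  for (i in seq_len(nrow(genomes))) {
    record <- genomes[i, ]
    loci <- find_capsid_loci(record, query, cfg)
    for (j in seq_len(nrow(loci))) {
      locus <- loci[j, ]
      pairs <- find_flanking_repeats(record, locus, cfg)
      if (nrow(pairs) == 0L) {
        pairs <- pwm_fallback_pair(record, locus, grammar, cfg, pwm)
      }
      accepted <- FALSE
      for (p in seq_len(nrow(pairs))) {
        call <- call_prophage(record, locus, pairs[p, ], grammar, cfg,
                              ann_cfg, references, pwm)
        if (call$status == "ok") {
          calls[[length(calls) + 1L]] <- call
          accepted <- TRUE
          break
        }
        rejects[[length(rejects) + 1L]] <-
          tibble(host_id = record$id, locus_start = locus$start,
                 pair = p, reason = call$reason)
      }
      if (!accepted && nrow(pairs) == 0L) {
        rejects[[length(rejects) + 1L]] <-
          tibble(host_id = record$id, locus_start = locus$start,
                 pair = NA_integer_, reason = "no boundary pair found")
      }
    }
  }
  out <- if (length(calls)) {
    list_rbind(map(calls, function(cl) {
      tidy(cl) %>% mutate(upstream_dif = list(cl$upstream_dif),
                          downstream_dif = list(cl$downstream_dif),
                          genes = list(cl$genes), excised = list(cl$excised))
    }))
  } else {
    tibble(host_id = character(), status = character(), start = integer(),
           end = integer(), length = integer(), upstream_class = character(),
           downstream_class = character(), n_genes = integer(),
           upstream_dif = list(), downstream_dif = list(), genes = list(),
           excised = list())
  }
  attr(out, "rejections") <- if (length(rejects)) list_rbind(rejects) else
    tibble(host_id = character(), locus_start = integer(), pair = integer(),
           reason = character())
  out
}

# PWM fallback: pair the best-scoring dif window in each flank
pwm_fallback_pair <- function(record, locus, grammar, cfg, pwm) {
  n <- nchar(record$seq)
  w <- grammar$total
  up_lo <- max(1L, locus$start - cfg$flank_len)
  dn_hi <- min(n, locus$end + cfg$flank_len)
  up_region <- substr(record$seq, up_lo, locus$start - 1L)
  dn_region <- substr(record$seq, locus$end + 1L, dn_hi)
  if (nchar(up_region) < w || nchar(dn_region) < w) return(empty_pairs())
  up_sc <- pwm_window_scores(up_region, pwm)
  dn_sc <- pwm_window_scores(dn_region, pwm)
  u <- up_lo + which.max(up_sc) - 1L
  d <- locus$end + which.max(dn_sc)
  tibble(up_start = u, up_end = u + w - 1L, down_start = d,
         down_end = d + w - 1L, length = w)
}
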