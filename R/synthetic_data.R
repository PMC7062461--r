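#' Simulation configuration
#'
#' Study conditions for the synthetic generator: host chromosomes carrying a
#' single dif site; circular phage genomes of 4047-4692 bp with the
#' conserved six-gene arrangement VP4, VP5, VP3, VP1, VP2, VP8; a phage dif
#' built as the canonical XerC arm plus a spacer/XerD arm mutated at
#' per-base rate 0.3; and MAG sets with planted dif-like motifs and decoy
#' near-motifs for recovery testing.
#'
#' @param seed Integer seed; every sampling decision flows from it.
#' @param host_len Host chromosome length in bp.
#' @param phage_len_range Two-element range of phage genome lengths in bp.
#' @param gene_order Roles in genomic order.
#' @param phage_dif_spacer_mut Per-base substitution probability applied to
#'   the spacer and XerD arm of the phage dif.
#' @param bacterial_dif_mut_max Maximum substitutions of the planted host
#'   dif from canonical.
#' @param mag_count Number of MAGs per set.
#' @param decoy_repeat_count Decoy near-motifs (10-14 bp identity to
#'   canonical) scattered over the MAG set.
#' @param coding_plant_fraction Fraction of planted MAG motifs placed in
#'   coding context (split between the VP4 N-terminus and mid-gene).
#' @param mag_plant_fraction Fraction of MAGs that carry a planted motif.
#' @param gc GC content of background sequence.
#' @param dif_gap_after Gene after whose 3' intergenic gap the phage dif is
#'   placed (the VP2-VP8 non-coding region by default).
#' @param grammar A [dif_grammar()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, host_len = 100000L,
                       phage_len_range = c(4047L, 4692L),
                       gene_order = c("VP4", "VP5", "VP3", "VP1", "VP2", "VP8"),
                       phage_dif_spacer_mut = 0.3,
                       bacterial_dif_mut_max = 1L,
                       mag_count = 12L, decoy_repeat_count = 5L,
                       coding_plant_fraction = 0.4,
                       mag_plant_fraction = 0.75,
                       gc = 0.5, dif_gap_after = "VP2",
                       grammar = dif_grammar()) {
  stopifnot(phage_len_range[1] >= 3500L, phage_len_range[2] <= 6000L,
            phage_len_range[1] <= phage_len_range[2],
            phage_dif_spacer_mut >= 0, phage_dif_spacer_mut <= 1,
            gc > 0, gc < 1,
            mag_plant_fraction >= 0, mag_plant_fraction <= 1)
  if (coding_plant_fraction < 0 || coding_plant_fraction > 1) {
    abort("coding_plant_fraction out of [0,1]")
  }
  if (host_len < 10L * grammar$total) abort("host_len too small for a dif site")
  structure(list(seed = as.integer(seed), host_len = as.integer(host_len),
                 phage_len_range = as.integer(phage_len_range),
                 gene_order = gene_order,
                 phage_dif_spacer_mut = phage_dif_spacer_mut,
                 bacterial_dif_mut_max = as.integer(bacterial_dif_mut_max),
                 mag_count = as.integer(mag_count),
                 decoy_repeat_count = as.integer(decoy_repeat_count),
                 coding_plant_fraction = coding_plant_fraction,
                 mag_plant_fraction = mag_plant_fraction,
                 gc = gc, dif_gap_after = dif_gap_after, grammar = grammar),
            class = "sim_config")
}

base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             T = (1 - gc) / 2)

# distinct RNG streams per generator operation, so a host and a phage built
# from the same configuration seed are independent
op_seed <- function(seed, op) {
  k <- match(op, c("host", "phage", "mags"))
  (as.double(seed) * 4 + k) %% 2147483647
}

random_seq <- function(n, gc) {
  paste(sample(names(base_probs(gc)), n, replace = TRUE,
               prob = base_probs(gc)), collapse = "")
}

# exactly k substitutions at distinct positions
mutate_k <- function(seq, k) {
  if (k == 0L) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

# per-base substitution at given rate
mutate_rate <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (p in hit) chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  paste(chars, collapse = "")
}

CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

# codons whose reverse complement is a stop codon; favouring them keeps the
# antisense strand stop-rich, as in real coding sequence
ANTISENSE_STOP_CODONS <- c("TTA", "CTA", "TCA")

back_translate <- function(aa) {
  codons <- vapply(strsplit(aa, "")[[1L]], function(a) {
    opts <- CODONS_BY_AA[[a]]
    wts <- ifelse(opts %in% ANTISENSE_STOP_CODONS, 4, 1)
    sample(opts, 1L, prob = wts)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Empty ground-truth container
#'
#' The generator's record of every planted feature, used as the oracle for
#' recovery tests: dif sites, gene calls, prophage intervals, MAG motif
#' positions with context labels, and decoy repeats.
#'
#' @return List of class `goku_truth` holding five tibbles.
#' @export
goku_truth <- function() {
  structure(list(
    dif_sites = tibble(record_id = character(), start = integer(),
                       end = integer(), strand = character(), seq = character(),
                       type = character()),
    genes = tibble(record_id = character(), start = integer(), end = integer(),
                   strand = character(), role = character(), seq = character()),
    prophages = tibble(record_id = character(), start = integer(),
                       end = integer()),
    mag_motifs = tibble(record_id = character(), start = integer(),
                        end = integer(), strand = character(), seq = character(),
                        context = character()),
    decoys = tibble(record_id = character(), start = integer(), end = integer(),
                    seq = character(), identity = integer())),
    class = "goku_truth")
}

merge_truth <- function(...) {
  parts <- list(...)
  out <- goku_truth()
  for (nm in names(out)) out[[nm]] <- list_rbind(map(parts, nm))
  out
}

#' Check the ground-truth re-extraction invariant
#'
#' Every planted feature's sequence, re-extracted from the emitted records
#' at the recorded coordinates, must equal the recorded sequence.
#'
#' @param records Record tibble.
#' @param truth A `goku_truth`.
#' @return `TRUE` if every feature verifies, else `FALSE`.
#' @export
verify_truth <- function(records, truth) {
  get_rec <- function(id) records[records$id == id, , drop = FALSE]
  check_tbl <- function(tbl, stranded = TRUE) {
    if (nrow(tbl) == 0L) return(TRUE)
    all(map_lgl2(seq_len(nrow(tbl)), function(i) {
      rec <- get_rec(tbl$record_id[i])
      if (nrow(rec) != 1L) return(FALSE)
      s <- circular_slice(rec, tbl$start[i], tbl$end[i])
      if (stranded && tbl$strand[i] == "-") s <- revcomp(s)
      identical(s, tbl$seq[i])
    }))
  }
  check_tbl(truth$dif_sites) && check_tbl(truth$genes) &&
    check_tbl(truth$mag_motifs) && check_tbl(truth$decoys, stranded = FALSE)
}

#' Simulate a host chromosome with a single dif site
#'
#' Draws an i.i.d. background at the configured GC content and plants one
#' dif site (at most `bacterial_dif_mut_max` substitutions from canonical)
#' in the central part of the chromosome. The background is
#' rejection-sampled so that no 17-mer of the planted site recurs anywhere
#' else on either strand, keeping the planted boundary signal unique.
#'
#' @param cfg A [sim_config()].
#' @param id Record id.
#' @return List with `record` (one-row tibble) and `truth` (`goku_truth`).
#' @export
make_host <- function(cfg, id = paste0("host_s", cfg$seed)) {
  g <- cfg$grammar
  withr::with_seed(op_seed(cfg$seed, "host"), {
    k <- sample(0:cfg$bacterial_dif_mut_max, 1L)
    dif <- mutate_k(g$canonical, k)
    pos <- sample(seq.int(floor(0.3 * cfg$host_len),
                          floor(0.7 * cfg$host_len)), 1L)
    repeat {
      bg <- random_seq(cfg$host_len, cfg$gc)
      host <- paste0(substr(bg, 1L, pos - 1L), dif,
                     substr(bg, pos + g$total, cfg$host_len))
      if (dif_kmers_unique(host, dif, pos)) break
    }
  })
  record <- seq_record(id, host, "linear")
  truth <- goku_truth()
  truth$dif_sites <- tibble(record_id = id, start = as.integer(pos),
                            end = as.integer(pos + g$total - 1L), strand = "+",
                            seq = dif, type = "bacterial")
  list(record = record, truth = truth)
}

dif_kmers_unique <- function(host, dif, pos, k = 17L) {
  rc <- revcomp(host)
  for (off in seq_len(nchar(dif) - k + 1L)) {
    kmer <- substr(dif, off, off + k - 1L)
    f <- gregexpr(kmer, host, fixed = TRUE)[[1L]]
    r <- gregexpr(kmer, rc, fixed = TRUE)[[1L]]
    n_f <- sum(f > 0L); n_r <- sum(r > 0L)
    if (n_f + n_r != 1L) return(FALSE)
  }
  TRUE
}

# shared phage/MAG genome builder; returns seq, genes, gaps, dif (or NULL)
build_phage_genome <- function(cfg, with_dif = TRUE) {
  g <- cfg$grammar
  refs <- vp_reference_proteins()[cfg$gene_order]
  repeat {
    L <- sample(seq.int(cfg$phage_len_range[1], cfg$phage_len_range[2]), 1L)
    gene_nt <- map_chr(refs, back_translate)
    C <- sum(nchar(gene_nt))
    k <- length(gene_nt)
    dif_gap <- match(cfg$dif_gap_after, cfg$gene_order)
    if (is.na(dif_gap)) dif_gap <- k
    base <- rep(20L, k)
    reserve <- if (with_dif) g$total + 12L else 0L
    extra_total <- L - C - sum(base) - reserve
    if (extra_total < 0L) abort("gene lengths incompatible with genome length")
    extra <- as.vector(stats::rmultinom(1L, extra_total, rep(1 / k, k)))
    gaps_len <- base + extra
    if (with_dif) gaps_len[dif_gap] <- gaps_len[dif_gap] + reserve
    pos <- 1L
    genes <- list(); gaps <- list(); seq_parts <- character(0)
    dif_site <- NULL
    for (i in seq_len(k)) {
      len <- nchar(gene_nt[[i]])
      genes[[i]] <- tibble(start = pos, end = pos + len - 1L, strand = "+",
                           role = cfg$gene_order[i], seq = gene_nt[[i]])
      seq_parts <- c(seq_parts, gene_nt[[i]])
      pos <- pos + len
      gap_seq <- random_seq(gaps_len[i], cfg$gc)
      # in-frame stop just before the next gene so ORFs cannot extend
      # upstream of the planted start codon
      substr(gap_seq, gaps_len[i] - 2L, gaps_len[i]) <- sample(STOP_CODONS, 1L)
      if (with_dif && i == dif_gap) {
        dif_seq <- phage_dif_seq(cfg)
        off <- sample(seq.int(4L, gaps_len[i] - g$total - 3L), 1L)
        substr(gap_seq, off, off + g$total - 1L) <- dif_seq
        dif_site <- tibble(start = pos + off - 1L,
                           end = pos + off + g$total - 2L,
                           strand = "+", seq = dif_seq, type = "phage")
      }
      gaps[[i]] <- tibble(start = pos, end = pos + gaps_len[i] - 1L,
                          after = cfg$gene_order[i])
      seq_parts <- c(seq_parts, gap_seq)
      pos <- pos + gaps_len[i]
    }
    seq <- paste(seq_parts, collapse = "")
    stopifnot(nchar(seq) == L)
    rec <- seq_record("tmp", seq, "circular")
    # uniqueness guards: no stray bacterial-like site; if a dif was planted,
    # the exact-XerC-arm site must be unique
    bact <- find_dif_sites(rec, g, max_mm = cfg$bacterial_dif_mut_max)
    if (with_dif && !is.null(dif_site)) {
      bact <- bact[!(bact$start == dif_site$start & bact$strand == "+"), ,
                   drop = FALSE]
    }
    if (nrow(bact) > 0L) next
    arm_sites <- find_dif_sites(rec, g, max_mm = 13L, exact_xerC_arm = TRUE)
    if (with_dif) {
      if (nrow(arm_sites) != 1L || arm_sites$start[1L] != dif_site$start) next
    } else if (nrow(arm_sites) != 0L) {
      next
    }
    gene_tbl <- list_rbind(genes)
    # the architecture must be recoverable: every planted gene called at its
    # exact coordinates by the constrained ORF caller
    called <- find_orfs(rec)
    key <- paste(called$start, called$end, called$strand)
    if (!all(paste(gene_tbl$start, gene_tbl$end, gene_tbl$strand) %in% key)) next
    return(list(seq = seq, genes = gene_tbl, gaps = list_rbind(gaps),
                dif = dif_site, called = called))
  }
}

# canonical XerC arm + spacer/XerD mutated at the configured rate, kept
# within the >=15-identical-bases grammar of recognisable dif motifs while
# staying distinguishable from the (near-canonical) bacterial site
phage_dif_seq <- function(cfg, min_identity = 15L) {
  g <- cfg$grammar
  arm <- substr(g$canonical, 1L, g$xerC_arm_len)
  rest <- substr(g$canonical, g$xerC_arm_len + 1L, g$total)
  if (cfg$phage_dif_spacer_mut == 0) return(g$canonical)
  repeat {
    cand <- paste0(arm, mutate_rate(rest, cfg$phage_dif_spacer_mut))
    mm <- hamming(cand, g$canonical)
    if (g$total - mm >= min_identity && mm > cfg$bacterial_dif_mut_max) {
      return(cand)
    }
  }
}

#' Simulate a circular phage genome
#'
#' Builds a circular genome of length uniform in `phage_len_range` carrying
#' six non-overlapping ORFs in the configured order (each opened with a
#' start codon, closed with a stop, free of internal in-frame stops), and a
#' single phage dif site in the VP2-VP8 intergenic analogue: canonical XerC
#' arm plus spacer/XerD arm mutated at the configured rate.
#'
#' @param cfg A [sim_config()].
#' @param id Record id.
#' @return List with `record` (circular) and `truth`.
#' @export
make_phage <- function(cfg, id = paste0("phage_s", cfg$seed)) {
  built <- withr::with_seed(op_seed(cfg$seed, "phage"),
                            build_phage_genome(cfg, with_dif = TRUE))
  record <- seq_record(id, built$seq, "circular")
  truth <- goku_truth()
  truth$genes <- built$genes %>% mutate(record_id = id, .before = 1L)
  truth$dif_sites <- built$dif %>% mutate(record_id = id, .before = 1L)
  list(record = record, truth = truth)
}

#' Plant a phage integration into a host chromosome
#'
#' Delegates the insertion arithmetic to [integrate()] under a wild-type
#' host state, then updates the ground truth: prophage interval, both dif
#' sites (upstream bacterial, downstream phage) and the phage genes mapped
#' into host coordinates.
#'
#' @param host,phage One-row record tibbles (host linear with one recorded
#'   dif, phage circular with one recorded dif).
#' @param truth Merged `goku_truth` covering both records.
#' @param grammar A [dif_grammar()].
#' @param cfg A [miner_config()].
#' @return List with `record` (integrated host) and `truth`.
#' @export
plant_integration <- function(host, phage, truth, grammar = dif_grammar(),
                              cfg = miner_config()) {
  phage_dif <- truth$dif_sites %>%
    filter(.data$record_id == phage$id, .data$type == "phage")
  stopifnot(nrow(phage_dif) == 1L)
  res <- integrate_phage(host, phage, host_state(), grammar, cfg,
                         phage_dif = phage_dif)
  if (!res$integrated) abort(paste("integration refused:", res$reason))
  L <- nchar(phage$seq)
  he <- res$host_dif_end
  pe <- phage_dif$end
  remap <- function(p) he + ((p - pe - 1L) %% L) + 1L
  new_truth <- goku_truth()
  host_dif <- truth$dif_sites %>%
    filter(.data$record_id == host$id, .data$type == "bacterial")
  phage_genes <- truth$genes %>% filter(.data$record_id == phage$id)
  new_truth$dif_sites <- bind_rows(
    host_dif,
    tibble(record_id = host$id, start = he + L - nchar(phage_dif$seq) + 1L,
           end = he + L, strand = "+", seq = phage_dif$seq, type = "phage"))
  if (nrow(phage_genes)) {
    ns <- as.integer(vapply(phage_genes$start, remap, numeric(1)))
    lens <- phage_genes$end - phage_genes$start
    new_truth$genes <- phage_genes %>%
      mutate(record_id = host$id, start = ns, end = ns + lens)
  }
  new_truth$prophages <- tibble(record_id = host$id, start = he + 1L,
                                end = he + L)
  keep <- truth
  for (nm in names(keep)) {
    keep[[nm]] <- keep[[nm]] %>% filter(!.data$record_id %in% c(host$id, phage$id))
  }
  list(record = res$record, truth = merge_truth(keep, new_truth))
}

#' Simulate a set of metagenome-assembled phage genomes
#'
#' Generates circular MAGs with synthetic gene complements. A configured
#' fraction carries one planted dif-like motif in a non-coding gap, within
#' the first 90 bp of the VP4 analogue, or mid-gene (a negative control the
#' coding-context filter must remove); coding plants never introduce
#' in-frame stops. Decoy near-motifs with 10-14 bp identity to canonical
#' are scattered over non-coding gaps.
#'
#' @param cfg A [sim_config()].
#' @param id_prefix Record id prefix.
#' @return List with `records` (tibble of circular MAGs) and `truth`.
#' @export
make_mag_set <- function(cfg, id_prefix = paste0("mag_s", cfg$seed, "_")) {
  g <- cfg$grammar
  withr::with_seed(op_seed(cfg$seed, "mags"), {
    n <- cfg$mag_count
    planted <- stats::runif(n) < cfg$mag_plant_fraction
    contexts <- map_chr(seq_len(n), function(i) {
      if (!planted[i]) return(NA_character_)
      if (stats::runif(1) < cfg$coding_plant_fraction) {
        sample(c("coding_VP4_Nterm", "coding_internal"), 1L)
      } else "non_coding"
    })
    mags <- list(); truths <- list()
    free_gaps <- list()
    for (i in seq_len(n)) {
      id <- sprintf("%s%02d", id_prefix, i)
      repeat {
        built <- build_phage_genome(cfg, with_dif = FALSE)
        seq <- built$seq
        used_gaps <- integer(0)
        plant <- NULL
        if (planted[i]) {
          plant <- plant_mag_motif(seq, built, contexts[i], cfg)
          seq <- plant$seq
          used_gaps <- plant$used_gap
          # the planted context must be what the annotation layer reports
          if (!mag_plant_consistent(seq, built, plant, contexts[i], cfg)) next
        }
        break
      }
      tr <- goku_truth()
      tr$genes <- built$genes %>% mutate(record_id = id, .before = 1L)
      if (!is.null(plant)) {
        # coding plants rewrite part of the gene body; record the final seq
        tr$genes$seq <- map_chr(seq_len(nrow(tr$genes)), function(k) {
          substr(seq, tr$genes$start[k], tr$genes$end[k])
        })
        tr$mag_motifs <- tibble(record_id = id, start = plant$start,
                                end = plant$end, strand = "+",
                                seq = plant$motif, context = contexts[i])
      }
      mags[[i]] <- list(id = id, seq = seq)
      truths[[i]] <- tr
      roomy <- which(built$gaps$end - built$gaps$start + 1L >= g$total + 6L)
      free_gaps[[i]] <- built$gaps[setdiff(roomy, used_gaps), , drop = FALSE]
    }
    # scatter decoys over unused roomy gaps; a decoy must stay below the
    # identity-rescue threshold against canonical AND every planted motif,
    # since planted motifs join the confirmed set during iterative search
    planted_motifs <- map(truths, function(tr) tr$mag_motifs$seq) %>%
      unlist(use.names = FALSE)
    decoy_rows <- list()
    if (cfg$decoy_repeat_count > 0L) {
      pool <- imap(free_gaps, function(gp, i) {
        if (nrow(gp)) mutate(gp, mag = i) else NULL
      }) %>% list_rbind()
      take <- pool[sample(nrow(pool), min(cfg$decoy_repeat_count, nrow(pool))), ]
      for (j in seq_len(nrow(take))) {
        repeat {
          ident <- sample(10:14, 1L)
          decoy <- mutate_k(g$canonical, g$total - ident)
          # scanning is strand-symmetric: both orientations must stay below
          # the rescue threshold against every motif that can be confirmed
          refs <- c(g$canonical, planted_motifs)
          both <- c(decoy, revcomp(decoy))
          worst <- max(vapply(refs, function(mm) {
            max(vapply(both, function(dd) g$total - hamming(dd, mm),
                       numeric(1)))
          }, numeric(1)))
          if (worst <= 14L) break
        }
        gp <- take[j, ]
        off <- sample(seq.int(3L, (gp$end - gp$start + 1L) - g$total - 2L), 1L)
        s <- gp$start + off - 1L
        substr(mags[[gp$mag]]$seq, s, s + g$total - 1L) <- decoy
        decoy_rows[[j]] <- tibble(record_id = mags[[gp$mag]]$id, start = s,
                                  end = s + g$total - 1L, seq = decoy,
                                  identity = ident)
      }
    }
    records <- seq_record(map_chr(mags, "id"), map_chr(mags, "seq"), "circular")
    truth <- do.call(merge_truth, truths)
    truth$decoys <- list_rbind(decoy_rows)
    if (is.null(truth$decoys) || nrow(truth$decoys) == 0L) truth$decoys <- goku_truth()$decoys
    list(records = records, truth = truth)
  })
}

# after planting, the constrained ORF caller must still recover every gene
# exactly and classify the planted interval as intended
mag_plant_consistent <- function(seq, built, plant, context, cfg) {
  rec <- seq_record("tmp", seq, "circular")
  called <- find_orfs(rec)
  key <- paste(called$start, called$end, called$strand)
  if (!all(paste(built$genes$start, built$genes$end, built$genes$strand) %in% key)) {
    return(FALSE)
  }
  # transfer true roles onto the matching calls; other calls stay unknown
  truth_key <- paste(built$genes$start, built$genes$end, built$genes$strand)
  idx <- match(key, truth_key)
  called$role <- ifelse(is.na(idx), "unknown", built$genes$role[idx])
  ctx <- coding_context(plant$start, plant$end, called,
                        record_len = nchar(seq))
  identical(ctx, context)
}

# place one dif-like motif in the requested context; in-frame stops are
# rejection-sampled away for coding plants
plant_mag_motif <- function(seq, built, context, cfg) {
  g <- cfg$grammar
  w <- g$total
  if (context == "non_coding") {
    roomy <- which(built$gaps$end - built$gaps$start + 1L >= w + 6L)
    gi <- sample(roomy, 1L)
    gp <- built$gaps[gi, ]
    motif <- phage_dif_seq(cfg)
    off <- sample(seq.int(3L, (gp$end - gp$start + 1L) - w - 2L), 1L)
    s <- gp$start + off - 1L
    substr(seq, s, s + w - 1L) <- motif
    return(list(seq = seq, start = s, end = s + w - 1L, motif = motif,
                used_gap = gi))
  }
  ntw <- 90L
  target_role <- if (context == "coding_VP4_Nterm") "VP4" else "VP1"
  gene <- built$genes[built$genes$role == target_role, ][1L, ]
  glen <- gene$end - gene$start + 1L
  offsets <- if (context == "coding_VP4_Nterm") {
    seq.int(4L, ntw - w + 1L)
  } else {
    seq.int(ntw + 2L, glen - ntw - w)
  }
  for (attempt in seq_len(200L)) {
    motif <- phage_dif_seq(cfg)
    off <- sample(offsets, 1L)
    new_gene <- gene$seq
    substr(new_gene, off, off + w - 1L) <- motif
    aa <- translate_orf(new_gene)
    if (!grepl("*", aa, fixed = TRUE)) {
      s <- gene$start + off - 1L
      substr(seq, s, s + w - 1L) <- motif
      return(list(seq = seq, start = s, end = s + w - 1L, motif = motif,
                  used_gap = integer(0)))
    }
  }
  abort("could not place coding motif without an in-frame stop")
}
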