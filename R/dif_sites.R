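#' Miner configuration
#'
#' Parameters for prophage locus finding and boundary detection: the 5 kb
#' flank windows searched either side of the capsid locus, the 17 bp exact
#' repeat seed, the capsid alignment score threshold (calibrated on null
#' simulations, see the methods vignette), and the dif classification
#' tolerances (upstream bacterial-type sites differ from canonical by at
#' most one base; phage-type sites keep a near-intact XerC arm).
#'
#' @param flank_len Window size (bp) searched up/downstream of a capsid locus.
#' @param repeat_seed_len Exact-repeat seed length in bp.
#' @param capsid_score_min Minimum local-alignment score (BLOSUM62) to accept
#'   a capsid locus.
#' @param bacterial_dif_max_mm Max total mismatches for a bacterial-like site.
#' @param xerC_arm_max_mm Max XerC-arm mismatches for a phage-like site.
#' @param phage_dif_max_mm Max total mismatches for a phage-like site (keeps
#'   random arm-only matches from classifying as sites).
#' @return List of class `miner_config`.
#' @export
miner_config <- function(flank_len = 5000L, repeat_seed_len = 17L,
                         capsid_score_min = 125, bacterial_dif_max_mm = 1L,
                         xerC_arm_max_mm = 2L, phage_dif_max_mm = 13L) {
  structure(list(flank_len = as.integer(flank_len),
                 repeat_seed_len = as.integer(repeat_seed_len),
                 capsid_score_min = capsid_score_min,
                 bacterial_dif_max_mm = as.integer(bacterial_dif_max_mm),
                 xerC_arm_max_mm = as.integer(xerC_arm_max_mm),
                 phage_dif_max_mm = as.integer(phage_dif_max_mm)),
            class = "miner_config")
}

split_dif_components <- function(seq, grammar) {
  c1 <- grammar$xerC_arm_len
  c2 <- c1 + grammar$spacer_len
  list(xerC = substr(seq, 1L, c1),
       spacer = substr(seq, c1 + 1L, c2),
       xerD = substr(seq, c2 + 1L, grammar$total))
}

#' Classify a candidate dif site against the grammar
#'
#' Computes per-component Hamming mismatch counts against the canonical
#' site and assigns a class: `bacterial_like` when the whole site differs
#' by at most `bacterial_dif_max_mm` bases (the "at most one nucleotide"
#' rule at the default), `phage_like` when the XerC arm is
#' within tolerance and both arms are present, `partial_C_missing` /
#' `partial_D_missing` for arm-deletion constructs (sequence shortened by
#' the respective arm), else `non_site`.
#'
#' @param seq Candidate sequence. Full grammar length for intact sites; a
#'   site lacking one arm is recognised by its reduced length.
#' @param grammar A [dif_grammar()].
#' @param cfg A [miner_config()].
#' @return One-row tibble: `seq`, `xerC_mm`, `spacer_mm`, `xerD_mm`,
#'   `total_mm`, `site_class`.
#' @export
#' @examples
#' g <- dif_grammar()
#' classify_dif(g$canonical, g)$site_class # "bacterial_like"
classify_dif <- function(seq, grammar = dif_grammar(), cfg = miner_config()) {
  seq <- normalize_seq(seq)
  comp <- split_dif_components(grammar$canonical, grammar)
  n <- nchar(seq)
  len_C_missing <- grammar$spacer_len + grammar$xerD_arm_len
  len_D_missing <- grammar$xerC_arm_len + grammar$spacer_len
  if (n == len_C_missing || n == len_D_missing) {
    # arm-deletion remnant; if both remnant lengths coincide (they do for
    # the default 11/6/11 grammar), decide by which hypothesis fits better
    mm_as_C_missing <- if (n == len_C_missing) {
      hamming(seq, paste0(comp$spacer, comp$xerD))
    } else Inf
    mm_as_D_missing <- if (n == len_D_missing) {
      hamming(seq, paste0(comp$xerC, comp$spacer))
    } else Inf
    if (mm_as_C_missing <= mm_as_D_missing) {
      return(tibble(seq = seq, xerC_mm = NA_integer_,
                    spacer_mm = hamming(substr(seq, 1L, grammar$spacer_len), comp$spacer),
                    xerD_mm = hamming(substr(seq, grammar$spacer_len + 1L, n), comp$xerD),
                    total_mm = NA_integer_, site_class = "partial_C_missing"))
    }
    return(tibble(seq = seq,
                  xerC_mm = hamming(substr(seq, 1L, grammar$xerC_arm_len), comp$xerC),
                  spacer_mm = hamming(substr(seq, grammar$xerC_arm_len + 1L, n), comp$spacer),
                  xerD_mm = NA_integer_,
                  total_mm = NA_integer_, site_class = "partial_D_missing"))
  }
  if (n != grammar$total) {
    if (n < grammar$spacer_len) {
      return(tibble(seq = seq, xerC_mm = NA_integer_, spacer_mm = NA_integer_,
                    xerD_mm = NA_integer_, total_mm = NA_integer_,
                    site_class = "non_site"))
    }
    abort(sprintf("candidate length %d does not match grammar total %d (or an arm-deleted form)",
                  n, grammar$total))
  }
  sc <- split_dif_components(seq, grammar)
  xc <- hamming(sc$xerC, comp$xerC)
  sp <- hamming(sc$spacer, comp$spacer)
  xd <- hamming(sc$xerD, comp$xerD)
  tot <- xc + sp + xd
  cls <- if (tot <= cfg$bacterial_dif_max_mm) {
    "bacterial_like"
  } else if (xc <= cfg$xerC_arm_max_mm && tot <= cfg$phage_dif_max_mm) {
    "phage_like"
  } else {
    "non_site"
  }
  tibble(seq = seq, xerC_mm = xc, spacer_mm = sp, xerD_mm = xd,
         total_mm = tot, site_class = cls)
}

# classified dif site with location, as one-row tibble
dif_site_at <- function(record, start, grammar, cfg = miner_config(),
                        strand = "+") {
  seq <- circular_slice(record, start, start + grammar$total - 1L)
  if (strand == "-") seq <- revcomp(seq)
  site <- classify_dif(seq, grammar, cfg)
  site$record_id <- record$id
  site$start <- as.integer(start)
  site$end <- as.integer(start + grammar$total - 1L)
  site$strand <- strand
  site[, c("record_id", "start", "end", "strand", "seq",
           "xerC_mm", "spacer_mm", "xerD_mm", "total_mm", "site_class")]
}

#' Locate dif-grammar sites in a record by mismatch criteria
#'
#' Slides the grammar window over both strands (wrapping the origin on
#' circular records) and reports windows whose total mismatch count against
#' the canonical site is within `max_mm`, or — when `exact_xerC_arm` — whose
#' XerC arm matches the canonical arm exactly and whose total mismatches are
#' within `max_mm`. Used to count bacterial- and phage-type sites in
#' simulated and excised genomes.
#'
#' @param record One-row record tibble.
#' @param grammar A [dif_grammar()].
#' @param max_mm Maximum total mismatches.
#' @param exact_xerC_arm Require a mismatch-free XerC arm.
#' @return Tibble of sites (`start`, `end`, `strand`, `seq`, mismatch
#'   columns, `site_class`), forward-strand coordinates.
#' @export
find_dif_sites <- function(record, grammar = dif_grammar(), max_mm = 1L,
                           exact_xerC_arm = FALSE) {
  stopifnot(nrow(record) == 1L)
  w <- grammar$total
  n <- nchar(record$seq)
  scan_one <- function(seq, strand) {
    ext <- if (record$topology == "circular") paste0(seq, substr(seq, 1L, w - 1L)) else seq
    tot <- hamming_windows(ext, grammar$canonical)
    arm <- hamming_windows(ext, substr(grammar$canonical, 1L, grammar$xerC_arm_len))
    arm <- arm[seq_along(tot)]
    keep <- if (exact_xerC_arm) which(arm == 0L & tot <= max_mm) else which(tot <= max_mm)
    keep <- keep[keep <= n]
    if (!length(keep)) return(NULL)
    list_rbind(map(keep, function(p) {
      site_seq <- substr(ext, p, p + w - 1L)
      site <- classify_dif(site_seq, grammar)
      if (strand == "+") {
        site$start <- p
      } else {
        # map window on revcomp back to forward coordinates (mod n for wraps)
        site$start <- ((n - (p + w - 1L)) %% n) + 1L
      }
      site$end <- site$start + w - 1L
      site$strand <- strand
      site
    }))
  }
  res <- bind_rows(scan_one(record$seq, "+"), scan_one(revcomp(record$seq), "-"))
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  seq = character(), xerC_mm = integer(), spacer_mm = integer(),
                  xerD_mm = integer(), total_mm = integer(), site_class = character()))
  }
  res %>% arrange(.data$start, .data$strand) %>%
    select("start", "end", "strand", "seq", "xerC_mm", "spacer_mm",
           "xerD_mm", "total_mm", "site_class")
}
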