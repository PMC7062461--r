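#' Annotation configuration
#'
#' Constraints for the simplified ORF caller: minimum gene length of 110 bp
#' (stop codon included) and maximum overlap of 50 bp between accepted
#' calls, with standard bacterial start codons. `n_term_window` quantifies
#' the gene "N-terminus" used by the dif coding-context filter: the first
#' 90 bp of a gene, wide enough to contain a 28-bp site just downstream of
#' a start codon.
#'
#' @param min_gene_len Minimum ORF length in bp, including the stop codon.
#' @param max_overlap Maximum overlap in bp tolerated between accepted calls.
#' @param start_codons Allowed start codons.
#' @param n_term_window N-terminal window in bp for context classification.
#' @param min_role_score Minimum local protein-alignment score (BLOSUM62)
#'   for a role assignment.
#' @return List of class `annotation_config`.
#' @export
annotation_config <- function(min_gene_len = 110L, max_overlap = 50L,
                              start_codons = c("ATG", "GTG", "TTG"),
                              n_term_window = 90L, min_role_score = 50) {
  stopifnot(min_gene_len > 9L, max_overlap < min_gene_len)
  structure(list(min_gene_len = as.integer(min_gene_len),
                 max_overlap = as.integer(max_overlap),
                 start_codons = start_codons,
                 n_term_window = as.integer(n_term_window),
                 min_role_score = min_role_score),
            class = "annotation_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# enumerate all start->stop ORFs (no internal in-frame stop) on one strand of
# a working sequence; returns working-strand coordinates
enumerate_orfs_strand <- function(work, n, circular, cfg) {
  res <- list()
  limit <- nchar(work)
  for (f in 0:2) {
    starts_at <- seq.int(f + 1L, limit - 2L, by = 3L)
    codons <- substring(work, starts_at, starts_at + 2L)
    is_start <- codons %in% cfg$start_codons
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    prev_stop <- 0L
    for (si in stop_idx) {
      cand <- which(is_start & seq_along(codons) > prev_stop & seq_along(codons) < si)
      for (ci in cand) {
        s <- starts_at[ci]
        e <- starts_at[si] + 2L
        len <- e - s + 1L
        if (len < cfg$min_gene_len) next
        if (circular && (len > n || s > n)) next
        if (!circular && e > n) next
        res[[length(res) + 1L]] <- c(s, e, f)
      }
      prev_stop <- si
    }
  }
  if (!length(res)) {
    return(tibble(start = integer(), end = integer(), frame = integer()))
  }
  m <- do.call(rbind, res)
  tibble(start = m[, 1], end = m[, 2], frame = m[, 3])
}

interval_overlap <- function(s1, e1, s2, e2, n = NULL) {
  ov <- function(a, b, c, d) pmax(0L, pmin(b, d) - pmax(a, c) + 1L)
  out <- ov(s1, e1, s2, e2)
  if (!is.null(n)) {
    out <- pmax(out, ov(s1, e1, s2 - n, e2 - n), ov(s1, e1, s2 + n, e2 + n))
  }
  out
}

#' Call open reading frames under length and overlap constraints
#'
#' Enumerates every start-to-stop ORF on both strands and all three frames
#' (wrapping the origin on circular records), then greedily accepts
#' candidates by decreasing length (ties: leftmost start, then `+` strand),
#' rejecting any candidate that overlaps an already accepted call by more
#' than `max_overlap`. Accepted calls are at least `min_gene_len` long
#' (stop codon included).
#'
#' @param record One-row record tibble.
#' @param cfg An [annotation_config()].
#' @return Tibble of gene calls sorted by start: `start`, `end` (may exceed
#'   the record length for origin-spanning genes on circular records),
#'   `strand`, `frame`, `length`, `seq` (coding strand, incl. stop codon),
#'   `role` (initialised `"unknown"`, see [assign_roles()]).
#' @export
find_orfs <- function(record, cfg = annotation_config()) {
  stopifnot(nrow(record) == 1L)
  n <- nchar(record$seq)
  circular <- record$topology == "circular"
  fwd_work <- if (circular) paste0(record$seq, record$seq) else record$seq
  rc <- revcomp(record$seq)
  rev_work <- if (circular) paste0(rc, rc) else rc
  fwd <- enumerate_orfs_strand(fwd_work, n, circular, cfg)
  fwd$strand <- rep("+", nrow(fwd))
  rev <- enumerate_orfs_strand(rev_work, n, circular, cfg)
  if (nrow(rev)) {
    # map working (revcomp) coordinates back to forward coordinates
    len <- rev$end - rev$start + 1L
    fs <- if (circular) ((n - (rev$end - 1L) %% n - 1L) %% n) + 1L else n - rev$end + 1L
    rev <- tibble(start = fs, end = fs + len - 1L, frame = rev$frame,
                  strand = "-")
  } else {
    rev$strand <- character(0)
  }
  cand <- bind_rows(fwd, rev)
  if (nrow(cand) == 0L) {
    return(tibble(start = integer(), end = integer(), strand = character(),
                  frame = integer(), length = integer(), seq = character(),
                  role = character()))
  }
  cand$length <- cand$end - cand$start + 1L
  cand <- cand %>% arrange(desc(.data$length), .data$start,
                           match(.data$strand, c("+", "-")))
  wrap_n <- if (circular) n else NULL
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!length(acc)) { acc <- i; next }
    ovl <- interval_overlap(cand$start[i], cand$end[i],
                            cand$start[acc], cand$end[acc], wrap_n)
    if (all(ovl <= cfg$max_overlap)) acc <- c(acc, i)
  }
  out <- cand[acc, ] %>% arrange(.data$start, .data$end)
  out$seq <- pmap_chr_orf(record, out)
  out$role <- rep("unknown", nrow(out))
  out
}

pmap_chr_orf <- function(record, calls) {
  map_chr(seq_len(nrow(calls)), function(i) {
    s <- circular_slice(record, calls$start[i], calls$end[i])
    if (calls$strand[i] == "-") revcomp(s) else s
  })
}

translate_orf <- function(nt, drop_stop = TRUE) {
  if (drop_stop) nt <- substr(nt, 1L, nchar(nt) - 3L)
  # bacterial alternative starts are translated as Met
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  substr(aa, 1L, 1L) <- "M"
  aa
}

#' Assign functional roles to gene calls by protein similarity
#'
#' Translates each call and aligns it locally (BLOSUM62, affine gaps)
#' against each reference protein; the best-scoring reference's role is
#' assigned when the score reaches `min_role_score`, otherwise the call
#' stays `unknown`. A role labelling more than one gene is flagged in
#' `role_shared`.
#'
#' @param genes Gene-call tibble from [find_orfs()] (needs a `seq` column).
#' @param references Named character vector of reference proteins
#'   (names are roles, e.g. `VP1`), such as [vp_reference_proteins()].
#' @param cfg An [annotation_config()].
#' @return `genes` with `role`, `role_score` and `role_shared` columns.
#' @export
assign_roles <- function(genes, references, cfg = annotation_config()) {
  if (length(references) == 0L) abort("empty reference list")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", references))) {
    abort("reference protein contains invalid amino acids")
  }
  if (nrow(genes) == 0L) {
    genes$role_score <- numeric(0); genes$role_shared <- logical(0)
    return(genes)
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  refs <- Biostrings::AAStringSet(references)
  scores <- vapply(genes$seq, function(nt) {
    aa <- Biostrings::AAString(translate_orf(nt))
    vapply(seq_along(refs), function(j) {
      Biostrings::pairwiseAlignment(refs[[j]], aa, type = "local",
                                    substitutionMatrix = mat,
                                    gapOpening = 10, gapExtension = 0.5,
                                    scoreOnly = TRUE)
    }, numeric(1))
  }, numeric(length(refs)))
  scores <- matrix(scores, nrow = length(refs))
  best <- apply(scores, 2, which.max)
  best_score <- scores[cbind(best, seq_len(ncol(scores)))]
  genes$role <- ifelse(best_score >= cfg$min_role_score,
                       names(references)[best], "unknown")
  genes$role_score <- best_score
  assigned <- genes$role[genes$role != "unknown"]
  genes$role_shared <- genes$role %in% assigned[duplicated(assigned)]
  genes
}

#' Classify the coding context of a genomic interval
#'
#' Labels an interval relative to a set of gene calls: `non_coding` when it
#' overlaps no gene; `coding_VP4_Nterm` when every overlapped portion lies
#' within the first `n_term_window` bp (in gene orientation) of a VP4-role
#' gene — the exception under which dif-like motifs inside coding sequence
#' are tolerated; `coding_gene_edge` when confined within `n_term_window`
#' of the 5' or 3' end of the genes it touches; otherwise `coding_internal`.
#'
#' @param start,end Interval coordinates (1-based inclusive).
#' @param genes Gene-call tibble from [find_orfs()].
#' @param cfg An [annotation_config()].
#' @param record_len Optional record length for circular overlap handling.
#' @return A single context label.
#' @export
coding_context <- function(start, end, genes, cfg = annotation_config(),
                           record_len = NULL) {
  if (nrow(genes) == 0L) return("non_coding")
  ovl <- interval_overlap(start, end, genes$start, genes$end, record_len)
  hit <- which(ovl > 0L)
  if (!length(hit)) return("non_coding")
  rel <- map(hit, function(i) {
    gs <- genes$start[i]; ge <- genes$end[i]
    s <- start; e <- end
    if (!is.null(record_len)) {
      # shift the interval next to the gene copy it actually overlaps
      shifts <- c(-record_len, 0L, record_len)
      ovs <- vapply(shifts, function(d) interval_overlap(s + d, e + d, gs, ge),
                    integer(1))
      d <- shifts[which.max(ovs)]
      s <- s + d; e <- e + d
    }
    glen <- ge - gs + 1L
    if (genes$strand[i] == "+") {
      c(ov_start = max(s - gs + 1L, 1L), ov_end = min(e - gs + 1L, glen),
        glen = glen)
    } else {
      c(ov_start = max(ge - e + 1L, 1L), ov_end = min(ge - s + 1L, glen),
        glen = glen)
    }
  })
  w <- cfg$n_term_window
  in_nterm <- map_lgl2(rel, function(r) r[["ov_end"]] <= w)
  in_cterm <- map_lgl2(rel, function(r) r[["ov_start"]] >= r[["glen"]] - w + 1L)
  is_vp4 <- genes$role[hit] == "VP4"
  if (all(is_vp4 & in_nterm)) return("coding_VP4_Nterm")
  if (all(in_nterm | in_cterm)) return("coding_gene_edge")
  "coding_internal"
}

map_lgl2 <- function(x, f) vapply(x, f, logical(1))

#' Synthetic reference proteins for the six-gene gokushovirus complement
#'
#' A deterministic, synthetic stand-in for the curated VP protein
#' references: six proteins (replication initiation VP4, ssDNA-switch VP5,
#' scaffold VP3, major capsid VP1, minor capsid VP2, DNA-binding VP8)
#' generated once from a fixed internal seed. They carry no biological
#' signal beyond their lengths and serve as alignment anchors for role
#' assignment and capsid-locus search on simulated genomes.
#'
#' @return Named character vector of six protein sequences.
#' @export
vp_reference_proteins <- function() {
  lens <- c(VP4 = 170L, VP5 = 100L, VP3 = 130L, VP1 = 216L, VP2 = 230L,
            VP8 = 60L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  withr::with_seed(874512, {
    vapply(lens, function(L) {
      paste0("M", paste(sample(aa, L - 1L, replace = TRUE), collapse = ""))
    }, character(1))
  })
}
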