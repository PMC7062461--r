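#' @import tibble
#' @importFrom dplyr %>% mutate filter arrange select bind_rows group_by ungroup
#'   summarise left_join desc row_number across all_of n distinct pull slice rename
#' @importFrom rlang .data abort
#' @importFrom purrr map map_chr map_int map_dbl map2 pmap imap keep list_rbind
#' @importFrom stringr str_detect str_sub str_locate_all str_replace_all
NULL

SEQ_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a sequence record tibble
#'
#' The universal carrier for host chromosomes, phage genomes and
#' metagenome-assembled genomes (MAGs): one row per sequence with an id, the
#' uppercase nucleotide string and a topology flag. Circular topology makes
#' all coordinate operations wrap around the origin.
#'
#' @param id Character vector of record ids (must be unique).
#' @param seq Character vector of nucleotide sequences over `A,C,G,T,N`
#'   (case-insensitive; `U` converted to `T`).
#' @param topology `"linear"` or `"circular"`, recycled as needed.
#' @return A tibble with columns `id`, `seq`, `topology`.
#' @export
#' @examples
#' seq_record("p1", "acgtacgt", "circular")
seq_record <- function(id, seq, topology = "linear") {
  seq <- normalize_seq(seq)
  topology <- rep_len(topology, length(seq))
  if (!all(topology %in% c("linear", "circular"))) {
    abort("topology must be 'linear' or 'circular'")
  }
  if (anyDuplicated(id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  tibble(id = as.character(id), seq = seq, topology = topology)
}

normalize_seq <- function(seq) {
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort(sprintf("invalid character '%s' at position %d of sequence %d",
                  substr(seq[i], bad[i], bad[i]), bad[i], i))
  }
  if (any(!nzchar(seq))) abort("empty sequence not allowed")
  seq
}

#' Read nucleotide FASTA into a record tibble
#'
#' Sequences are uppercased, `U` is converted to `T`, and any character
#' outside `A,C,G,T,N` is an error. Topology defaults to linear unless the
#' header carries the circular tag (anywhere in the description line); the
#' tag is stripped from the id.
#'
#' @param path FASTA file path.
#' @param circular_tag Header token marking circular topology.
#' @return Tibble with columns `id`, `seq`, `topology`; zero rows for an
#'   empty file.
#' @export
read_fasta <- function(path, circular_tag = "[circular]") {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble(id = character(), seq = character(), topology = character()))
  }
  headers <- names(set)
  circ <- str_detect(headers, stringr::fixed(circular_tag))
  ids <- trimws(str_replace_all(headers, stringr::fixed(circular_tag), ""))
  ids <- sub("\\s.*$", "", ids)
  seqs <- unname(as.character(set))
  if (any(!nzchar(seqs))) {
    abort(sprintf("empty sequence under header '%s'", ids[!nzchar(seqs)][1L]))
  }
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seq_record(ids, seqs, ifelse(circ, "circular", "linear"))
}

#' Write a record tibble as FASTA
#'
#' Circular records get the circular tag appended to their header so that
#' topology round-trips through [read_fasta()].
#'
#' @param records Record tibble (`id`, `seq`, `topology`).
#' @param path Output file.
#' @param circular_tag Header token marking circular topology.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, circular_tag = "[circular]", width = 70) {
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- ifelse(records$topology == "circular",
                       paste(records$id, circular_tag), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq Character vector of nucleotide sequences (`A,C,G,T,N`).
#' @return Character vector of reverse complements (`N` maps to `N`).
#' @export
#' @examples
#' revcomp("AAAC") # "GTTT"
revcomp <- function(seq) {
  seq <- normalize_seq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Extract a (possibly origin-spanning) slice of a record
#'
#' Coordinates are 1-based inclusive. On circular records indices wrap
#' around the origin, so `end` may exceed the sequence length; on linear
#' records an out-of-range request is a topology error.
#'
#' @param record One-row record tibble.
#' @param start,end 1-based inclusive coordinates, `end >= start`.
#' @return Nucleotide string of length `end - start + 1`.
#' @export
circular_slice <- function(record, start, end) {
  stopifnot(nrow(record) == 1L, end >= start, start >= 1L)
  n <- nchar(record$seq)
  if (record$topology != "circular") {
    if (end > n) {
      abort(sprintf("slice [%d,%d] exceeds linear record '%s' of length %d",
                    start, end, record$id, n))
    }
    return(substr(record$seq, start, end))
  }
  if (end - start + 1L > n) abort("slice longer than circular record")
  idx <- ((seq.int(start, end) - 1L) %% n) + 1L
  chars <- strsplit(record$seq, "", fixed = TRUE)[[1L]]
  paste(chars[idx], collapse = "")
}

rotate_seq <- function(seq, k) {
  # rotate left by k: new sequence starts at position k+1
  n <- nchar(seq)
  k <- k %% n
  if (k == 0L) return(seq)
  paste0(substr(seq, k + 1L, n), substr(seq, 1L, k))
}

# Booth's algorithm: 0-based index of the lexicographically least rotation
least_rotation_index <- function(seq) {
  s <- utf8ToInt(paste0(seq, seq))
  n <- nchar(seq)
  f <- rep.int(-1L, length(s))
  k <- 0L
  for (j in seq.int(1L, length(s) - 1L)) {
    sj <- s[j + 1L]
    i <- f[j - k]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
    if (j - k + 1L > n) break
  }
  k %% n
}

#' Canonical rotation of a circular record
#'
#' Rotates (and, if needed, reverse-complements) a circular genome into a
#' deterministic reference frame so that rotated copies of the same genome
#' compare equal. With an `anchor` that occurs exactly once across both
#' strands, the record is oriented so the anchor starts at position 1 on the
#' forward strand; without an anchor the lexicographically minimal rotation
#' of the forward sequence is chosen.
#'
#' @param record One-row circular record tibble.
#' @param anchor Optional anchor subsequence (e.g. the phage dif site).
#' @return The rotated record tibble.
#' @export
canonical_rotation <- function(record, anchor = NULL) {
  stopifnot(nrow(record) == 1L)
  if (record$topology != "circular") abort("canonical_rotation requires a circular record")
  seq <- record$seq
  n <- nchar(seq)
  if (!is.null(anchor)) {
    anchor <- normalize_seq(anchor)
    fwd <- find_in_circular(seq, anchor)
    rev <- find_in_circular(seq, revcomp(anchor))
    total <- length(fwd) + length(rev)
    if (total == 0L) {
      k <- least_rotation_index(seq)
      record$seq <- rotate_seq(seq, k)
      return(record)
    }
    if (total > 1L) {
      abort(sprintf("anchor occurs %d times in '%s' (positions %s)", total, record$id,
                    paste(sort(c(fwd, rev)), collapse = ", ")))
    }
    if (length(fwd) == 1L) {
      record$seq <- rotate_seq(seq, fwd - 1L)
    } else {
      # anchor on minus strand: flip, then rotate so anchor leads
      rc <- revcomp(seq)
      pos <- find_in_circular(rc, anchor)
      record$seq <- rotate_seq(rc, pos[1L] - 1L)
    }
    return(record)
  }
  record$seq <- rotate_seq(seq, least_rotation_index(seq))
  record
}

# all start positions (1-based) of pattern in circular sequence
find_in_circular <- function(seq, pattern) {
  n <- nchar(seq)
  doubled <- paste0(seq, substr(seq, 1L, min(nchar(pattern) - 1L, n)))
  m <- gregexpr(pattern, doubled, fixed = TRUE)[[1L]]
  pos <- m[m > 0L]
  pos[pos <= n]
}

#' dif-site grammar
#'
#' The 28-bp dif site decomposes into an 11-bp XerC-binding arm, a 6-bp
#' central spacer and an 11-bp XerD-binding arm. The canonical sequence
#' defaults to the E. coli chromosomal dif and can be overridden; it is a
#' configuration value, not ground truth.
#'
#' @param xerC_arm_len,spacer_len,xerD_arm_len Component lengths in bp.
#' @param canonical Canonical site sequence of the total grammar length.
#' @return A list of class `dif_grammar` with the component lengths,
#'   canonical sequence and `total` width.
#' @export
dif_grammar <- function(xerC_arm_len = 11L, spacer_len = 6L, xerD_arm_len = 11L,
                        canonical = "GGTGCGCATAATGTATATTATGTTAAAT") {
  canonical <- normalize_seq(canonical)
  total <- xerC_arm_len + spacer_len + xerD_arm_len
  if (nchar(canonical) != total) {
    abort(sprintf("canonical sequence length %d != grammar total %d",
                  nchar(canonical), total))
  }
  structure(list(xerC_arm_len = as.integer(xerC_arm_len),
                 spacer_len = as.integer(spacer_len),
                 xerD_arm_len = as.integer(xerD_arm_len),
                 total = as.integer(total),
                 canonical = canonical),
            class = "dif_grammar")
}

#' @export
print.dif_grammar <- function(x, ...) {
  cat(sprintf("dif grammar: %d bp = XerC arm %d + spacer %d + XerD arm %d\ncanonical: %s\n",
              x$total, x$xerC_arm_len, x$spacer_len, x$xerD_arm_len, x$canonical))
  invisible(x)
}

# Hamming distance; N mismatches everything (conservative)
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  av <- charToRaw(a); bv <- charToRaw(b)
  nn <- charToRaw("N")
  sum(av != bv | av == nn | bv == nn)
}

# mismatch count of every length-m window of seq against motif; vectorized
hamming_windows <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  s <- charToRaw(seq); mo <- charToRaw(motif)
  nn <- charToRaw("N")
  k <- n - m + 1L
  mm <- integer(k)
  for (j in seq_len(m)) {
    win <- s[j:(j + k - 1L)]
    mm <- mm + as.integer(win != mo[j] | win == nn | mo[j] == nn)
  }
  mm
}

#' Write pipeline outputs in standard formats
#'
#' Serialises a set of prophage calls (see [mine()]) as GFF3 (features
#' `prophage`, `gene`, `dif_site`; 1-based inclusive coordinates) plus a TSV
#' summary, the excised genomes as FASTA with the circular header tag, and
#' optional dif-scan hits as BED (0-based half-open) plus a scored TSV.
#' Coordinates round-trip exactly through `rtracklayer`.
#'
#' @param calls Prophage call tibble from [mine()] (may have zero rows).
#' @param path Output directory (created if missing).
#' @param hits Optional dif-scan hit tibble from [scan_pwm()]/[filter_hits()],
#'   with a `record_id` column.
#' @return Invisibly, the named vector of files written.
#' @export
write_outputs <- function(calls, path, hits = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(gff3 = file.path(path, "prophages.gff3"),
             tsv = file.path(path, "prophages.tsv"),
             fasta = file.path(path, "excised.fasta"))
  gr <- calls_to_granges(calls)
  rtracklayer::export(gr, files[["gff3"]], format = "gff3")
  summary_cols <- c("host_id", "start", "end", "length",
                    "upstream_class", "downstream_class", "n_genes")
  readr::write_tsv(calls[intersect(summary_cols, names(calls))], files[["tsv"]])
  excised <- if (nrow(calls)) {
    seq_record(paste0(calls$host_id, "_prophage"),
               map_chr(calls$excised, ~ .x$seq[1L]), "circular")
  } else {
    tibble(id = character(), seq = character(), topology = character())
  }
  write_fasta(excised, files[["fasta"]])
  if (!is.null(hits)) {
    files <- c(files, bed = file.path(path, "dif_hits.bed"),
               hits_tsv = file.path(path, "dif_hits.tsv"))
    bed <- GenomicRanges::GRanges(
      seqnames = if (nrow(hits)) hits$record_id else character(),
      ranges = IRanges::IRanges(start = hits$start, end = hits$end),
      strand = if (nrow(hits)) hits$strand else character())
    S4Vectors::mcols(bed)$name <- if (nrow(hits)) {
      paste0("dif_hit_", seq_len(nrow(hits)))
    } else character()
    S4Vectors::mcols(bed)$score <- if (nrow(hits)) hits$score else numeric()
    rtracklayer::export(bed, files[["bed"]], format = "BED")
    readr::write_tsv(hits, files[["hits_tsv"]])
  }
  invisible(files)
}

calls_to_granges <- function(calls) {
  if (nrow(calls) == 0L) {
    return(GenomicRanges::GRanges())
  }
  rows <- pmap(list(calls$host_id, calls$start, calls$end,
                    calls$upstream_dif, calls$downstream_dif, calls$genes),
    function(hid, s, e, up, down, genes) {
      feat <- tibble(
        seqnames = hid,
        start = c(s, up$start, down$start, s - 1L + genes$start),
        end = c(e, up$end, down$end, s - 1L + genes$end),
        strand = c("+", "+", "+", genes$strand),
        type = c("prophage", "dif_site", "dif_site", rep("gene", nrow(genes))),
        ID = c(paste0(hid, "_prophage"),
               paste0(hid, "_dif_up"), paste0(hid, "_dif_down"),
               paste0(hid, "_gene_", seq_len(nrow(genes)))),
        Name = c(paste0(hid, "_prophage"), up$site_class, down$site_class,
                 as.character(genes$role)))
      feat
    }) %>% list_rbind()
  GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand,
    type = rows$type, ID = rows$ID, Name = rows$Name)
}
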