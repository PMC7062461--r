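#' Rotation-aware pairwise average nucleotide identity
#'
#' Circular genomes are first brought into a canonical frame
#' ([canonical_rotation()], using the dif site as anchor when supplied) and
#' then globally aligned with affine gap penalties; identity is the number
#' of matching columns divided by the aligned columns excluding terminal
#' gaps, as a percentage. Linear records are aligned as given.
#'
#' @param a,b One-row record tibbles, both circular or both linear.
#' @param anchor Optional rotation anchor (e.g. a shared dif motif).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_ani <- function(a, b, anchor = NULL) {
  stopifnot(nrow(a) == 1L, nrow(b) == 1L)
  if (!nzchar(a$seq) || !nzchar(b$seq)) abort("empty sequence")
  if (a$topology != b$topology) {
    abort("records must share topology (both circular or both linear)")
  }
  if (a$topology == "circular") {
    a <- canonical_rotation(a, anchor)
    b <- canonical_rotation(b, anchor)
  }
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                 baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a$seq),
                                      Biostrings::DNAString(b$seq),
                                      type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 10, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  gap <- p == "-" | s == "-"
  first <- which(!gap)[1L]
  last <- max(which(!gap))
  # terminal gap columns excluded; internal gap columns count as aligned
  keep <- seq.int(first, last)
  100 * sum(p[keep] == s[keep]) / length(keep)
}

#' All-pairs ANI matrix
#'
#' @param records Record tibble (all the same topology).
#' @param anchor Optional rotation anchor passed to [pairwise_ani()].
#' @return Object of class `goku_ani`: `ids` and the symmetric percent
#'   `mat` with a diagonal of 100.
#' @export
ani_matrix <- function(records, anchor = NULL) {
  n <- nrow(records)
  m <- diag(100, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        v <- pairwise_ani(records[i, ], records[j, ], anchor)
        m[i, j] <- v; m[j, i] <- v
      }
    }
  }
  dimnames(m) <- list(records$id, records$id)
  structure(list(ids = records$id, mat = m), class = "goku_ani")
}

#' @export
print.goku_ani <- function(x, ...) {
  cat(sprintf("ANI matrix over %d genomes (mean off-diagonal %.1f%%)\n",
              length(x$ids),
              if (length(x$ids) > 1L) mean(x$mat[upper.tri(x$mat)]) else NA))
  invisible(x)
}

#' @export
tidy.goku_ani <- function(x, ...) {
  expand.grid(id1 = x$ids, id2 = x$ids, stringsAsFactors = FALSE) %>%
    as_tibble() %>%
    mutate(ani = as.vector(x$mat)) %>%
    filter(match(.data$id1, x$ids) < match(.data$id2, x$ids))
}

#' Cluster genomes into clades by an ANI threshold
#'
#' Single-linkage components of the graph whose edges join genome pairs
#' with ANI strictly above the threshold. Components of two or more
#' members are labelled A, B, ... in order of decreasing size (ties by
#' smallest member id); isolated genomes are singletons.
#'
#' @param m A `goku_ani` from [ani_matrix()].
#' @param threshold Percent ANI; edges require `ani > threshold`.
#' @return Tibble: `id`, `clade` (`"singleton"` for isolated genomes),
#'   `singleton` flag.
#' @export
cluster_clades <- function(m, threshold = 95) {
  adj <- m$mat > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  members <- split(m$ids, comp$membership)
  sizes <- lengths(members)
  ord <- order(-sizes, map_chr(members, ~ sort(.x)[1L]))
  label <- rep(NA_character_, length(members))
  next_clade <- 1L
  for (ci in ord) {
    if (sizes[ci] >= 2L) {
      label[ci] <- if (next_clade <= 26L) LETTERS[next_clade] else
        paste0("clade", next_clade)
      next_clade <- next_clade + 1L
    } else {
      label[ci] <- "singleton"
    }
  }
  tibble(id = m$ids, clade = label[comp$membership],
         singleton = label[comp$membership] == "singleton")
}

#' Read an aligned FASTA (gaps allowed)
#'
#' @param path Aligned FASTA path.
#' @return Tibble with `id` and aligned `seq` (uppercase, `-` gaps).
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (length(unique(nchar(seqs))) > 1L) abort("ragged alignment")
  tibble(id = sub("\\s.*$", "", names(set)), seq = unname(seqs))
}

#' Per-column mean pairwise identity of an alignment
#'
#' For each alignment column, the mean over unordered sequence pairs of
#' the indicator that both members carry the same base; pairs with a gap
#' in either member are excluded, and a column with no gap-free pair is
#' missing. An optional centred moving average smooths the profile. Dips
#' in the profile mark hypervariable regions.
#'
#' @param msa Character vector of aligned sequences (equal lengths) or a
#'   tibble with a `seq` column, e.g. from [read_msa()].
#' @param window Odd moving-average width; 1 disables smoothing.
#' @return Tibble of class `goku_identity_profile`: `column`, `identity`
#'   (and `smoothed` when `window > 1`).
#' @export
identity_profile <- function(msa, window = 1L) {
  seqs <- if (is.data.frame(msa)) msa$seq else msa
  if (length(seqs) < 2L) abort("need at least two sequences")
  if (length(unique(nchar(seqs))) > 1L) abort("ragged alignment")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ncol_aln <- ncol(mat)
  identity <- vapply(seq_len(ncol_aln), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    npairs <- choose(length(col), 2)
    if (npairs == 0) return(NA_real_)
    tab <- table(col)
    sum(choose(tab, 2)) / npairs
  }, numeric(1))
  out <- tibble(column = seq_len(ncol_aln), identity = identity)
  if (window > 1L) {
    half <- (window - 1L) %/% 2L
    out$smoothed <- vapply(seq_len(ncol_aln), function(j) {
      idx <- max(1L, j - half):min(ncol_aln, j + half)
      v <- identity[idx]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  attr(out, "window") <- window
  class(out) <- c("goku_identity_profile", class(out))
  out
}

#' Define a PCR primer pair
#'
#' @param name Assay name.
#' @param fwd,rev Primer sequences, 5' to 3', at least 15 nt.
#' @param max_product Largest product size reported.
#' @param max_mismatch Mismatches tolerated per primer (the 3'-terminal
#'   base must always match).
#' @return One-row tibble.
#' @export
primer_pair <- function(name, fwd, rev, max_product = 10000L,
                        max_mismatch = 0L) {
  fwd <- normalize_seq(fwd); rev <- normalize_seq(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) {
    abort("primers must be at least 15 nt")
  }
  tibble(name = name, fwd = fwd, rev = rev,
         max_product = as.integer(max_product),
         max_mismatch = as.integer(max_mismatch))
}

#' Read a primer TSV (columns name, fwd, rev, max_product[, max_mismatch])
#'
#' @param path TSV path.
#' @return Tibble of primer pairs.
#' @export
read_primers <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("name", "fwd", "rev", "max_product") %in% names(tb))) {
    abort("primer TSV needs columns name, fwd, rev, max_product")
  }
  if (is.null(tb$max_mismatch)) tb$max_mismatch <- 0L
  list_rbind(map(seq_len(nrow(tb)), function(i) {
    primer_pair(tb$name[i], tb$fwd[i], tb$rev[i], tb$max_product[i],
                tb$max_mismatch[i])
  }))
}

# primer binding sites on the forward strand of (possibly extended) template
primer_sites <- function(seq, primer, max_mismatch, anchor_3prime_end) {
  subj <- Biostrings::DNAString(seq)
  hits <- Biostrings::matchPattern(primer, subj, max.mismatch = max_mismatch)
  st <- BiocGenerics::start(hits); en <- BiocGenerics::end(hits)
  if (!length(st)) return(tibble(start = integer(), end = integer()))
  # the primer's 3'-terminal base must match the template exactly
  keep <- vapply(seq_along(st), function(i) {
    pos <- if (anchor_3prime_end) en[i] else st[i]
    ch <- substr(seq, pos, pos)
    pb <- if (anchor_3prime_end) substr(primer, nchar(primer), nchar(primer))
          else substr(primer, 1L, 1L)
    ch == pb
  }, logical(1))
  tibble(start = st[keep], end = en[keep])
}

#' Predict PCR products on a template
#'
#' The forward primer is matched on either strand and paired with the
#' reverse primer binding downstream in the same orientation; the product
#' spans from the 5' end of one primer through the 5' end of the other,
#' inclusive of both primers. Circular templates also yield
#' origin-crossing products; products longer than `max_product` are
#' suppressed.
#'
#' @param template One-row record tibble.
#' @param primers One-row tibble from [primer_pair()].
#' @return Amplicon tibble: `assay`, `start`, `end` (forward coordinates;
#'   `end` may exceed the template length for origin-crossing products),
#'   `size`, `wraps`.
#' @export
insilico_pcr <- function(template, primers) {
  stopifnot(nrow(template) == 1L, nrow(primers) == 1L)
  n <- nchar(template$seq)
  circular <- template$topology == "circular"
  ext_len <- if (circular) min(n - 1L, primers$max_product) else 0L
  seq <- paste0(template$seq, substr(template$seq, 1L, ext_len))
  mm <- primers$max_mismatch
  products <- list()
  # left primer on + strand, right primer's reverse complement downstream
  combos <- list(c(primers$fwd, primers$rev), c(primers$rev, primers$fwd))
  for (cb in combos) {
    left <- primer_sites(seq, cb[1L], mm, anchor_3prime_end = TRUE)
    right <- primer_sites(seq, revcomp(cb[2L]), mm, anchor_3prime_end = FALSE)
    for (i in seq_len(nrow(left))) {
      ls <- left$start[i]
      if (ls > n) next  # count each circular origin once
      cand <- right[right$start > left$end[i], , drop = FALSE]
      for (j in seq_len(nrow(cand))) {
        size <- cand$end[j] - ls + 1L
        if (size > primers$max_product) next
        products[[length(products) + 1L]] <-
          tibble(assay = primers$name, start = ls, end = cand$end[j],
                 size = size, wraps = cand$end[j] > n)
      }
    }
  }
  if (!length(products)) {
    return(tibble(assay = character(), start = integer(), end = integer(),
                  size = integer(), wraps = logical()))
  }
  list_rbind(products) %>% distinct() %>% arrange(.data$start, .data$size)
}

#' Expected band table for a genotype population
#'
#' Runs every assay against every member of a (possibly mixed) population
#' and tabulates the expected amplicon sizes per assay, with the genotype
#' labels producing each band and the fraction of the population carrying
#' it — the counting model behind lysogen-fraction readouts from band
#' intensities.
#'
#' @param population Record tibble with an additional `label` column
#'   (e.g. `integrated`, `circular_carrier`, `empty`).
#' @param assays Primer tibble ([primer_pair()] rows).
#' @return Tibble: `assay`, `size`, `labels` (comma-separated genotypes),
#'   `fraction`, `n_members`.
#' @export
genotype_bands <- function(population, assays) {
  if (nrow(population) == 0L) {
    return(tibble(assay = character(), size = integer(), labels = character(),
                  fraction = numeric(), n_members = integer()))
  }
  stopifnot("label" %in% names(population))
  per_member <- map(seq_len(nrow(population)), function(i) {
    rec <- population[i, c("id", "seq", "topology")]
    bands <- map(seq_len(nrow(assays)), function(a) {
      insilico_pcr(rec, assays[a, ]) %>%
        distinct(.data$assay, .data$size)
    }) %>% list_rbind()
    if (nrow(bands)) bands %>% mutate(member = population$id[i],
                                      label = population$label[i])
    else NULL
  }) %>% list_rbind()
  if (is.null(per_member) || nrow(per_member) == 0L) {
    return(tibble(assay = character(), size = integer(), labels = character(),
                  fraction = numeric(), n_members = integer()))
  }
  per_member %>%
    group_by(.data$assay, .data$size) %>%
    summarise(labels = paste(sort(unique(.data$label)), collapse = ","),
              fraction = dplyr::n_distinct(.data$member) / nrow(population),
              n_members = dplyr::n_distinct(.data$member), .groups = "drop") %>%
    arrange(.data$assay, .data$size)
}
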