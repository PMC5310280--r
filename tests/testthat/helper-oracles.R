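# Independent brute-force oracles, kept deliberately naive: enumeration and
# scalar case tables, no shared code with the implementation paths they check.

or_tok <- function(ids, signs) paste0(ifelse(signs > 0L, "+", "-"), ids)

# is the signed run (ids, signs) present, forward or fully reversed with
# flipped signs, as a consecutive (circularly, if applicable) window?
oracle_run_present <- function(ids, signs, ord) {
  n <- length(ord$ids); k <- length(ids)
  if (k > n) return(FALSE)
  hay <- or_tok(ord$ids, ord$signs)
  if (ord$circular && k > 1L) hay <- c(hay, hay)
  pat_f <- or_tok(ids, signs)
  pat_r <- or_tok(rev(ids), -rev(signs))
  starts <- if (ord$circular) seq_len(n) else seq_len(n - k + 1L)
  for (s in starts) {
    win <- hay[s:(s + k - 1L)]
    if (identical(win, pat_f) || identical(win, pat_r)) return(TRUE)
  }
  FALSE
}

run_canonical <- function(ids, signs, full_circle = FALSE) {
  if (!full_circle) {
    f <- paste(or_tok(ids, signs), collapse = ",")
    r <- paste(or_tok(rev(ids), -rev(signs)), collapse = ",")
    return(min(f, r))
  }
  # a run covering a whole circular order has no distinguished start:
  # canonicalize over all rotations of both readings
  n <- length(ids)
  best <- NULL
  for (dir in 1:2) {
    if (dir == 2L) { ids <- rev(ids); signs <- -rev(signs) }
    for (r in seq_len(n)) {
      idx <- c(seq(r, n), if (r > 1L) seq_len(r - 1L))
      key <- paste(or_tok(ids[idx], signs[idx]), collapse = ",")
      if (is.null(best) || key < best) best <- key
    }
  }
  best
}

# exhaustive enumeration of maximal conserved consecutive runs
oracle_segments <- function(orders, min_len) {
  simp <- lapply(orders, function(o) {
    r <- o$replicons[[1L]]
    list(ids = r$ids, signs = r$signs, circular = r$circular,
         genome = o$genome_id)
  })
  simp <- simp[order(vapply(simp, `[[`, "", "genome"))]
  first <- simp[[1L]]
  n <- length(first$ids)
  runs <- list()
  for (s in seq_len(n)) {
    for (k in seq_len(n)) {
      if (!first$circular && s + k - 1L > n) break
      idx <- ((s - 1L + seq_len(k) - 1L) %% n) + 1L
      if (anyDuplicated(idx)) break
      ids <- first$ids[idx]; signs <- first$signs[idx]
      ok <- all(vapply(simp, function(o)
        oracle_run_present(ids, signs, o), logical(1)))
      if (ok) runs[[length(runs) + 1L]] <-
          list(ids = ids, signs = signs, pos = idx)
    }
  }
  # maximality: drop runs whose index set is strictly contained in another
  keep <- vapply(seq_along(runs), function(i) {
    !any(vapply(seq_along(runs), function(j) {
      j != i && length(runs[[j]]$pos) > length(runs[[i]]$pos) &&
        all(runs[[i]]$pos %in% runs[[j]]$pos)
    }, logical(1)))
  }, logical(1))
  runs <- runs[keep]
  runs <- runs[vapply(runs, function(r) length(r$ids) >= min_len,
                      logical(1))]
  sort(unique(vapply(runs, function(r)
    run_canonical(r$ids, r$signs,
                  full_circle = first$circular && length(r$ids) == n),
    "")))
}

segments_canonical <- function(segments, n_universe = NA_integer_,
                               circular = FALSE) {
  sort(vapply(segments$segments, function(s)
    run_canonical(s$ids, s$signs,
                  full_circle = circular &&
                    length(s$ids) == n_universe), ""))
}

random_orders <- function(n_genes, n_genomes, circular = TRUE) {
  ids <- paste0("g", seq_len(n_genes))
  lapply(seq_len(n_genomes), function(i) {
    perm <- sample(n_genes)
    core_order(sprintf("G%02d", i), ids[perm],
               sample(c(1L, -1L), n_genes, replace = TRUE),
               circular = circular)
  })
}

# hand case table for which contig end a mate points off:
# a forward mate near the tail points off the tail, a reverse mate near the
# head points off the head; interior mates point off nothing
oracle_mate_end <- function(strand, pos, width, len, W) {
  if (strand == 1L && (len - (pos + width)) <= W) return("tail")
  if (strand == -1L && pos <= W) return("head")
  NA_character_
}

oracle_count_links <- function(pairs, lens, W) {
  tab <- list()
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    if (!p$mapped_1 || !p$mapped_2) next
    if (p$contig_1 == p$contig_2) next
    e1 <- oracle_mate_end(p$strand_1, p$pos_1, p$width_1,
                          lens[[p$contig_1]], W)
    e2 <- oracle_mate_end(p$strand_2, p$pos_2, p$width_2,
                          lens[[p$contig_2]], W)
    if (is.na(e1) || is.na(e2)) next
    a <- c(p$contig_1, e1); b <- c(p$contig_2, e2)
    if (a[1L] > b[1L]) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a[1L], a[2L], b[1L], b[2L], sep = "|")
    tab[[key]] <- (tab[[key]] %||% 0L) + 1L
  }
  tab
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_pairs <- function(n_pairs, n_contigs) {
  lens <- stats::setNames(sample(500:3000, n_contigs, replace = TRUE),
                          sprintf("t%02d", seq_len(n_contigs)))
  mk_mate <- function() {
    cid <- sample(names(lens), n_pairs, replace = TRUE)
    w <- 100L
    pos <- floor(stats::runif(n_pairs) * (lens[cid] - w))
    list(contig = cid, pos = pos, width = rep(w, n_pairs),
         strand = sample(c(1L, -1L), n_pairs, replace = TRUE),
         mapped = stats::runif(n_pairs) < 0.95)
  }
  m1 <- mk_mate(); m2 <- mk_mate()
  pairs <- data.frame(pair_id = sprintf("p%04d", seq_len(n_pairs)),
                      contig_1 = m1$contig, pos_1 = m1$pos,
                      width_1 = m1$width, strand_1 = m1$strand,
                      mapped_1 = m1$mapped,
                      contig_2 = m2$contig, pos_2 = m2$pos,
                      width_2 = m2$width, strand_2 = m2$strand,
                      mapped_2 = m2$mapped,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, lens = lens)
}

edges_to_oracle_form <- function(edges) {
  out <- list()
  for (k in seq_len(nrow(edges))) {
    key <- paste(edges$contig_a[k], edges$end_a[k],
                 edges$contig_b[k], edges$end_b[k], sep = "|")
    out[[key]] <- edges$n[k]
  }
  out
}

# write a pair table as literal SAM text (independent of write_truth_sam)
pairs_to_sam <- function(pairs, lens, path) {
  hdr <- c("@HD\tVN:1.6",
           paste0("@SQ\tSN:", names(lens), "\tLN:", unname(lens)))
  lines <- character(0)
  for (r in seq_len(nrow(pairs))) {
    p <- pairs[r, ]
    for (m in 1:2) {
      mapped <- p[[paste0("mapped_", m)]]
      other <- p[[paste0("mapped_", 3L - m)]]
      flag <- 1L + (if (m == 1L) 64L else 128L) +
        (if (!mapped) 4L else 0L) + (if (!other) 8L else 0L) +
        (if (mapped && p[[paste0("strand_", m)]] < 0L) 16L else 0L)
      seqs <- strrep("A", p[[paste0("width_", m)]])
      lines <- c(lines, paste(p$pair_id, flag,
                              if (mapped) p[[paste0("contig_", m)]] else "*",
                              if (mapped) p[[paste0("pos_", m)]] + 1L else 0L,
                              if (mapped) 60L else 0L,
                              if (mapped)
                                paste0(p[[paste0("width_", m)]], "M")
                              else "*",
                              "*", 0L, 0L, seqs,
                              strrep("I", nchar(seqs)), sep = "\t"))
    }
  }
  writeLines(c(hdr, lines), path)
  path
}

# independent compatibility check: a witnessed oriented adjacency (a,b) is
# in a circular pattern iff the pattern shows a then b (with those signs) or
# -b then -a consecutively, wrapping around
oracle_pattern_has_adjacency <- function(ids, signs, a_id, a_sign,
                                         b_id, b_sign) {
  n <- length(ids)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (ids[i] == a_id && signs[i] == a_sign &&
        ids[j] == b_id && signs[j] == b_sign) return(TRUE)
    if (ids[i] == b_id && signs[i] == -b_sign &&
        ids[j] == a_id && signs[j] == -a_sign) return(TRUE)
  }
  FALSE
}
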