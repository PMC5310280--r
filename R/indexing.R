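#' Assign core-gene hits to contigs
#'
#' Filters alignment hits by identity and query coverage, then keeps a single
#' best placement per gene (score = identity x coverage).  A gene whose top
#' two placements tie within 1% (relative) is discarded as ambiguous: genes
#' that do not map uniquely cannot index a contig.
#'
#' @param hits Hit data.frame from [read_gene_hits()] / [match_core_genes()].
#' @param min_identity Minimum identity fraction (default 0.90).
#' @param min_coverage Minimum query coverage fraction (default 0.80).
#' @return Data.frame of one row per assigned gene (columns as in the input),
#'   with attribute \code{"ambiguous_genes"} naming discarded genes.
#' @export
assign_gene_hits <- function(hits, min_identity = 0.90, min_coverage = 0.80) {
  h <- hits[hits$identity >= min_identity &
              (is.na(hits$coverage) | hits$coverage >= min_coverage), ,
            drop = FALSE]
  ambiguous <- character(0)
  if (nrow(h) == 0L) {
    out <- h
  } else {
    h$score <- h$identity * ifelse(is.na(h$coverage), 1, h$coverage)
    keep <- logical(nrow(h))
    for (q in unique(h$query_id)) {
      i <- which(h$query_id == q)
      sc <- h$score[i]
      o <- order(-sc, h$target_id[i], h$tstart[i])
      if (length(i) > 1L && sc[o[2L]] >= sc[o[1L]] * 0.99) {
        ambiguous <- c(ambiguous, q)
      } else {
        keep[i[o[1L]]] <- TRUE
      }
    }
    out <- h[keep, setdiff(names(h), "score"), drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "ambiguous_genes") <- ambiguous
  out
}

#' Index contigs by the segments they carry
#'
#' Annotates each contig with maximal runs of same-segment genes in
#' consistent segment order.  Within a run, gene indexes must be strictly
#' monotone (ascending for orientation +, descending for -); gaps in the
#' index are allowed — a contig missing interior genes of a segment (an
#' internal deletion in the target) stays indexed, the missing genes simply
#' widen the downstream gap estimate.  Orientation is + when gene order on
#' the contig ascends in segment gene index.
#'
#' A contig is \code{ambiguous} when two of its intervals claim overlapping
#' gene ranges of one segment (an irreconcilable orientation or placement
#' mix); \code{unindexed} when it has no surviving hits on segment genes.
#'
#' @param assigned Assigned hits from [assign_gene_hits()].
#' @param segments \code{cgof_segments} object.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return List of per-contig indexes: \code{list(contig_id, length, hits,
#'   intervals, status)}; \code{intervals} has columns \code{segment_id},
#'   \code{gi_lo}, \code{gi_hi}, \code{orient}, \code{n_hits}, \code{t_lo},
#'   \code{t_hi}.
#' @export
index_contigs <- function(assigned, segments, contig_lengths) {
  seg_of <- segments$gene_segment
  idx_of <- segments$gene_index
  sign_of <- segments$gene_sign
  lapply(sort(names(contig_lengths)), function(cid) {
    h <- assigned[assigned$target_id == cid, , drop = FALSE]
    h <- h[h$query_id %in% names(seg_of), , drop = FALSE]
    h <- h[order(h$tstart), , drop = FALSE]
    if (nrow(h) == 0L)
      return(list(contig_id = cid, length = contig_lengths[[cid]],
                  hits = h, intervals = empty_intervals(),
                  status = "unindexed"))
    seg <- seg_of[h$query_id]
    gi <- idx_of[h$query_id]
    rel <- h$strand * sign_of[h$query_id]   # orientation vs segment
    iv <- list()
    cur <- NULL
    flush <- function(cur) {
      data.frame(segment_id = cur$seg,
                 gi_lo = min(cur$gi), gi_hi = max(cur$gi),
                 orient = cur$rel, n_hits = length(cur$gi),
                 t_lo = cur$t_lo, t_hi = cur$t_hi,
                 stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(h))) {
      extend <- !is.null(cur) && seg[k] == cur$seg && rel[k] == cur$rel &&
        ((cur$rel > 0L && gi[k] > cur$gi[length(cur$gi)]) ||
           (cur$rel < 0L && gi[k] < cur$gi[length(cur$gi)]))
      if (extend) {
        cur$gi <- c(cur$gi, gi[k]); cur$t_hi <- h$tend[k]
      } else {
        if (!is.null(cur)) iv[[length(iv) + 1L]] <- flush(cur)
        cur <- list(seg = seg[k], rel = rel[k], gi = gi[k],
                    t_lo = h$tstart[k], t_hi = h$tend[k])
      }
    }
    iv[[length(iv) + 1L]] <- flush(cur)
    intervals <- do.call(rbind, iv)
    status <- "indexed"
    # same segment claimed twice with overlapping gene ranges -> ambiguous
    for (s in unique(intervals$segment_id)) {
      ii <- intervals[intervals$segment_id == s, , drop = FALSE]
      if (nrow(ii) > 1L) {
        o <- order(ii$gi_lo)
        if (any(ii$gi_lo[o][-1L] <= ii$gi_hi[o][-nrow(ii)]))
          status <- "ambiguous"
      }
    }
    list(contig_id = cid, length = contig_lengths[[cid]],
         hits = h, intervals = intervals, status = status)
  })
}

empty_intervals <- function() {
  data.frame(segment_id = character(), gi_lo = integer(), gi_hi = integer(),
             orient = integer(), n_hits = integer(),
             t_lo = numeric(), t_hi = numeric(), stringsAsFactors = FALSE)
}

#' Merge indexed contigs and segments into ordered scaffold strings
#'
#' Contigs sharing a segment are ordered along it by their gene subranges;
#' a contig whose intervals span two segments is an overbridge and fuses
#' those segments' chains into one string.  When two contigs claim
#' overlapping gene subranges of a segment, the one with more gene hits is
#' kept and the other is demoted to ambiguous.  Gaps between consecutive
#' contigs are estimated from the genomic span of the intervening genes in
#' the references (median across genomes; fallback \code{gap_default}).
#'
#' @param indices Contig indexes from [index_contigs()].
#' @param segments \code{cgof_segments} object.
#' @param clusters Cluster table, for reference-based gap estimates
#'   (optional; NULL uses \code{gap_default} everywhere).
#' @param gap_default Fallback gap length in bp (default 100).
#' @return List of class \code{scaffold_strings}: \code{strings} (each
#'   \code{list(string_id, items, arc)} where \code{items} has columns
#'   \code{contig_id}, \code{orient}, \code{gap_after} and \code{arc} is a
#'   data.frame of oriented segments), \code{demoted} (contig ids),
#'   \code{junctions} (witnessed oriented segment adjacencies).
#' @export
merge_strings <- function(indices, segments, clusters = NULL,
                          gap_default = 100) {
  names(indices) <- vapply(indices, `[[`, "", "contig_id")
  demoted <- character(0)
  repeat {
    idx <- indices[vapply(indices, function(x)
      x$status == "indexed", logical(1))]
    conflict <- find_overlap_conflict(idx)
    if (is.null(conflict)) break
    indices[[conflict]]$status <- "ambiguous"
    demoted <- c(demoted, conflict)
  }
  idx <- indices[vapply(indices, function(x)
    x$status == "indexed", logical(1))]
  all_sids <- vapply(segments$segments, `[[`, "", "segment_id")
  # per-segment chains of contig intervals, in gene-index order
  chains <- lapply(all_sids, function(s) {
    rows <- list()
    for (ci in idx) {
      iv <- ci$intervals[ci$intervals$segment_id == s, , drop = FALSE]
      if (nrow(iv) > 0L) {
        iv$contig_id <- ci$contig_id
        rows[[length(rows) + 1L]] <- iv
      }
    }
    if (length(rows) == 0L) return(NULL)
    ch <- do.call(rbind, rows)
    ch[order(ch$gi_lo, ch$gi_hi, ch$contig_id), , drop = FALSE]
  })
  names(chains) <- all_sids
  # overbridge junctions: consecutive intervals on one contig, walking the
  # contig forward, traverse oriented segments o1*S1 -> o2*S2
  junctions <- list()
  for (ci in idx) {
    iv <- ci$intervals[order(ci$intervals$t_lo), , drop = FALSE]
    if (nrow(iv) < 2L) next
    for (k in seq_len(nrow(iv) - 1L)) {
      if (iv$segment_id[k] == iv$segment_id[k + 1L]) next
      junctions[[length(junctions) + 1L]] <- data.frame(
        seg_a = iv$segment_id[k], orient_a = iv$orient[k],
        seg_b = iv$segment_id[k + 1L], orient_b = iv$orient[k + 1L],
        contig_id = ci$contig_id, n_hits = iv$n_hits[k] + iv$n_hits[k + 1L],
        stringsAsFactors = FALSE)
    }
  }
  junctions <- if (length(junctions) > 0L) do.call(rbind, junctions)
  else data.frame(seg_a = character(), orient_a = integer(),
                  seg_b = character(), orient_b = integer(),
                  contig_id = character(), n_hits = integer(),
                  stringsAsFactors = FALSE)
  paths <- segment_paths(all_sids[!vapply(chains, is.null, logical(1))],
                         junctions)
  lengths <- stats::setNames(
    vapply(indices, function(x) as.numeric(x$length), 0),
    names(indices))
  strings <- list()
  for (p in paths) {
    items <- expand_segment_path(p, chains)
    if (is.null(items) || nrow(items) == 0L) next
    items$gap_after <- c(estimate_gaps(items, segments, clusters,
                                       gap_default, lengths), NA_real_)[
                                         seq_len(nrow(items))]
    items$gap_after[nrow(items)] <- NA_real_
    strings[[length(strings) + 1L]] <-
      list(string_id = paste0("STR", length(strings) + 1L),
           items = items[c("contig_id", "orient", "gap_after")],
           arc = p)
  }
  structure(list(strings = strings, demoted = demoted,
                 junctions = junctions, indices = indices),
            class = "scaffold_strings")
}

# first contig demotable due to an overlapping gene-subrange claim, or NULL
find_overlap_conflict <- function(idx) {
  segs <- unique(unlist(lapply(idx, function(ci) ci$intervals$segment_id)))
  for (s in segs) {
    rows <- list()
    for (ci in idx) {
      iv <- ci$intervals[ci$intervals$segment_id == s, , drop = FALSE]
      if (nrow(iv) > 0L) {
        iv$contig_id <- ci$contig_id
        iv$total_hits <- sum(ci$intervals$n_hits)
        rows[[length(rows) + 1L]] <- iv
      }
    }
    if (length(rows) < 2L) next
    ch <- do.call(rbind, rows)
    ch <- ch[order(ch$gi_lo, ch$gi_hi), , drop = FALSE]
    for (k in seq_len(nrow(ch) - 1L)) {
      if (ch$gi_lo[k + 1L] <= ch$gi_hi[k] &&
          ch$contig_id[k] != ch$contig_id[k + 1L]) {
        pair <- ch[c(k, k + 1L), ]
        loser <- pair$contig_id[order(pair$total_hits,
                                      -rank(pair$contig_id))[1L]]
        warning("contigs ", paste(pair$contig_id, collapse = " and "),
                " claim overlapping genes of ", s, "; demoting ", loser)
        return(loser)
      }
    }
  }
  NULL
}

# assemble oriented-segment paths from overbridge junctions; each segment has
# a 'start' end (gene index 1) and an 'end' end, used like contig head/tail
segment_paths <- function(seg_ids, junctions) {
  if (length(seg_ids) == 0L) return(list())
  used <- list()   # key "seg|end" -> c(other seg, other end)
  take <- function(seg, orient, exit = TRUE) {
    # port used when leaving (exit) or entering a segment traversed with
    # the given orientation
    if (exit) { if (orient > 0L) "end" else "start" }
    else { if (orient > 0L) "start" else "end" }
  }
  links <- list()
  if (nrow(junctions) > 0L) {
    jx <- junctions[order(-junctions$n_hits, junctions$contig_id), ,
                    drop = FALSE]
    for (k in seq_len(nrow(jx))) {
      a <- jx$seg_a[k]; b <- jx$seg_b[k]
      if (!(a %in% seg_ids) || !(b %in% seg_ids) || a == b) next
      pa <- paste(a, take(a, jx$orient_a[k], TRUE), sep = "|")
      pb <- paste(b, take(b, jx$orient_b[k], FALSE), sep = "|")
      if (!is.null(used[[pa]]) || !is.null(used[[pb]])) next
      used[[pa]] <- pb; used[[pb]] <- pa
      links[[length(links) + 1L]] <- c(pa, pb)
    }
  }
  port_other <- function(port) used[[port]]
  seen <- character(0)
  paths <- list()
  for (s in seg_ids) {
    if (s %in% seen) next
    # walk right from s's end port, then (unless the walk closed a cycle)
    # left from its start port, avoiding segments already taken
    walk <- function(seg, orient, forbidden) {
      out <- data.frame(segment_id = seg, orient = orient,
                        stringsAsFactors = FALSE)
      repeat {
        port <- paste(seg, if (orient > 0L) "end" else "start", sep = "|")
        nxt <- port_other(port)
        if (is.null(nxt)) break
        seg2 <- sub("\\|.*$", "", nxt)
        if (seg2 %in% out$segment_id || seg2 %in% forbidden) break
        orient2 <- if (endsWith(nxt, "|start")) 1L else -1L
        out <- rbind(out, data.frame(segment_id = seg2, orient = orient2,
                                     stringsAsFactors = FALSE))
        seg <- seg2; orient <- orient2
      }
      out
    }
    right <- walk(s, 1L, character(0))
    last <- right[nrow(right), ]
    last_port <- paste(last$segment_id,
                       if (last$orient > 0L) "end" else "start", sep = "|")
    closes <- !is.null(port_other(last_port)) &&
      sub("\\|.*$", "", port_other(last_port)) == s
    if (closes) {
      path <- right   # full cycle, linearized at s
    } else {
      left <- walk(s, -1L, right$segment_id[-1L])   # the reflection
      if (nrow(left) > 1L) {
        left <- left[seq(nrow(left), 2L), , drop = FALSE]
        left$orient <- -left$orient
        path <- rbind(left, right)
      } else {
        path <- right
      }
    }
    seen <- c(seen, path$segment_id)
    rownames(path) <- NULL
    paths[[length(paths) + 1L]] <- path
  }
  paths
}

# expand an oriented-segment path into the ordered contig items
expand_segment_path <- function(path, chains) {
  items <- list()
  bounds <- list()   # per item: first/last gene (segment, index) covered
  for (k in seq_len(nrow(path))) {
    ch <- chains[[path$segment_id[k]]]
    if (is.null(ch)) next
    if (path$orient[k] > 0L) {
      ord <- seq_len(nrow(ch)); flip <- 1L
    } else {
      ord <- rev(seq_len(nrow(ch))); flip <- -1L
    }
    for (r in ord) {
      cid <- ch$contig_id[r]
      n <- length(items)
      if (n > 0L && items[[n]]$contig_id == cid) {
        # overbridge contig already emitted from the previous segment
        bounds[[n]]$last <- list(seg = path$segment_id[k],
                                 gi = if (flip > 0L) ch$gi_hi[r] else ch$gi_lo[r])
        bounds[[n]]$t_min <- min(bounds[[n]]$t_min, ch$t_lo[r])
        bounds[[n]]$t_max <- max(bounds[[n]]$t_max, ch$t_hi[r])
        next
      }
      items[[n + 1L]] <- list(contig_id = cid,
                              orient = ch$orient[r] * flip)
      bounds[[n + 1L]] <- list(
        first = list(seg = path$segment_id[k],
                     gi = if (flip > 0L) ch$gi_lo[r] else ch$gi_hi[r]),
        last = list(seg = path$segment_id[k],
                    gi = if (flip > 0L) ch$gi_hi[r] else ch$gi_lo[r]),
        t_min = ch$t_lo[r], t_max = ch$t_hi[r])
    }
  }
  if (length(items) == 0L) return(NULL)
  # a contig tiling the circular origin carries intervals at both ends of
  # the segment index space and surfaces at both ends of the chain; merge
  # the two occurrences (the string is circular through it)
  n <- length(items)
  if (n > 1L && items[[1L]]$contig_id == items[[n]]$contig_id &&
      items[[1L]]$orient == items[[n]]$orient) {
    bounds[[1L]]$t_min <- min(bounds[[1L]]$t_min, bounds[[n]]$t_min)
    bounds[[1L]]$t_max <- max(bounds[[1L]]$t_max, bounds[[n]]$t_max)
    bounds[[1L]]$first <- bounds[[n]]$first
    items <- items[-n]; bounds <- bounds[-n]
  }
  df <- data.frame(contig_id = vapply(items, `[[`, "", "contig_id"),
                   orient = vapply(items, `[[`, 0L, "orient"),
                   stringsAsFactors = FALSE)
  attr(df, "bounds") <- bounds
  df
}

# reference-median span between the flanking genes of consecutive items,
# minus the contig sequence already flanking the junction (overhangs); the
# fallback applies when no reference carries both genes on one replicon
estimate_gaps <- function(items, segments, clusters, gap_default,
                          lengths = NULL) {
  bounds <- attr(items, "bounds")
  n <- nrow(items)
  if (n < 2L) return(numeric(0))
  gaps <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    g_u <- g_v <- NULL
    if (!is.null(bounds)) {
      bu <- bounds[[k]]$last; bv <- bounds[[k + 1L]]$first
      g_u <- segment_gene_at(segments, bu$seg, bu$gi)
      g_v <- segment_gene_at(segments, bv$seg, bv$gi)
    }
    med <- estimate_gap_between(g_u, g_v, clusters, NA_real_)
    if (is.na(med) || is.null(bounds) || is.null(lengths)) {
      gaps[k] <- gap_default
    } else {
      len_a <- lengths[[items$contig_id[k]]]
      oh_right <- if (items$orient[k] > 0L)
        len_a - bounds[[k]]$t_max else bounds[[k]]$t_min
      len_b <- lengths[[items$contig_id[k + 1L]]]
      oh_left <- if (items$orient[k + 1L] > 0L)
        bounds[[k + 1L]]$t_min else len_b - bounds[[k + 1L]]$t_max
      gaps[k] <- max(0, med - oh_right - oh_left)
    }
  }
  gaps
}

segment_gene_at <- function(segments, seg_id, gi) {
  sids <- vapply(segments$segments, `[[`, "", "segment_id")
  s <- segments$segments[[match(seg_id, sids)]]
  if (is.null(s) || is.na(gi) || gi < 1L || gi > length(s$ids)) return(NULL)
  s$ids[gi]
}

#' @keywords internal
# median inter-gene distance across reference genomes; replicons are
# circular, so the distance is the shorter way around, with the replicon
# extent approximated by its furthest gene end (the trailing spacer is
# unobservable from gene coordinates alone)
estimate_gap_between <- function(gene_u, gene_v, clusters, gap_default = 100) {
  if (is.null(gene_u) || is.null(gene_v) || is.null(clusters))
    return(gap_default)
  ds <- numeric(0)
  for (g in unique(clusters$genome_id)) {
    sub <- clusters[clusters$genome_id == g, , drop = FALSE]
    ru <- sub[sub$cluster_id == gene_u, ]
    rv <- sub[sub$cluster_id == gene_v, ]
    if (nrow(ru) != 1L || nrow(rv) != 1L) next
    if (ru$replicon_id != rv$replicon_id) next
    inner <- max(0, max(ru$start, rv$start) - min(ru$end, rv$end))
    extent <- max(sub$end[sub$replicon_id == ru$replicon_id])
    wrap <- max(0, extent - max(ru$end, rv$end) + min(ru$start, rv$start))
    ds <- c(ds, min(inner, wrap))
  }
  if (length(ds) == 0L) return(gap_default)
  stats::median(ds)
}
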