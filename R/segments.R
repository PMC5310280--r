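#' Identify order-conserved core-gene segments
#'
#' A segment is a maximal run of core genes whose signed adjacencies are
#' conserved in every reference: the adjacency (a, b) is conserved iff every
#' genome carries \code{..., a, b, ...} or \code{..., -b, -a, ...}
#' consecutively (wrapping around circular replicons).  Because conservation
#' is required in all genomes simultaneously, the conserved adjacencies form
#' the same disjoint paths/cycles in every genome, so maximal runs can be
#' read off any one of them; the lexicographically first genome is used,
#' which also fixes segment numbering and canonical orientation.
#'
#' Runs shorter than \code{min_seg_len} are discarded (their genes drop out
#' of the framework); the surviving segments partition the remaining genes.
#'
#' @param orders List of \code{core_order} objects sharing one gene universe.
#' @param min_seg_len Minimum number of genes per segment (default 2, the
#'   smallest run that still carries order information).
#' @return Object of class \code{cgof_segments}: a list with
#'   \code{segments} (list of \code{list(segment_id, ids, signs)} in canonical
#'   orientation), and lookup vectors \code{gene_segment}, \code{gene_index},
#'   \code{gene_sign} named by gene id.
#' @export
identify_segments <- function(orders, min_seg_len = 2L) {
  stopifnot(length(orders) >= 1L, min_seg_len >= 1L)
  orders <- orders[order(vapply(orders, `[[`, "", "genome_id"))]
  universe <- Reduce(intersect, lapply(orders, function(o)
    unlist(lapply(o$replicons, `[[`, "ids"), use.names = FALSE)))
  adj_sets <- lapply(orders, order_adjacencies)
  conserved <- Reduce(intersect, adj_sets)
  ref <- orders[[1L]]
  segs <- list()
  for (rep_ in ref$replicons) {
    keep <- rep_$ids %in% universe
    ids <- rep_$ids[keep]; signs <- rep_$signs[keep]
    n <- length(ids)
    if (n == 0L) next
    pair_ok <- function(i, j) {
      paste(signs[i], ids[i], signs[j], ids[j], sep = "\r") %in% conserved
    }
    if (n == 1L) {
      runs <- list(1L)
    } else {
      edge <- vapply(seq_len(n - 1L), function(i) pair_ok(i, i + 1L),
                     logical(1))
      wrap <- rep_$circular && pair_ok(n, 1L)
      if (all(edge) && wrap) {
        # fully conserved circle: one segment; rotate to start at the
        # lexicographically smallest gene id for determinism
        s <- order(ids)[1L]
        idx <- c(seq(s, n), if (s > 1L) seq_len(s - 1L))
        runs <- list(idx)
      } else {
        brk <- which(!edge)            # break after position brk
        if (rep_$circular && !wrap) brk <- c(brk, n)
        if (!rep_$circular) brk <- c(brk, n)
        brk <- sort(unique(brk))
        # walk runs between breaks, circularly if needed
        starts <- c(if (rep_$circular) brk[length(brk)] %% n + 1L else 1L,
                    brk[-length(brk)] + 1L)
        if (!rep_$circular) starts <- c(1L, brk[-length(brk)] + 1L)
        runs <- lapply(seq_along(starts), function(k) {
          s <- starts[k]; e <- brk[k]
          if (s <= e) seq(s, e) else c(seq(s, n), seq_len(e))
        })
      }
    }
    for (r in runs) {
      if (length(r) < min_seg_len) next
      segs[[length(segs) + 1L]] <- list(ids = ids[r], signs = signs[r])
    }
  }
  # number segments by first occurrence in the first genome's order
  segments <- lapply(seq_along(segs), function(k)
    list(segment_id = paste0("S", k),
         ids = segs[[k]]$ids, signs = segs[[k]]$signs))
  gene_segment <- gene_sign <- character(0)
  gene_index <- integer(0)
  for (s in segments) {
    gene_segment[s$ids] <- s$segment_id
    gene_index[s$ids] <- seq_along(s$ids)
    gene_sign[s$ids] <- as.character(s$signs)
  }
  sign_int <- as.integer(gene_sign)
  names(sign_int) <- names(gene_sign)
  structure(list(segments = segments,
                 gene_segment = gene_segment,
                 gene_index = gene_index,
                 gene_sign = sign_int),
            class = "cgof_segments")
}

#' @export
print.cgof_segments <- function(x, ...) {
  cat("cgof_segments:", length(x$segments), "segment(s),",
      length(x$gene_segment), "gene(s)\n")
  for (s in x$segments)
    cat(" ", s$segment_id, ": ", length(s$ids), " genes [",
        paste0(ifelse(s$signs > 0, "+", "-"), s$ids)[1L], " ...]\n", sep = "")
  invisible(x)
}

# Orientation of an observed gene run against a segment's canonical form:
# +1 forward, -1 reversed-with-flipped-signs, NA no match.  When the run is a
# whole circular replicon its stored rotation is arbitrary, so all rotations
# are tried.
match_segment_run <- function(ids, signs, seg, circular = FALSE) {
  n <- length(ids)
  rots <- if (circular) seq_len(n) else 1L
  for (r in rots) {
    idx <- if (r == 1L) seq_len(n) else c(seq(r, n), seq_len(r - 1L))
    if (identical(ids[idx], seg$ids) && identical(signs[idx], seg$signs))
      return(1L)
    if (identical(rev(ids[idx]), seg$ids) &&
        identical(-rev(signs[idx]), seg$signs))
      return(-1L)
  }
  NA_integer_
}

#' Derive each genome's signed segment permutation
#'
#' Locates every segment in every genome's core order (forward in canonical
#' orientation gives sign +, fully reversed with flipped signs gives -) and
#' records the circular order of segments per genome.  Replicons are
#' concatenated in sorted order for multi-replicon genomes; the permutation
#' is marked circular only for single-replicon genomes.
#'
#' @param segments \code{cgof_segments} from [identify_segments()].
#' @param orders The same core orders used to identify the segments.
#' @return List of permutations, one per genome: \code{list(genome_id,
#'   seg_ids, seg_signs, circular)}.
#' @export
derive_permutations <- function(segments, orders) {
  orders <- orders[order(vapply(orders, `[[`, "", "genome_id"))]
  first_gene <- lapply(segments$segments, function(s) s$ids[1L])
  lapply(orders, function(o) {
    seg_ids <- character(0); seg_signs <- integer(0)
    for (rep_ in o$replicons) {
      keep <- rep_$ids %in% names(segments$gene_segment)
      ids <- rep_$ids[keep]; signs <- rep_$signs[keep]
      n <- length(ids)
      if (n == 0L) next
      seg_of <- segments$gene_segment[ids]
      # rotate a circular order so it starts on a segment boundary
      if (rep_$circular && n > 1L && length(unique(seg_of)) > 1L) {
        cut <- which(seg_of != c(seg_of[n], seg_of[-n]))[1L]
        idx <- c(seq(cut, n), if (cut > 1L) seq_len(cut - 1L))
        ids <- ids[idx]; signs <- signs[idx]; seg_of <- seg_of[idx]
      }
      grp <- cumsum(c(TRUE, seg_of[-1L] != seg_of[-n]))
      all_sids <- vapply(segments$segments, `[[`, "", "segment_id")
      for (g in unique(grp)) {
        i <- which(grp == g)
        sid <- seg_of[i[1L]]
        seg <- segments$segments[[match(sid, all_sids)]]
        if (length(i) != length(seg$ids))
          stop("segment ", sid, " not intact in genome ", o$genome_id)
        m <- match_segment_run(ids[i], signs[i], seg,
                               circular = rep_$circular &&
                                 length(i) == n)
        if (is.na(m))
          stop("segment ", sid, " order mismatch in genome ", o$genome_id)
        seg_ids <- c(seg_ids, sid); seg_signs <- c(seg_signs, m)
      }
    }
    list(genome_id = o$genome_id, seg_ids = unname(seg_ids),
         seg_signs = seg_signs,
         circular = length(o$replicons) == 1L &&
           isTRUE(o$replicons[[1L]]$circular))
  })
}
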