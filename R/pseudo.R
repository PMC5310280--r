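#' Canonicalize a circular signed segment permutation
#'
#' Two deposited genomes with the same architecture can differ by rotation
#' (arbitrary origin) and by reflection with sign flips (arbitrary strand),
#' so prevalence counting needs a canonical representative: the
#' lexicographically smallest encoding over all rotations of the permutation
#' and of its reflection.  Linear permutations admit only the identity and
#' the reflection.
#'
#' @param seg_ids Character segment ids.
#' @param seg_signs Integer \code{+1}/\code{-1} signs.
#' @param circular Topology flag (default TRUE).
#' @return \code{list(seg_ids, seg_signs, key)} where \code{key} is the
#'   canonical string encoding.
#' @export
canonicalize_permutation <- function(seg_ids, seg_signs, circular = TRUE) {
  stopifnot(length(seg_ids) == length(seg_signs))
  n <- length(seg_ids)
  if (n == 0L) return(list(seg_ids = seg_ids, seg_signs = seg_signs,
                           key = ""))
  cands <- list()
  add <- function(ids, signs) {
    rots <- if (circular) seq_len(length(ids)) else 1L
    for (r in rots) {
      idx <- if (r == 1L) seq_along(ids) else
        c(seq(r, length(ids)), seq_len(r - 1L))
      cands[[length(cands) + 1L]] <<- list(ids = ids[idx],
                                           signs = signs[idx])
    }
  }
  add(seg_ids, seg_signs)
  add(rev(seg_ids), -rev(seg_signs))
  keys <- vapply(cands, function(x) perm_key(x$ids, x$signs), "")
  best <- cands[[order(keys)[1L]]]
  list(seg_ids = best$ids, seg_signs = best$signs,
       key = perm_key(best$ids, best$signs))
}

perm_key <- function(ids, signs) {
  paste(paste0(ifelse(signs > 0L, "+", "-"), ids), collapse = ",")
}

#' Tally canonical permutation patterns across reference genomes
#'
#' @param permutations List of per-genome permutations from
#'   [derive_permutations()].
#' @return Data.frame of votes: \code{key}, \code{prevalence},
#'   \code{genomes} (comma-separated supporting genome ids), with the
#'   canonical permutations attached as the \code{"patterns"} attribute
#'   (a named list).
#' @export
permutation_votes <- function(permutations) {
  canon <- lapply(permutations, function(p)
    canonicalize_permutation(p$seg_ids, p$seg_signs, p$circular))
  keys <- vapply(canon, `[[`, "", "key")
  genomes <- vapply(permutations, `[[`, "", "genome_id")
  uk <- sort(unique(keys))
  votes <- data.frame(
    key = uk,
    prevalence = vapply(uk, function(k) sum(keys == k), 0L),
    genomes = vapply(uk, function(k)
      paste(sort(genomes[keys == k]), collapse = ","), ""),
    stringsAsFactors = FALSE)
  rownames(votes) <- NULL
  patterns <- lapply(uk, function(k) canon[[match(k, keys)]])
  names(patterns) <- uk
  attr(votes, "patterns") <- patterns
  votes
}

# oriented segment adjacencies of a signed circular sequence, both readings
perm_adjacencies <- function(seg_ids, seg_signs, circular = TRUE) {
  adjacency_keys(seg_ids, seg_signs, circular)
}

# witnessed oriented-segment adjacencies from assembled strings
string_junctions <- function(strings) {
  adj <- character(0)
  for (s in strings$strings) {
    arc <- s$arc
    if (is.null(arc) || nrow(arc) < 2L) next
    adj <- c(adj, adjacency_keys(arc$segment_id, arc$orient,
                                 circular = FALSE))
  }
  unique(adj)
}

#' Remove permutation patterns conflicting with the assembled strings
#'
#' A pattern is removed iff it lacks a segment adjacency (with orientation)
#' that the strings directly witness; with no witnessed junction every
#' pattern is vacuously compatible.
#'
#' @param votes Vote table from [permutation_votes()].
#' @param strings \code{scaffold_strings} whose arcs carry the witnessed
#'   junctions.
#' @return The vote table restricted to compatible patterns (a
#'   \code{compatible} column is added to the full table in the
#'   \code{"verdicts"} attribute).
#' @export
filter_conflicting <- function(votes, strings) {
  witnessed <- string_junctions(strings)
  patterns <- attr(votes, "patterns")
  ok <- vapply(votes$key, function(k) {
    p <- patterns[[k]]
    pa <- perm_adjacencies(p$seg_ids, p$seg_signs, circular = TRUE)
    all(witnessed %in% pa)
  }, logical(1))
  verdicts <- votes
  verdicts$compatible <- ok
  out <- votes[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "patterns") <- patterns[out$key]
  attr(out, "verdicts") <- verdicts
  out
}

#' Select the guiding permutation pattern
#'
#' The most prevalent compatible pattern wins; ties are broken in favour of
#' the pattern whose supporting genome set contains the lexicographically
#' first genome id, so adding unrelated genomes cannot silently flip the
#' winner.  Returns NULL when no compatible pattern exists — a novel
#' arrangement in the target.
#'
#' @param compatible Filtered vote table from [filter_conflicting()].
#' @return \code{list(seg_ids, seg_signs, key, prevalence, genomes)} or NULL.
#' @export
select_guide <- function(compatible) {
  if (nrow(compatible) == 0L) return(NULL)
  first_genome <- vapply(strsplit(compatible$genomes, ","), `[`, "", 1L)
  o <- order(-compatible$prevalence, first_genome)[1L]
  p <- attr(compatible, "patterns")[[compatible$key[o]]]
  list(seg_ids = p$seg_ids, seg_signs = p$seg_signs, key = p$key,
       prevalence = compatible$prevalence[o],
       genomes = compatible$genomes[o])
}

#' Build a circular pseudo-genome along the guide permutation
#'
#' Each segment-bearing string must embed as a contiguous arc of the guide
#' (forward or reflected); an arc matching more than one position is an
#' ambiguous embedding and is an error rather than a guess.  Strings are
#' ordered and oriented along the guide circle; inter-string gaps are filled
#' with N runs (reference-estimated where possible, at least
#' \code{gap_min}, at most \code{gap_max}).  Adjacencies created only by the
#' guide — joined by neither an overbridge contig nor PE links — are
#' reported as unverified.
#'
#' @param strings Resolved \code{scaffold_strings}.
#' @param guide Guide pattern from [select_guide()].
#' @param contig_seqs DNAStringSet of contig sequences.
#' @param clusters Cluster table for gap estimation (optional).
#' @param segments \code{cgof_segments} (for gap estimation; optional).
#' @param gap_min,gap_max Bounds on emitted gap lengths (default 100/10000).
#' @return \code{list(seq, placements, gaps, guide, unverified, leftovers,
#'   topology)}; \code{placements} has 0-based half-open coordinates on the
#'   emitted circular sequence.
#' @export
build_pseudo_genome <- function(strings, guide, contig_seqs,
                                clusters = NULL, segments = NULL,
                                gap_min = 100, gap_max = 10000) {
  if (is.null(guide)) stop("no guide pattern: novel arrangement")
  m <- length(guide$seg_ids)
  seg_strings <- Filter(function(s) !is.null(s$arc) && nrow(s$arc) > 0L,
                        strings$strings)
  placed <- list()
  for (s in seg_strings) {
    emb <- embed_arc(s$arc, guide$seg_ids, guide$seg_signs)
    if (is.null(emb))
      stop("string ", s$string_id, " cannot embed in the guide permutation")
    placed[[length(placed) + 1L]] <-
      list(string = s, start = emb$start, flip = emb$flip,
           span = nrow(s$arc))
  }
  if (length(placed) == 0L) stop("no segment-bearing string to place")
  ord <- order(vapply(placed, `[[`, 0L, "start"))
  placed <- placed[ord]
  # assemble around the circle
  pieces <- list()
  placements <- list()
  unverified <- list()
  pos <- 0
  for (k in seq_along(placed)) {
    p <- placed[[k]]
    it <- p$string$items
    arc <- p$string$arc
    if (p$flip < 0L) {
      it <- it[rev(seq_len(nrow(it))), , drop = FALSE]
      it$orient <- -it$orient
      it$gap_after <- c(it$gap_after[-1L], NA_real_)
      arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
      arc$orient <- -arc$orient
    }
    for (j in seq_len(nrow(it))) {
      cid <- it$contig_id[j]
      seq_j <- contig_seqs[[cid]]
      if (it$orient[j] < 0L) seq_j <- Biostrings::reverseComplement(seq_j)
      pieces[[length(pieces) + 1L]] <- seq_j
      placements[[length(placements) + 1L]] <- data.frame(
        contig_id = cid, orient = it$orient[j],
        start = pos, end = pos + length(seq_j),
        string_id = p$string$string_id, stringsAsFactors = FALSE)
      pos <- pos + length(seq_j)
      if (j < nrow(it)) {
        # within-string gaps are reference-estimated and may be zero
        # (directly abutting contigs); only guide-created inter-string
        # gaps carry the gap_min floor
        g <- it$gap_after[j]
        if (is.null(g) || is.na(g)) g <- gap_min
        g <- max(0, min(gap_max, round(g)))
        if (g > 0) {
          pieces[[length(pieces) + 1L]] <- n_run(g)
          pos <- pos + g
        }
      }
    }
    # guide-created junction to the next string (circularly)
    nxt <- placed[[if (k == length(placed)) 1L else k + 1L]]
    lo <- p$start + p$span - 1L
    hi <- nxt$start
    gap_guess <- inter_string_gap(p, nxt, guide, clusters, segments,
                                  gap_min)
    g <- clamp_gap(gap_guess, gap_min, gap_max)
    if (k < length(placed) || length(placed) > 1L ||
        !arc_covers_all(p, m)) {
      pieces[[length(pieces) + 1L]] <- n_run(g)
      pos <- pos + g
    }
    unverified[[length(unverified) + 1L]] <- data.frame(
      from_string = p$string$string_id,
      to_string = nxt$string$string_id,
      guide_position = lo %% m + 1L, support = "cgof_guide_only",
      stringsAsFactors = FALSE)
  }
  single_full <- length(placed) == 1L && arc_covers_all(placed[[1L]], m)
  if (single_full) unverified <- list()
  seq_out <- do.call(Biostrings::xscat, pieces)
  placements <- do.call(rbind, placements)
  leftovers <- setdiff(names(contig_seqs), placements$contig_id)
  list(seq = seq_out, placements = placements,
       guide = guide,
       unverified = if (length(unverified) > 0L) do.call(rbind, unverified)
       else NULL,
       leftovers = leftovers, topology = "circular")
}

arc_covers_all <- function(p, m) p$span == m

clamp_gap <- function(g, gap_min, gap_max) {
  if (is.null(g) || is.na(g)) g <- gap_min
  max(gap_min, min(gap_max, round(g)))
}

n_run <- function(n) {
  Biostrings::DNAString(paste(rep("N", n), collapse = ""))
}

# locate an arc (oriented segment run) in the circular guide; NULL if absent,
# error if ambiguous
embed_arc <- function(arc, guide_ids, guide_signs) {
  m <- length(guide_ids)
  k <- nrow(arc)
  if (k > m) return(NULL)
  hits <- list()
  whole <- k == m
  for (flip in c(1L, -1L)) {
    ids <- arc$segment_id; signs <- arc$orient
    if (flip < 0L) { ids <- rev(ids); signs <- -rev(signs) }
    starts <- if (whole && m > 1L) seq_len(m) else seq_len(m)
    for (s in starts) {
      idx <- ((s - 1L + seq_len(k) - 1L) %% m) + 1L
      if (identical(guide_ids[idx], ids) &&
          identical(guide_signs[idx], signs))
        hits[[length(hits) + 1L]] <- list(start = s, flip = flip)
    }
  }
  if (length(hits) == 0L) return(NULL)
  if (whole) {
    # a full-circle arc matches at every rotation of itself; any one
    # placement is the same pseudo-genome up to rotation — keep the first
    return(hits[[1L]])
  }
  if (length(hits) > 1L)
    stop("ambiguous embedding: arc matches the guide at ",
         length(hits), " positions")
  hits[[1L]]
}

# reference-estimated gap between the last gene of one string and the first
# gene of the next along the guide
inter_string_gap <- function(p, nxt, guide, clusters, segments, gap_min) {
  if (is.null(clusters) || is.null(segments)) return(gap_min)
  arc_a <- p$string$arc; arc_b <- nxt$string$arc
  if (p$flip < 0L) {
    arc_a <- arc_a[rev(seq_len(nrow(arc_a))), , drop = FALSE]
    arc_a$orient <- -arc_a$orient
  }
  if (nxt$flip < 0L) {
    arc_b <- arc_b[rev(seq_len(nrow(arc_b))), , drop = FALSE]
    arc_b$orient <- -arc_b$orient
  }
  last_seg <- arc_a[nrow(arc_a), ]
  first_seg <- arc_b[1L, ]
  sids <- vapply(segments$segments, `[[`, "", "segment_id")
  sa <- segments$segments[[match(last_seg$segment_id, sids)]]
  sb <- segments$segments[[match(first_seg$segment_id, sids)]]
  if (is.null(sa) || is.null(sb)) return(gap_min)
  gene_u <- if (last_seg$orient > 0L) sa$ids[length(sa$ids)] else sa$ids[1L]
  gene_v <- if (first_seg$orient > 0L) sb$ids[1L] else sb$ids[length(sb$ids)]
  estimate_gap_between(gene_u, gene_v, clusters, gap_min)
}
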