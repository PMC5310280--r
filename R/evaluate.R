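#' Canonical key of the target's true segment permutation
#'
#' Restricts the target's known gene order to the framework genes of the
#' identified segments and derives its signed segment permutation — the
#' ground truth a recovered pseudo-genome's guide must match.
#'
#' @param truth Truth list from [simulate_pangenome()].
#' @param segments \code{cgof_segments} identified from the references.
#' @return Canonical permutation key string.
#' @export
true_segment_permutation <- function(truth, segments) {
  tc <- truth$target_coords
  ords <- build_core_orders(rbind(tc, tc_dummy(tc)),
                            genomes = c("target", "..dummy.."))
  ord <- ords[[which(vapply(ords, `[[`, "", "genome_id") == "target")]]
  perm <- derive_permutations(segments, list(ord, ord))[[1L]]
  canonicalize_permutation(perm$seg_ids, perm$seg_signs, perm$circular)$key
}

# duplicate of the target coordinates under another genome id so that
# build_core_orders' two-genome requirement is met without altering the order
tc_dummy <- function(tc) {
  d <- tc
  d$genome_id <- "..dummy.."
  d
}

#' Score an assembly against the simulator's truth
#'
#' Coverage is the length of all placed contigs over the true genome length
#' (in percent); falsely located is the length of contigs placed at the
#' wrong locus or orientation.  A contig is correctly located when it sits
#' on its scaffold's dominant diagonal: per scaffold (forward and
#' reflected), each contig with truth-matching orientation votes, weighted
#' by length, for the circular offset between its truth position and its
#' scaffold position, and the winning offset defines correct placement.
#' Errors are junction breaks: each adjacent pair in the output that is not
#' a true adjacency counts one error — an inversion when the mates' relative
#' orientation is wrong, an indel when they are correctly oriented but skip
#' truth positions in order, a relocation otherwise.  Corrected N50 is the
#' N50 after breaking scaffolds at every error junction.
#'
#' @param scaffolds List of data.frames \code{(contig_id, orient)} in
#'   scaffold order; a pseudo-genome is one circular scaffold.
#' @param truth_placements True contig placements (contig_id, start, end,
#'   strand) from [fragment_target()].
#' @param circular Logical vector (recycled) marking circular scaffolds.
#' @return List: \code{recovered_pct}, \code{false_pct}, \code{n_errors},
#'   \code{error_types}, \code{corrected_n50}, \code{n_scaffolds}.
#' @export
evaluate_against_truth <- function(scaffolds, truth_placements,
                                   circular = FALSE) {
  tp <- truth_placements[order(truth_placements$start), , drop = FALSE]
  if (!all(unlist(lapply(scaffolds, function(s)
    s$contig_id %in% tp$contig_id))))
    stop("output names contigs unknown to the truth set")
  tlen <- stats::setNames(tp$end - tp$start, tp$contig_id)
  genome_len <- sum(tlen)
  circular <- rep_len(circular, length(scaffolds))
  placed <- unique(unlist(lapply(scaffolds, `[[`, "contig_id")))
  # ranks in truth order among placed contigs only, so that contigs the
  # output omits entirely neither shift downstream placements nor charge
  # junction errors
  ranked <- tp$contig_id[tp$contig_id %in% placed]
  M <- length(ranked)
  rnk <- stats::setNames(seq_len(M), ranked)
  correct <- character(0)
  n_err <- 0L
  err_types <- c(inversion = 0L, indel = 0L, relocation = 0L)
  frag_lens <- numeric(0)
  for (si in seq_along(scaffolds)) {
    sc <- scaffolds[[si]]
    best <- NULL
    for (flip in c(1L, -1L)) {
      s <- sc
      if (flip < 0L) {
        s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
        s$orient <- -s$orient
      }
      valid <- s$orient == 1L
      d <- (rnk[s$contig_id] - seq_len(nrow(s))) %% M
      for (dv in unique(d[valid])) {
        w <- sum(tlen[s$contig_id[valid & d == dv]])
        if (is.null(best) || w > best$w)
          best <- list(w = w, flip = flip, d = dv)
      }
    }
    s <- sc
    if (!is.null(best) && best$flip < 0L) {
      s <- s[rev(seq_len(nrow(s))), , drop = FALSE]
      s$orient <- -s$orient
    }
    if (!is.null(best)) {
      d <- (rnk[s$contig_id] - seq_len(nrow(s))) %% M
      ok <- s$orient == 1L & d == best$d
      correct <- union(correct, s$contig_id[ok])
    }
    # junction errors: an adjacency is true when both mates share an
    # orientation and are consecutive (in that direction) among placed
    n <- nrow(s)
    pairs <- if (n >= 2L) seq_len(n - 1L) else integer(0)
    a_idx <- c(pairs, if (circular[si] && n >= 2L) n)
    b_idx <- c(pairs + 1L, if (circular[si] && n >= 2L) 1L)
    frag <- tlen[s$contig_id[1L]]
    for (k in seq_along(a_idx)) {
      a <- a_idx[k]; b <- b_idx[k]
      oa <- s$orient[a]; ob <- s$orient[b]
      ra <- rnk[s$contig_id[a]]; rb <- rnk[s$contig_id[b]]
      jump <- if (oa > 0L) (rb - ra) %% M else (ra - rb) %% M
      true_adj <- oa == ob && jump == 1L
      if (true_adj) {
        frag <- frag + tlen[s$contig_id[b]]
      } else {
        n_err <- n_err + 1L
        type <- if (oa != ob) "inversion"
        else if (jump > 1L && jump <= 5L) "indel"
        else "relocation"
        err_types[type] <- err_types[type] + 1L
        frag_lens <- c(frag_lens, frag)
        frag <- tlen[s$contig_id[b]]
      }
    }
    frag_lens <- c(frag_lens, frag)
  }
  false_ids <- setdiff(placed, correct)
  list(recovered_pct = 100 * sum(tlen[placed]) / genome_len,
       false_pct = 100 * sum(tlen[false_ids]) / genome_len,
       n_errors = n_err,
       error_types = err_types,
       corrected_n50 = n50(frag_lens),
       n_scaffolds = length(scaffolds))
}

n50 <- function(lens) {
  if (length(lens) == 0L) return(0)
  lens <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  lens[which(cumsum(lens) >= half)[1L]]
}
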