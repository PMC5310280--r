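#' Default pipeline parameters
#'
#' @return Named list of tunables: \code{min_seg_len} (2), \code{min_identity}
#'   (0.90), \code{min_coverage} (0.80), \code{link_cutoff} (5),
#'   \code{alpha} (0.5), \code{l_sat} (10), \code{window} (NULL = estimated
#'   insert size), \code{gap_default} (100), \code{gap_min} (100),
#'   \code{gap_max} (10000), \code{repeat_depth_factor} (1.5).
#' @export
default_params <- function() {
  list(min_seg_len = 2L, min_identity = 0.90, min_coverage = 0.80,
       link_cutoff = 5L, alpha = 0.5, l_sat = 10, window = NULL,
       gap_default = 100, gap_min = 100, gap_max = 10000,
       repeat_depth_factor = 1.5)
}

#' Run the full scaffolding pipeline
#'
#' Identifies framework segments from the reference cluster table, indexes
#' the target contigs by them, merges contigs into ordered strings, refines
#' and extends adjacencies with paired-end links (when provided), and
#' attempts a circular pseudo-genome guided by the most prevalent
#' conflict-free reference segment permutation.  When every reference
#' permutation conflicts with the assembled strings, no pseudo-genome is
#' emitted and the verdict reports a novel arrangement.
#'
#' @param clusters Normalized cluster table of the references.
#' @param contig_seqs DNAStringSet of target contigs.
#' @param hits Gene-hit data.frame ([read_gene_hits()],
#'   [match_core_genes()] or [truth_gene_hits()]).
#' @param pairs Optional pair table from [read_pe_alignments()].
#' @param params Parameter list; see [default_params()].
#' @return List: \code{segments}, \code{permutations}, \code{indices},
#'   \code{strings} (resolved), \code{edges}, \code{votes},
#'   \code{compatible}, \code{guide}, \code{pseudo} (NULL on novel
#'   arrangement), \code{verdict}, \code{contig_seqs}.
#' @export
run_pipeline <- function(clusters, contig_seqs, hits, pairs = NULL,
                         params = default_params()) {
  prm <- utils::modifyList(default_params(), params)
  contig_lengths <- stats::setNames(Biostrings::width(contig_seqs),
                                    names(contig_seqs))
  orders <- build_core_orders(clusters)
  segments <- identify_segments(orders, min_seg_len = prm$min_seg_len)
  permutations <- derive_permutations(segments, orders)
  assigned <- assign_gene_hits(hits, min_identity = prm$min_identity,
                               min_coverage = prm$min_coverage)
  indices <- index_contigs(assigned, segments, contig_lengths)
  strings <- merge_strings(indices, segments, clusters,
                           gap_default = prm$gap_default)
  for (k in seq_along(strings$strings))
    strings$strings[[k]]$items$source <- "cgof"
  edges <- NULL
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    window <- if (is.null(prm$window)) estimate_insert_size(pairs)
    else prm$window
    counts <- count_pe_links(pairs, contig_lengths, window = window)
    filtered <- filter_links(counts, cutoff = prm$link_cutoff)
    classed <- classify_adjacency(filtered, strings)
    edges <- edge_confidence(classed, alpha = prm$alpha,
                             l_sat = prm$l_sat)
    depths <- contig_depths(pairs, contig_lengths)
    strings <- resolve_chains(strings, edges,
                              depths = depths,
                              gap_default = prm$gap_default,
                              repeat_depth_factor =
                                prm$repeat_depth_factor)
  }
  votes <- permutation_votes(permutations)
  compatible <- filter_conflicting(votes, strings)
  guide <- select_guide(compatible)
  has_arc <- any(vapply(strings$strings, function(s)
    !is.null(s$arc) && nrow(s$arc) > 0L, logical(1)))
  pseudo <- NULL
  verdict <- "novel arrangement"
  if (!is.null(guide) && has_arc) {
    pseudo <- build_pseudo_genome(strings, guide, contig_seqs,
                                  clusters = clusters,
                                  segments = segments,
                                  gap_min = prm$gap_min,
                                  gap_max = prm$gap_max)
    verdict <- "pseudo-genome"
  }
  list(segments = segments, permutations = permutations,
       indices = indices, strings = strings, edges = edges,
       votes = votes, compatible = compatible, guide = guide,
       pseudo = pseudo, verdict = verdict, contig_seqs = contig_seqs,
       params = prm)
}
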