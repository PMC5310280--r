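#' Build per-genome circular orders of single-copy core genes
#'
#' Restricts the cluster table to clusters present single-copy in every
#' requested genome (the core set), then sorts each genome's members by start
#' coordinate within each replicon.  The gene's strand becomes its sign in
#' the order.  Replicons are circular by default; no adjacency spans a
#' replicon boundary.
#'
#' @param clusters Normalized cluster table (see [read_cluster_table()]).
#' @param genomes Genomes to use; default all genomes in the table.
#' @param circular Logical: treat each replicon as circular (default TRUE).
#' @return List of per-genome core orders (class \code{core_order}), sorted by
#'   genome id.  Each has \code{genome_id} and \code{replicons}, a list of
#'   \code{list(replicon_id, ids, signs, circular)}.
#' @export
build_core_orders <- function(clusters, genomes = NULL, circular = TRUE) {
  if (is.null(genomes)) genomes <- sort(unique(clusters$genome_id))
  genomes <- sort(as.character(genomes))
  if (length(genomes) < 2L)
    stop("need at least 2 reference genomes, got ", length(genomes))
  tab <- clusters[clusters$genome_id %in% genomes, , drop = FALSE]
  # core = single-copy everywhere and present everywhere
  ok <- tab[tab$single_copy, , drop = FALSE]
  counts <- table(ok$cluster_id)
  multi_any <- unique(tab$cluster_id[!tab$single_copy])
  core <- setdiff(names(counts)[counts == length(genomes)], multi_any)
  if (length(core) == 0L)
    stop("no cluster is single-copy in all ", length(genomes), " genomes")
  ok <- ok[ok$cluster_id %in% core, , drop = FALSE]
  lapply(genomes, function(g) {
    sub <- ok[ok$genome_id == g, , drop = FALSE]
    reps <- lapply(sort(unique(sub$replicon_id)), function(r) {
      rr <- sub[sub$replicon_id == r, , drop = FALSE]
      rr <- rr[order(rr$start), , drop = FALSE]
      list(replicon_id = r, ids = rr$cluster_id,
           signs = as.integer(rr$strand), circular = circular)
    })
    structure(list(genome_id = g, replicons = reps), class = "core_order")
  })
}

#' Construct a core order directly from signed gene vectors
#'
#' Convenience constructor used heavily in tests and small examples: a signed
#' gene order like \code{c("+g1", "-g2")} or paired \code{ids}/\code{signs}.
#'
#' @param genome_id Genome identifier.
#' @param ids Character gene ids, or a single character vector of signed
#'   tokens (\code{"+g1"}, \code{"-g2"}) when \code{signs} is NULL.
#' @param signs Integer \code{+1}/\code{-1} vector, or NULL.
#' @param circular Circular topology flag.
#' @param replicon_id Replicon name.
#' @return A \code{core_order} object.
#' @export
core_order <- function(genome_id, ids, signs = NULL, circular = TRUE,
                       replicon_id = "chr") {
  if (is.null(signs)) {
    signs <- ifelse(substr(ids, 1L, 1L) == "-", -1L, 1L)
    ids <- sub("^[+-]", "", ids)
  }
  stopifnot(length(ids) == length(signs), all(signs %in% c(-1L, 1L)))
  structure(list(genome_id = genome_id,
                 replicons = list(list(replicon_id = replicon_id,
                                       ids = ids, signs = as.integer(signs),
                                       circular = circular))),
            class = "core_order")
}

# signed adjacency keys of one replicon, both reading directions
adjacency_keys <- function(ids, signs, circular) {
  n <- length(ids)
  if (n < 2L) return(character())
  i <- seq_len(if (circular) n else n - 1L)
  j <- if (circular) c(seq_len(n)[-1L], 1L) else i + 1L
  fwd <- paste(signs[i], ids[i], signs[j], ids[j], sep = "\r")
  rev <- paste(-signs[j], ids[j], -signs[i], ids[i], sep = "\r")
  c(fwd, rev)
}

order_adjacencies <- function(ord) {
  unlist(lapply(ord$replicons, function(r)
    adjacency_keys(r$ids, r$signs, r$circular)), use.names = FALSE)
}
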