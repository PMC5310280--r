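#' Read a core-gene cluster table
#'
#' Reads a TSV of ortholog-cluster gene placements on reference genomes, the
#' shape produced by pan-genome clustering pipelines: one row per placement of
#' a cluster member on a replicon.  The header must name at least
#' \code{cluster_id}, \code{genome_id}, \code{replicon_id}, \code{start},
#' \code{end} and \code{strand}.
#'
#' Coordinates are normalized to 0-based half-open internally.  Clusters with
#' more than one placement in a genome are not single-copy there; their rows
#' are retained but flagged, and downstream core-order construction excludes
#' them.
#'
#' @param path Path to a TSV file.
#' @param dialect Coordinate dialect of the input: \code{"one_based"}
#'   (inclusive start/end, the common GFF-like convention) or
#'   \code{"zero_based"} (half-open).
#' @return A data.frame with columns \code{cluster_id}, \code{genome_id},
#'   \code{replicon_id}, \code{start}, \code{end} (0-based half-open),
#'   \code{strand} (\code{+1}/\code{-1} integer) and \code{single_copy}
#'   (logical).  The attribute \code{"multi_copy"} lists the flagged
#'   (cluster_id, genome_id) pairs.
#' @export
read_cluster_table <- function(path, dialect = c("one_based", "zero_based")) {
  dialect <- match.arg(dialect)
  if (file.size(path) == 0L) {
    warning("empty cluster table: ", path)
    return(empty_cluster_table())
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  required <- c("cluster_id", "genome_id", "replicon_id",
                "start", "end", "strand")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("cluster table missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("cluster table has a header but no rows: ", path)
    return(empty_cluster_table())
  }
  as_cluster_table(df[required], dialect = dialect)
}

#' Normalize an in-memory cluster table
#'
#' @param df Data.frame with the six cluster-table columns.
#' @param dialect See [read_cluster_table()].
#' @return Normalized cluster table (see [read_cluster_table()]).
#' @export
as_cluster_table <- function(df, dialect = c("one_based", "zero_based")) {
  dialect <- match.arg(dialect)
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- which(is.na(start) | is.na(end) |
                 !(as.character(df$strand) %in% c("+", "-", "1", "-1")))
  if (length(bad) > 0L)
    stop("malformed cluster table row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  if (dialect == "one_based") start <- start - 1
  if (any(start >= end))
    stop("cluster table row(s) with start >= end after normalization: ",
         paste(which(start >= end) + 1L, collapse = ", "))
  strand <- ifelse(as.character(df$strand) %in% c("+", "1"), 1L, -1L)
  out <- data.frame(cluster_id = as.character(df$cluster_id),
                    genome_id = as.character(df$genome_id),
                    replicon_id = as.character(df$replicon_id),
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  key <- paste(out$cluster_id, out$genome_id, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  out$single_copy <- !(key %in% dup_keys)
  multi <- unique(out[!out$single_copy, c("cluster_id", "genome_id")])
  rownames(multi) <- NULL
  attr(out, "multi_copy") <- multi
  out
}

empty_cluster_table <- function() {
  out <- data.frame(cluster_id = character(), genome_id = character(),
                    replicon_id = character(), start = numeric(),
                    end = numeric(), strand = integer(),
                    single_copy = logical(), stringsAsFactors = FALSE)
  attr(out, "multi_copy") <- out[c("cluster_id", "genome_id")]
  out
}

#' Write a cluster table as TSV
#'
#' Inverse of [read_cluster_table()]; coordinates are emitted in the requested
#' dialect so that a write/read cycle is the identity.
#'
#' @param tab Normalized cluster table.
#' @param path Output path.
#' @param dialect Output coordinate dialect.
#' @export
write_cluster_table <- function(tab, path,
                                dialect = c("one_based", "zero_based")) {
  dialect <- match.arg(dialect)
  df <- tab[c("cluster_id", "genome_id", "replicon_id",
              "start", "end", "strand")]
  if (dialect == "one_based") df$start <- df$start + 1
  df$strand <- ifelse(df$strand > 0L, "+", "-")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
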