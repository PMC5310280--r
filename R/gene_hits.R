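#' Read core-gene alignment hits on contigs
#'
#' Ingests alignments of core-gene representative sequences against the
#' target's contigs, either in PSL layout (as emitted by BLAT-like aligners)
#' or in 12/13-column BLAST tabular layout.  Hits are normalized to a common
#' shape with an identity fraction and a query-coverage fraction; target spans
#' are always stored ascending with a separate strand field.
#'
#' For PSL, identity is \code{(matches + repMatches) / (matches + repMatches +
#' misMatches)} and coverage is \code{(qEnd - qStart) / qSize}.  For tabular
#' input the standard 12 columns carry no query length, so coverage needs
#' either a 13th \code{qlen} column or the \code{query_lengths} argument;
#' without both, coverage is set to 1 with a warning.
#'
#' @param path Alignment file.
#' @param format \code{"psl"} or \code{"tabular"}.
#' @param query_lengths Optional named numeric vector of query (gene) lengths,
#'   used to compute coverage for tabular input.
#' @param known_contigs Optional character vector; hits on other targets are
#'   dropped with a warning.
#' @return Data.frame with columns \code{query_id}, \code{target_id},
#'   \code{qstart}, \code{qend}, \code{tstart}, \code{tend} (0-based
#'   half-open), \code{strand} (\code{+1}/\code{-1}), \code{identity},
#'   \code{coverage}.
#' @export
read_gene_hits <- function(path, format = c("psl", "tabular"),
                           query_lengths = NULL, known_contigs = NULL) {
  format <- match.arg(format)
  hits <- switch(format,
                 psl = parse_psl(path),
                 tabular = parse_blast_tabular(path, query_lengths))
  if (!is.null(known_contigs)) {
    unknown <- !(hits$target_id %in% known_contigs)
    if (any(unknown)) {
      warning(sum(unknown), " hit(s) on unknown contig(s) dropped")
      hits <- hits[!unknown, , drop = FALSE]
      rownames(hits) <- NULL
    }
  }
  hits
}

parse_psl <- function(path) {
  lines <- readLines(path)
  # tolerate the optional psLayout 5-line header
  body <- grep("^[0-9]", lines, value = TRUE)
  if (length(body) == 0L) return(empty_hits())
  fields <- strsplit(body, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 21L))
    stop("PSL line(s) with fewer than 21 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:21))
  num <- function(j) as.numeric(m[, j])
  matches <- num(1); mism <- num(2); rep_m <- num(3)
  aligned <- matches + rep_m + mism
  data.frame(
    query_id = m[, 10], target_id = m[, 14],
    qstart = num(12), qend = num(13),
    tstart = num(16), tend = num(17),
    strand = ifelse(substr(m[, 9], 1L, 1L) == "-", -1L, 1L),
    identity = ifelse(aligned > 0, (matches + rep_m) / aligned, 0),
    coverage = (num(13) - num(12)) / num(11),
    stringsAsFactors = FALSE)
}

parse_blast_tabular <- function(path, query_lengths = NULL) {
  df <- tryCatch(
    utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                      comment.char = "#", quote = ""),
    error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) return(empty_hits())
  if (ncol(df) < 12L) stop("tabular hits need at least 12 columns")
  qlen <- if (ncol(df) >= 13L) {
    as.numeric(df[[13]])
  } else if (!is.null(query_lengths)) {
    unname(query_lengths[as.character(df[[1]])])
  } else {
    warning("no query lengths available; coverage set to 1")
    NA_real_
  }
  sstart <- as.numeric(df[[9]]); send <- as.numeric(df[[10]])
  minus <- sstart > send
  tstart <- ifelse(minus, send, sstart) - 1
  tend <- ifelse(minus, sstart, send)
  alen <- abs(as.numeric(df[[8]]) - as.numeric(df[[7]])) + 1
  cov <- if (all(is.na(qlen))) rep(1, nrow(df)) else alen / qlen
  data.frame(
    query_id = as.character(df[[1]]), target_id = as.character(df[[2]]),
    qstart = as.numeric(df[[7]]) - 1, qend = as.numeric(df[[8]]),
    tstart = tstart, tend = tend,
    strand = ifelse(minus, -1L, 1L),
    identity = as.numeric(df[[3]]) / 100,
    coverage = pmin(1, cov),
    stringsAsFactors = FALSE)
}

empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             qstart = numeric(), qend = numeric(),
             tstart = numeric(), tend = numeric(),
             strand = integer(), identity = numeric(), coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' Locate core genes on contigs with the built-in matcher
#'
#' A small substitution-tolerant matcher for workflows where no external
#' aligner output is available: every gene is searched on both strands of
#' every contig with up to \code{max_mismatch_rate} mismatches (no indels).
#' Intended for near-identical intra-species core genes; a real aligner's PSL
#' or tabular output through [read_gene_hits()] is the production path.
#'
#' @param genes DNAStringSet of core-gene representative sequences, named by
#'   cluster id.
#' @param contigs DNAStringSet of target contigs.
#' @param max_mismatch_rate Maximum mismatch fraction per gene (default 0.05).
#' @return Hit data.frame in the [read_gene_hits()] shape.
#' @export
match_core_genes <- function(genes, contigs, max_mismatch_rate = 0.05) {
  stopifnot(!is.null(names(genes)), !is.null(names(contigs)))
  out <- list()
  for (g in seq_along(genes)) {
    pat <- genes[[g]]
    glen <- length(pat)
    max_mm <- floor(max_mismatch_rate * glen)
    for (strand in c(1L, -1L)) {
      p <- if (strand > 0L) pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::vmatchPattern(p, contigs, max.mismatch = max_mm)
      for (ci in seq_along(hits)) {
        ir <- hits[[ci]]
        if (length(ir) == 0L) next
        st <- IRanges::start(ir); en <- IRanges::end(ir)
        keep <- st >= 1L & en <= length(contigs[[ci]])
        if (!any(keep)) next
        st <- st[keep]; en <- en[keep]
        mm <- vapply(seq_along(st), function(k) {
          Biostrings::neditAt(p, contigs[[ci]], at = st[k])
        }, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          query_id = names(genes)[g], target_id = names(contigs)[ci],
          qstart = 0, qend = glen,
          tstart = st - 1, tend = en,
          strand = strand,
          identity = 1 - mm / glen, coverage = 1,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
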