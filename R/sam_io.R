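#' Read paired-end alignments from a SAM file
#'
#' Loads primary alignments from a SAM file and joins mates by query name.
#' Secondary and supplementary records are ignored; orphan records (only one
#' record for a query name) are skipped and counted.  A pair is retained even
#' when one mate is unmapped — downstream link counting requires both mates
#' mapped and filters accordingly.
#'
#' @param path SAM file with paired flags set.
#' @return Data.frame with one row per pair: \code{pair_id}, then for each
#'   mate \code{contig}, \code{pos} (0-based leftmost), \code{width},
#'   \code{strand} (\code{+1}/\code{-1}) and \code{mapped}.  The attribute
#'   \code{"n_orphans"} reports skipped orphan records.
#' @export
read_pe_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "pos", "strand", "qwidth"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  qname <- rec$qname
  if (length(qname) == 0L) {
    out <- empty_pairs()
    attr(out, "n_orphans") <- 0L
    return(out)
  }
  is_first <- bitwAnd(rec$flag, 64L) > 0L
  unmapped <- bitwAnd(rec$flag, 4L) > 0L
  df <- data.frame(qname = qname,
                   contig = as.character(rec$rname),
                   pos = ifelse(unmapped, NA_real_, rec$pos - 1),
                   width = ifelse(is.na(rec$qwidth), 0L, rec$qwidth),
                   strand = ifelse(as.character(rec$strand) == "-", -1L, 1L),
                   mapped = !unmapped,
                   first = is_first,
                   stringsAsFactors = FALSE)
  tab <- table(df$qname)
  paired <- names(tab)[tab == 2L]
  n_orphans <- sum(tab != 2L)
  df <- df[df$qname %in% paired, , drop = FALSE]
  df <- df[order(df$qname, !df$first), , drop = FALSE]
  i1 <- seq(1L, nrow(df), by = 2L)
  i2 <- i1 + 1L
  out <- data.frame(pair_id = df$qname[i1],
                    contig_1 = df$contig[i1], pos_1 = df$pos[i1],
                    width_1 = df$width[i1], strand_1 = df$strand[i1],
                    mapped_1 = df$mapped[i1],
                    contig_2 = df$contig[i2], pos_2 = df$pos[i2],
                    width_2 = df$width[i2], strand_2 = df$strand[i2],
                    mapped_2 = df$mapped[i2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_orphans") <- n_orphans
  out
}

empty_pairs <- function() {
  data.frame(pair_id = character(),
             contig_1 = character(), pos_1 = numeric(), width_1 = integer(),
             strand_1 = integer(), mapped_1 = logical(),
             contig_2 = character(), pos_2 = numeric(), width_2 = integer(),
             strand_2 = integer(), mapped_2 = logical(),
             stringsAsFactors = FALSE)
}
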