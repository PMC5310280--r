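#' Write identified segments as TSV
#'
#' One row per segment: id and the signed gene list in canonical
#' orientation.  [read_segments_tsv()] restores the object exactly.
#'
#' @param segments \code{cgof_segments} object.
#' @param path Output path.
#' @export
write_segments_tsv <- function(segments, path) {
  df <- data.frame(
    segment_id = vapply(segments$segments, `[[`, "", "segment_id"),
    genes = vapply(segments$segments, function(s)
      paste(paste0(ifelse(s$signs > 0L, "+", "-"), s$ids),
            collapse = ","), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments back from TSV
#'
#' @param path TSV written by [write_segments_tsv()].
#' @return \code{cgof_segments} object.
#' @export
read_segments_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  segs <- lapply(seq_len(nrow(df)), function(k) {
    tok <- strsplit(df$genes[k], ",", fixed = TRUE)[[1L]]
    list(segment_id = df$segment_id[k],
         ids = sub("^[+-]", "", tok),
         signs = ifelse(substr(tok, 1L, 1L) == "-", -1L, 1L))
  })
  gene_segment <- gene_sign <- character(0)
  gene_index <- integer(0)
  for (s in segs) {
    gene_segment[s$ids] <- s$segment_id
    gene_index[s$ids] <- seq_along(s$ids)
    gene_sign[s$ids] <- as.character(s$signs)
  }
  sign_int <- as.integer(gene_sign)
  names(sign_int) <- names(gene_sign)
  structure(list(segments = segs, gene_segment = gene_segment,
                 gene_index = gene_index, gene_sign = sign_int),
            class = "cgof_segments")
}

#' Write per-genome segment permutations as TSV
#'
#' @param permutations List from [derive_permutations()].
#' @param path Output path.
#' @export
write_permutations_tsv <- function(permutations, path) {
  df <- data.frame(
    genome_id = vapply(permutations, `[[`, "", "genome_id"),
    permutation = vapply(permutations, function(p)
      paste(paste0(ifelse(p$seg_signs > 0L, "+", "-"), p$seg_ids),
            collapse = ","), ""),
    circular = vapply(permutations, `[[`, TRUE, "circular"),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read permutations back from TSV
#'
#' @param path TSV written by [write_permutations_tsv()].
#' @return List of permutations.
#' @export
read_permutations_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(k) {
    tok <- strsplit(df$permutation[k], ",", fixed = TRUE)[[1L]]
    list(genome_id = df$genome_id[k],
         seg_ids = sub("^[+-]", "", tok),
         seg_signs = ifelse(substr(tok, 1L, 1L) == "-", -1L, 1L),
         circular = df$circular[k])
  })
}

#' Write scaffold strings as TSV
#'
#' @param strings \code{scaffold_strings} object.
#' @param path Output path.
#' @export
write_strings_tsv <- function(strings, path) {
  rows <- lapply(strings$strings, function(s) {
    it <- s$items
    data.frame(string_id = s$string_id,
               idx = seq_len(nrow(it)),
               contig_id = it$contig_id,
               orient = ifelse(it$orient > 0L, "+", "-"),
               gap_after = ifelse(is.na(it$gap_after), ".",
                                  as.character(it$gap_after)),
               segments = if (!is.null(s$arc) && nrow(s$arc) > 0L)
                 paste(paste0(ifelse(s$arc$orient > 0L, "+", "-"),
                              s$arc$segment_id), collapse = ",")
               else ".",
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows) > 0L) do.call(rbind, rows)
  else data.frame(string_id = character(), idx = integer(),
                  contig_id = character(), orient = character(),
                  gap_after = character(), segments = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the link-edge table as TSV
#'
#' @param edges Classified, confidence-scored edge table.
#' @param path Output path.
#' @export
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an AGP 2.1 description of a pseudo-genome or scaffold
#'
#' Components are emitted 1-based inclusive; contig (W) and gap (N) lines
#' tile the object with no overlap and no uncovered base.
#'
#' @param placements Contig placements (contig_id, orient, start, end;
#'   0-based half-open on the object).
#' @param object_len Total object length.
#' @param object_id Object name.
#' @param path Output path.
#' @param evidence Linkage evidence tag for gap lines (default
#'   \code{"align_genus"}, the reference-guided evidence class).
#' @export
write_agp <- function(placements, object_len, object_id, path,
                      evidence = "align_genus") {
  pl <- placements[order(placements$start), , drop = FALSE]
  lines <- character(0)
  part <- 0L
  cursor <- 0
  emit_gap <- function(from, to) {
    part <<- part + 1L
    lines <<- c(lines, paste(object_id, from + 1, to, part, "N",
                             to - from, "scaffold", "yes", evidence,
                             sep = "\t"))
  }
  for (k in seq_len(nrow(pl))) {
    if (pl$start[k] > cursor) emit_gap(cursor, pl$start[k])
    part <- part + 1L
    lines <- c(lines, paste(object_id, pl$start[k] + 1, pl$end[k], part,
                            "W", pl$contig_id[k], 1,
                            pl$end[k] - pl$start[k],
                            ifelse(pl$orient[k] > 0L, "+", "-"),
                            sep = "\t"))
    cursor <- pl$end[k]
  }
  if (cursor < object_len) emit_gap(cursor, object_len)
  writeLines(c("##agp-version\t2.1", lines), path)
  invisible(path)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the segment and permutation tables, the string/edge reports, and
#' either the circular pseudo-genome (FASTA with a topology tag, AGP 2.1,
#' guide report, unverified-adjacency list, leftovers FASTA) or, when the
#' target shows a novel arrangement, the draft strings FASTA and a report
#' stating the verdict.
#'
#' @param result Result list from [run_pipeline()].
#' @param outdir Output directory (created if needed).
#' @return \code{outdir}, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok || file.access(outdir, 2L) != 0L)
    stop("cannot write to output directory: ", outdir)
  p <- function(f) file.path(outdir, f)
  write_segments_tsv(result$segments, p("segments.tsv"))
  write_permutations_tsv(result$permutations, p("permutations.tsv"))
  write_strings_tsv(result$strings, p("strings.tsv"))
  if (!is.null(result$edges)) write_edges_tsv(result$edges, p("edges.tsv"))
  status <- vapply(result$strings$indices, `[[`, "", "status")
  names(status) <- vapply(result$strings$indices, `[[`, "", "contig_id")
  utils::write.table(
    data.frame(contig_id = names(status), status = unname(status)),
    p("contig_status.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  verdicts <- attr(result$compatible, "verdicts")
  if (!is.null(verdicts))
    utils::write.table(verdicts, p("guide_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(result$pseudo)) {
    ps <- result$pseudo
    out <- Biostrings::DNAStringSet(ps$seq)
    names(out) <- paste0("pseudo_genome topology=circular guide=",
                         ps$guide$key)
    Biostrings::writeXStringSet(out, p("pseudo.fasta"))
    write_agp(ps$placements, length(ps$seq), "pseudo_genome",
              p("pseudo.agp"))
    if (!is.null(ps$unverified))
      utils::write.table(ps$unverified, p("unverified_adjacencies.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(ps$leftovers) > 0L)
      Biostrings::writeXStringSet(result$contig_seqs[ps$leftovers],
                                  p("leftovers.fasta"))
    writeLines("verdict\tpseudo-genome", p("verdict.tsv"))
  } else {
    draft <- draft_fasta(result)
    Biostrings::writeXStringSet(draft, p("draft.fasta"))
    writeLines("verdict\tnovel arrangement", p("verdict.tsv"))
  }
  invisible(outdir)
}

# concatenate each string's contigs (with N gaps) into draft scaffolds
draft_fasta <- function(result) {
  seqs <- lapply(result$strings$strings, function(s) {
    it <- s$items
    pieces <- list()
    for (k in seq_len(nrow(it))) {
      sq <- result$contig_seqs[[it$contig_id[k]]]
      if (it$orient[k] < 0L) sq <- Biostrings::reverseComplement(sq)
      pieces[[length(pieces) + 1L]] <- sq
      if (k < nrow(it)) {
        g <- it$gap_after[k]
        if (is.na(g)) g <- 100
        pieces[[length(pieces) + 1L]] <- n_run(max(1, round(g)))
      }
    }
    do.call(Biostrings::xscat, pieces)
  })
  placed <- unlist(lapply(result$strings$strings,
                          function(s) s$items$contig_id))
  left <- setdiff(names(result$contig_seqs), placed)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- vapply(result$strings$strings, `[[`, "", "string_id")
  c(out, result$contig_seqs[left])
}
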