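#' Configuration for the synthetic pangenome simulator
#'
#' Defaults emulate the benchmark regime the method targets: a panel of
#' complete references of one bacterial species whose core genes keep
#' within-segment synteny while segments rearrange between strains, a target
#' drawn from (or deliberately outside) the reference architectures, draft
#' contigs, and 2 x 100 bp paired-end reads with a 0.02 base error rate and
#' deep (100x) coverage.
#'
#' @param n_refs Number of reference genomes (default 5).
#' @param n_core Number of single-copy core genes (default 200).
#' @param n_dispensable Number of dispensable genes, each absent from at
#'   least one genome (default 40).
#' @param gene_len_range Gene length bounds in bp (default 300-600).
#' @param spacer_len_range Intergenic spacer bounds in bp (default 40-120).
#' @param n_segments Number of framework segments (default 3).
#' @param rearrangement \code{"free"} (segments shuffle and flip freely) or
#'   \code{"symmetric"} (order fixed, segments flip around the
#'   origin-terminus axis).
#' @param target_mode \code{"reference"} (target architecture drawn from the
#'   panel) or \code{"novel"} (architecture matching no reference).
#' @param n_repeat_copies Copies of a planted repeat element in the target
#'   (default 0).
#' @param repeat_len Planted repeat length (default 500).
#' @param n_breaks Contig breaks in the target (default 39).
#' @param min_contig Minimum contig length in bp (default 300).
#' @param read_len Read length (default 100).
#' @param insert_mean,insert_sd Insert size distribution (default 500/50).
#' @param error_rate Per-base substitution rate (default 0.02).
#' @param coverage Sequence coverage of the PE library (default 100).
#' @param seed Integer seed driving all randomness.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_refs = 5L, n_core = 200L, n_dispensable = 40L,
                       gene_len_range = c(300L, 600L),
                       spacer_len_range = c(40L, 120L),
                       n_segments = 3L,
                       rearrangement = c("free", "symmetric"),
                       target_mode = c("reference", "novel"),
                       n_repeat_copies = 0L, repeat_len = 500L,
                       n_breaks = 39L, min_contig = 300L,
                       read_len = 100L, insert_mean = 500, insert_sd = 50,
                       error_rate = 0.02, coverage = 100, seed = 1L) {
  rearrangement <- match.arg(rearrangement)
  target_mode <- match.arg(target_mode)
  stopifnot(n_refs >= 2L, n_core >= 2L * n_segments, n_segments >= 1L,
            error_rate >= 0, error_rate < 1,
            insert_mean > 2 * read_len)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a pangenome of rearranged references plus a target genome
#'
#' Every reference carries all core genes single-copy with conserved
#' within-segment order; segment permutations differ between references
#' according to the rearrangement model.  Dispensable genes are present in
#' random proper subsets of the genomes at genome-specific positions.  The
#' target's architecture is drawn from the reference panel, or constructed
#' to match none of them in \code{"novel"} mode.
#'
#' @param cfg A [sim_config()].
#' @return List: \code{clusters} (normalized cluster table over the
#'   references), \code{gene_seqs} (DNAStringSet of core-gene
#'   representatives), \code{ref_seqs} (DNAStringSet), \code{truth} (list
#'   with the target sequence, its gene coordinates, the configured segment
#'   blocks, per-genome permutations, the target permutation, and planted
#'   repeat intervals).
#' @export
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_core <- cfg$n_core
  core_ids <- sprintf("g%04d", seq_len(n_core))
  disp_ids <- if (cfg$n_dispensable > 0L)
    sprintf("d%04d", seq_len(cfg$n_dispensable)) else character(0)
  gene_len <- sample(seq(cfg$gene_len_range[1L], cfg$gene_len_range[2L]),
                     n_core + cfg$n_dispensable, replace = TRUE)
  names(gene_len) <- c(core_ids, disp_ids)
  gene_seq <- vapply(gene_len, random_dna, "")
  base_sign <- sample(c(1L, -1L), n_core, replace = TRUE)
  # contiguous segment blocks, each with at least 2 genes
  blocks <- segment_blocks(n_core, cfg$n_segments)
  # per-genome permutations of the blocks
  ref_ids <- sprintf("R%02d", seq_len(cfg$n_refs))
  perms <- lapply(ref_ids, function(g) random_block_perm(cfg))
  names(perms) <- ref_ids
  # dispensable presence: random proper subsets
  disp_presence <- matrix(FALSE, nrow = cfg$n_dispensable,
                          ncol = cfg$n_refs,
                          dimnames = list(disp_ids, ref_ids))
  for (d in seq_len(cfg$n_dispensable)) {
    repeat {
      row <- stats::runif(cfg$n_refs) < 0.5
      if (!all(row)) break
    }
    disp_presence[d, ] <- row
  }
  repeat_seq <- if (cfg$n_repeat_copies > 0L) random_dna(cfg$repeat_len)
  else NULL
  build <- function(genome_id, perm, with_repeats = FALSE) {
    order_df <- expand_block_perm(perm, blocks, core_ids, base_sign)
    # insert dispensable genes at random slots
    if (genome_id %in% ref_ids) {
      present <- disp_ids[disp_presence[, genome_id]]
    } else {
      present <- disp_ids[stats::runif(length(disp_ids)) < 0.5]
    }
    for (d in present) {
      slot <- sample(nrow(order_df) + 1L, 1L)
      row <- data.frame(id = d, sign = sample(c(1L, -1L), 1L),
                        stringsAsFactors = FALSE)
      order_df <- rbind(order_df[seq_len(slot - 1L), ], row,
                        order_df[seq(slot, length.out =
                                       nrow(order_df) - slot + 1L), ])
    }
    rep_slots <- if (with_repeats && cfg$n_repeat_copies > 0L)
      sort(sample(nrow(order_df), cfg$n_repeat_copies)) else integer(0)
    pieces <- character(0)
    coords <- list()
    pos <- 0
    rep_iv <- list()
    for (k in seq_len(nrow(order_df))) {
      sp <- random_dna(sample(seq(cfg$spacer_len_range[1L],
                                  cfg$spacer_len_range[2L]), 1L))
      pieces <- c(pieces, sp); pos <- pos + nchar(sp)
      id <- order_df$id[k]
      gs <- gene_seq[[id]]
      if (order_df$sign[k] < 0L)
        gs <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(gs)))
      pieces <- c(pieces, gs)
      coords[[length(coords) + 1L]] <- data.frame(
        cluster_id = id, genome_id = genome_id, replicon_id = "chr",
        start = pos, end = pos + nchar(gs), strand = order_df$sign[k],
        stringsAsFactors = FALSE)
      pos <- pos + nchar(gs)
      if (k %in% rep_slots) {
        pieces <- c(pieces, repeat_seq)
        rep_iv[[length(rep_iv) + 1L]] <- c(pos, pos + cfg$repeat_len)
        pos <- pos + cfg$repeat_len
      }
    }
    list(seq = paste(pieces, collapse = ""),
         coords = do.call(rbind, coords),
         repeat_intervals = rep_iv)
  }
  refs <- lapply(ref_ids, function(g) build(g, perms[[g]]))
  names(refs) <- ref_ids
  # target permutation
  ref_keys <- vapply(perms, function(p) block_perm_key(p, cfg$n_segments),
                     "")
  if (cfg$target_mode == "reference") {
    target_perm <- perms[[sample(cfg$n_refs, 1L)]]
  } else {
    # block adjacencies conserved in every reference will merge into one
    # framework segment; a usable novel architecture must keep those
    # adjacencies intact while differing canonically from every reference
    conserved <- Reduce(intersect, lapply(perms, function(p)
      adjacency_keys(paste0("B", p$order), p$signs, circular = TRUE)))
    target_perm <- NULL
    for (try in seq_len(5000L)) {
      cand <- random_block_perm(cfg, free_override = TRUE)
      keys <- adjacency_keys(paste0("B", cand$order), cand$signs,
                             circular = TRUE)
      if (!all(conserved %in% keys)) next
      if (!(block_perm_key(cand, cfg$n_segments) %in% ref_keys)) {
        target_perm <- cand; break
      }
    }
    if (is.null(target_perm))
      stop("could not draw a novel architecture; too few segments")
  }
  target <- build("target", target_perm, with_repeats = TRUE)
  clusters <- as_cluster_table(
    do.call(rbind, lapply(refs, `[[`, "coords")), dialect = "zero_based")
  truth <- list(
    target_seq = Biostrings::DNAString(target$seq),
    target_coords = as_cluster_table(target$coords,
                                     dialect = "zero_based"),
    repeat_intervals = target$repeat_intervals,
    blocks = blocks, base_sign = base_sign, core_ids = core_ids,
    ref_perms = perms, target_perm = target_perm, cfg = cfg)
  list(clusters = clusters,
       gene_seqs = Biostrings::DNAStringSet(gene_seq[core_ids]),
       ref_seqs = Biostrings::DNAStringSet(
         vapply(refs, `[[`, "", "seq")),
       truth = truth)
}

segment_blocks <- function(n_core, n_segments) {
  if (n_segments == 1L) return(list(seq_len(n_core)))
  for (try in seq_len(1000L)) {
    cuts <- sort(sample(seq(2L, n_core - 2L), n_segments - 1L))
    sizes <- diff(c(0L, cuts, n_core))
    if (all(sizes >= 2L)) {
      bounds <- c(0L, cuts, n_core)
      return(lapply(seq_len(n_segments), function(i)
        seq(bounds[i] + 1L, bounds[i + 1L])))
    }
  }
  stop("cannot place segment boundaries: too many segments for n_core")
}

random_block_perm <- function(cfg, free_override = FALSE) {
  k <- cfg$n_segments
  if (cfg$rearrangement == "free" || free_override) {
    list(order = sample(k), signs = sample(c(1L, -1L), k, replace = TRUE))
  } else {
    list(order = seq_len(k), signs = sample(c(1L, -1L), k, replace = TRUE))
  }
}

expand_block_perm <- function(perm, blocks, core_ids, base_sign) {
  rows <- list()
  for (j in seq_along(perm$order)) {
    b <- blocks[[perm$order[j]]]
    if (perm$signs[j] > 0L) {
      ids <- core_ids[b]; signs <- base_sign[b]
    } else {
      ids <- rev(core_ids[b]); signs <- -rev(base_sign[b])
    }
    rows[[j]] <- data.frame(id = ids, sign = signs,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# canonical key of a block permutation (circular, reflection-invariant)
block_perm_key <- function(perm, n_segments) {
  canonicalize_permutation(paste0("B", perm$order), perm$signs,
                           circular = TRUE)$key
}

#' Fragment the target genome into draft contigs
#'
#' Breaks are placed uniformly, or inside planted repeat copies
#' (\code{"at-repeats"}), on the linearized target; every contig must reach
#' \code{min_contig} bp.  Contig names are shuffled so that input order
#' carries no positional signal.
#'
#' @param truth Truth list from [simulate_pangenome()].
#' @param n_breaks Number of breaks (default from the configuration).
#' @param policy \code{"uniform"} or \code{"at-repeats"}.
#' @return List: \code{contigs} (DNAStringSet), \code{placements}
#'   (data.frame contig_id, start, end, strand, in target order).
#' @export
fragment_target <- function(truth, n_breaks = NULL,
                            policy = c("uniform", "at-repeats")) {
  policy <- match.arg(policy)
  cfg <- truth$cfg
  set.seed((cfg$seed %% 536870000L) + 1L)
  if (is.null(n_breaks)) n_breaks <- cfg$n_breaks
  L <- length(truth$target_seq)
  min_len <- cfg$min_contig
  stopifnot(n_breaks < L / min_len)
  if (policy == "at-repeats") {
    centers <- vapply(truth$repeat_intervals, function(iv)
      floor((iv[1L] + iv[2L]) / 2), 0)
    if (length(centers) < n_breaks)
      stop("not enough repeat copies for ", n_breaks, " at-repeat breaks")
    breaks <- sort(centers[seq_len(n_breaks)])
  } else if (n_breaks == 0L) {
    breaks <- numeric(0)
  } else {
    # stick-breaking: every fragment gets min_len, the surplus is split
    # uniformly, so breaks stay uniform conditional on the length floor
    surplus <- L - (n_breaks + 1L) * min_len
    if (surplus < 0) stop("too many breaks for min_contig")
    cuts <- sort(stats::runif(n_breaks, 0, surplus))
    gaps <- min_len + diff(c(0, cuts, surplus))
    breaks <- round(cumsum(gaps[-length(gaps)]))
  }
  bounds <- c(0, breaks, L)
  n <- length(bounds) - 1L
  ids <- sprintf("c%03d", sample(n))
  placements <- data.frame(contig_id = ids,
                           start = bounds[-length(bounds)],
                           end = bounds[-1L], strand = 1L,
                           stringsAsFactors = FALSE)
  seqs <- Biostrings::DNAStringSet(truth$target_seq,
                                   start = placements$start + 1L,
                                   end = placements$end)
  names(seqs) <- placements$contig_id
  list(contigs = seqs, placements = placements)
}

#' Emit true core-gene hits on the fragmented contigs
#'
#' Converts the simulator's known gene coordinates into the alignment-hit
#' shape the pipeline ingests, clipping genes that span contig breaks
#' (their coverage drops accordingly).
#'
#' @param truth Truth list.
#' @param placements Contig placements from [fragment_target()].
#' @return Hit data.frame in the [read_gene_hits()] shape.
#' @export
truth_gene_hits <- function(truth, placements) {
  g <- truth$target_coords
  g <- g[substr(g$cluster_id, 1L, 1L) == "g", , drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(placements))) {
    p <- placements[k, ]
    ov <- g[g$end > p$start & g$start < p$end, , drop = FALSE]
    if (nrow(ov) == 0L) next
    lo <- pmax(ov$start, p$start); hi <- pmin(ov$end, p$end)
    glen <- ov$end - ov$start
    qlo <- ifelse(ov$strand > 0L, lo - ov$start, ov$end - hi)
    out[[length(out) + 1L]] <- data.frame(
      query_id = ov$cluster_id, target_id = p$contig_id,
      qstart = qlo, qend = qlo + (hi - lo),
      tstart = lo - p$start, tend = hi - p$start,
      strand = ov$strand, identity = 1,
      coverage = (hi - lo) / glen, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write truth gene hits as a 13-column BLAST-like tabular file
#'
#' @param hits Hit data.frame from [truth_gene_hits()].
#' @param gene_lengths Named vector of gene lengths.
#' @param path Output path.
#' @export
write_tabular_hits <- function(hits, gene_lengths, path) {
  alen <- hits$tend - hits$tstart
  sstart <- ifelse(hits$strand > 0L, hits$tstart + 1, hits$tend)
  send <- ifelse(hits$strand > 0L, hits$tend, hits$tstart + 1)
  df <- data.frame(hits$query_id, hits$target_id,
                   round(hits$identity * 100, 2), alen, 0L, 0L,
                   hits$qstart + 1, hits$qend, sstart, send,
                   0, 2 * alen,
                   unname(gene_lengths[hits$query_id]))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate a paired-end library from the target genome
#'
#' Pairs are drawn uniformly from the linearized target with normal insert
#' sizes; each mate receives independent per-base substitutions at the
#' configured error rate.  Forward mate reads the plus strand, reverse mate
#' the minus strand of the fragment's far end (FR orientation).
#'
#' @param truth Truth list.
#' @param cfg Configuration (default the one stored in \code{truth}).
#' @return List: \code{pair_id}, \code{pos1}, \code{insert} (fragment
#'   coordinates on the target), \code{r1}, \code{r2} (character reads).
#' @export
simulate_pe_reads <- function(truth, cfg = truth$cfg) {
  set.seed((cfg$seed %% 536870000L) + 2L)
  L <- length(truth$target_seq)
  rl <- cfg$read_len
  n_pairs <- round(cfg$coverage * L / (2 * rl))
  ins <- pmax(2 * rl + 10, round(stats::rnorm(n_pairs, cfg$insert_mean,
                                              cfg$insert_sd)))
  ins <- pmin(ins, L)
  p1 <- floor(stats::runif(n_pairs, min = 0, max = L - ins + 1))
  tgt <- as.character(truth$target_seq)
  r1 <- substring(tgt, p1 + 1, p1 + rl)
  r2_fwd <- substring(tgt, p1 + ins - rl + 1, p1 + ins)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2_fwd)))
  r1 <- inject_errors(r1, cfg$error_rate)
  r2 <- inject_errors(r2, cfg$error_rate)
  list(pair_id = sprintf("p%07d", seq_len(n_pairs)),
       pos1 = p1, insert = ins, r1 = r1, r2 = r2, read_len = rl)
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  rl <- nchar(reads[1L])
  nerr <- stats::rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample(rl, nerr[i])
    for (a in at) {
      old <- substr(reads[i], a, a)
      substr(reads[i], a, a) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Write the simulated library as FASTQ
#'
#' @param reads Read list from [simulate_pe_reads()].
#' @param prefix Output path prefix; writes \code{<prefix>_1.fastq} and
#'   \code{<prefix>_2.fastq}.
#' @return The two file paths, invisibly.
#' @export
write_pe_fastq <- function(reads, prefix) {
  qual <- strrep("I", reads$read_len)
  f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
  writeLines(as.vector(rbind(paste0("@", reads$pair_id, "/1"),
                             reads$r1, "+", qual)), f1)
  writeLines(as.vector(rbind(paste0("@", reads$pair_id, "/2"),
                             reads$r2, "+", qual)), f2)
  invisible(c(f1, f2))
}

#' Write the truth SAM of a simulated library against the contigs
#'
#' The simulator knows each read's exact origin, so the mapping step is
#' resolved by coordinate arithmetic: a mate maps to the contig that fully
#' contains its target interval, and is unmapped when it spans a contig
#' break.  This keeps tests aligner-free; production users supply a real
#' mapper's SAM.
#'
#' @param reads Read list from [simulate_pe_reads()].
#' @param placements Contig placements from [fragment_target()].
#' @param path Output SAM path.
#' @return \code{path}, invisibly.
#' @export
write_truth_sam <- function(reads, placements, path) {
  rl <- reads$read_len
  pl <- placements[order(placements$start), , drop = FALSE]
  locate <- function(from, to) {
    i <- findInterval(from, pl$start)
    ok <- i >= 1L & to <= pl$end[pmax(i, 1L)]
    list(contig = ifelse(ok, pl$contig_id[pmax(i, 1L)], "*"),
         pos = ifelse(ok, from - pl$start[pmax(i, 1L)] + 1, 0))
  }
  s1 <- reads$pos1; e1 <- s1 + rl
  s2 <- reads$pos1 + reads$insert - rl; e2 <- s2 + rl
  m1 <- locate(s1, e1); m2 <- locate(s2, e2)
  un1 <- m1$contig == "*"; un2 <- m2$contig == "*"
  flag1 <- 1L + 64L + 32L + ifelse(un1, 4L, 0L) + ifelse(un2, 8L, 0L)
  flag2 <- 1L + 128L + 16L + ifelse(un2, 4L, 0L) + ifelse(un1, 8L, 0L)
  qual <- strrep("I", rl)
  cig1 <- ifelse(un1, "*", paste0(rl, "M"))
  cig2 <- ifelse(un2, "*", paste0(rl, "M"))
  line1 <- paste(reads$pair_id, flag1, m1$contig, m1$pos,
                 ifelse(un1, 0L, 60L), cig1, "*", 0L, 0L,
                 reads$r1, qual, sep = "\t")
  line2 <- paste(reads$pair_id, flag2, m2$contig, m2$pos,
                 ifelse(un2, 0L, 60L), cig2, "*", 0L, 0L,
                 reads$r2, qual, sep = "\t")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           paste0("@SQ\tSN:", pl$contig_id, "\tLN:",
                  pl$end - pl$start))
  writeLines(c(hdr, as.vector(rbind(line1, line2))), path)
  invisible(path)
}
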