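test_that("circular canonicalization collapses rotations and reflections", {
  a <- canonicalize_permutation(c("S2", "S1"), c(1L, 1L))
  expect_equal(a$key, "+S1,+S2")
  b <- canonicalize_permutation(c("S2", "S1"), c(-1L, -1L))
  expect_equal(b$key, "+S1,+S2")                     # reflection
  expect_equal(canonicalize_permutation("S1", -1L)$key, "+S1")
  # a genome and its reverse complement count as one arrangement
  p <- c("S1", "S3", "S2"); s <- c(1L, -1L, 1L)
  expect_equal(canonicalize_permutation(p, s)$key,
               canonicalize_permutation(rev(p), -rev(s))$key)
})

test_that("votes tally prevalence over canonical patterns", {
  perms <- list(
    list(genome_id = "a", seg_ids = c("S1", "S2"), seg_signs = c(1L, 1L),
         circular = TRUE),
    list(genome_id = "b", seg_ids = c("S2", "S1"), seg_signs = c(1L, 1L),
         circular = TRUE),                            # same pattern rotated
    list(genome_id = "c", seg_ids = c("S1", "S2"), seg_signs = c(1L, -1L),
         circular = TRUE))
  v <- permutation_votes(perms)
  expect_equal(nrow(v), 2L)
  expect_equal(v$prevalence[v$key == "+S1,+S2"], 2L)
  expect_equal(v$genomes[v$key == "+S1,+S2"], "a,b")
})

test_that("patterns conflicting with witnessed junctions are removed", {
  perms <- list(
    list(genome_id = "a", seg_ids = c("S1", "S2", "S3"),
         seg_signs = c(1L, 1L, 1L), circular = TRUE),
    list(genome_id = "b", seg_ids = c("S1", "S2", "S3"),
         seg_signs = c(1L, -1L, 1L), circular = TRUE))
  v <- permutation_votes(perms)
  strings <- list(strings = list(list(
    string_id = "STR1",
    items = data.frame(contig_id = "A", orient = 1L, gap_after = NA,
                       stringsAsFactors = FALSE),
    arc = data.frame(segment_id = c("S1", "S2"), orient = c(1L, 1L),
                     stringsAsFactors = FALSE))))
  keep <- filter_conflicting(v, strings)
  expect_equal(keep$key, "+S1,+S2,+S3")
  verdicts <- attr(keep, "verdicts")
  expect_equal(sum(verdicts$compatible), 1L)
  # no witnessed junction: every pattern is vacuously compatible
  strings0 <- list(strings = list())
  expect_equal(nrow(filter_conflicting(v, strings0)), 2L)
})

test_that("guide selection follows prevalence then the genome tie rule", {
  v <- data.frame(key = c("P1", "P2"), prevalence = c(5L, 2L),
                  genomes = c("x,y,z,w,v", "a,b"),
                  stringsAsFactors = FALSE)
  attr(v, "patterns") <- list(
    P1 = list(seg_ids = "S1", seg_signs = 1L, key = "P1"),
    P2 = list(seg_ids = "S1", seg_signs = -1L, key = "P2"))
  expect_equal(select_guide(v)$key, "P1")
  # tie: the pattern supported by the lexicographically first genome wins
  v$prevalence <- c(3L, 3L)
  v$genomes <- c("b,c,d", "a,e,f")
  expect_equal(select_guide(v)$key, "P2")
  expect_null(select_guide(v[0, , drop = FALSE]))
})

test_that("guide selection agrees with exhaustive compatibility checking", {
  set.seed(314)
  for (trial in 1:40) {
    n_seg <- sample(2:5, 1L)
    n_ref <- sample(2:6, 1L)
    sids <- paste0("S", seq_len(n_seg))
    perms <- lapply(seq_len(n_ref), function(i)
      list(genome_id = sprintf("G%02d", i),
           seg_ids = sids[sample(n_seg)],
           seg_signs = sample(c(1L, -1L), n_seg, replace = TRUE),
           circular = TRUE))
    # witness 0-2 junctions drawn from one of the reference patterns
    w <- perms[[sample(n_ref, 1L)]]
    n_wit <- sample(0:min(2L, n_seg), 1L)
    arcs <- list()
    if (n_wit > 0L) {
      for (j in seq_len(n_wit)) {
        i <- sample(n_seg, 1L)
        k <- if (i == n_seg) 1L else i + 1L
        arcs[[j]] <- list(
          string_id = paste0("STR", j),
          items = data.frame(contig_id = paste0("c", j), orient = 1L,
                             gap_after = NA, stringsAsFactors = FALSE),
          arc = data.frame(segment_id = c(w$seg_ids[i], w$seg_ids[k]),
                           orient = c(w$seg_signs[i], w$seg_signs[k]),
                           stringsAsFactors = FALSE))
      }
    }
    strings <- list(strings = arcs)
    votes <- permutation_votes(perms)
    got <- select_guide(filter_conflicting(votes, strings))
    # oracle: check every pattern against every witnessed junction with an
    # independent circular scan, then apply prevalence + tie rule by hand
    patterns <- attr(votes, "patterns")
    compat <- vapply(votes$key, function(key) {
      p <- patterns[[key]]
      all(vapply(arcs, function(a)
        oracle_pattern_has_adjacency(p$seg_ids, p$seg_signs,
                                     a$arc$segment_id[1L], a$arc$orient[1L],
                                     a$arc$segment_id[2L], a$arc$orient[2L]),
        logical(1)))
    }, logical(1))
    cand <- votes[compat, , drop = FALSE]
    if (nrow(cand) == 0L) {
      expect_null(got, info = paste("trial", trial))
    } else {
      first_g <- vapply(strsplit(cand$genomes, ","), `[`, "", 1L)
      want_key <- cand$key[order(-cand$prevalence, first_g)][1L]
      expect_equal(got$key, want_key, info = paste("trial", trial))
    }
  }
})

test_that("pseudo-genome places strings along the guide with N gaps", {
  set.seed(12)
  x <- make_sim_inputs(12, n_segments = 2L, with_reads = FALSE)
  res <- run_pipeline(x$sim$clusters, x$frag$contigs, x$hits)
  expect_equal(res$verdict, "pseudo-genome")
  ps <- res$pseudo
  expect_equal(ps$topology, "circular")
  # induced permutation equals the guide pattern
  arc <- do.call(rbind, lapply(res$strings$strings, `[[`, "arc"))
  expect_equal(canonicalize_permutation(arc$segment_id, arc$orient)$key,
               ps$guide$key)
  # every placed contig appears verbatim or reverse-complemented
  for (k in seq_len(nrow(ps$placements))) {
    p <- ps$placements[k, ]
    sq <- Biostrings::subseq(ps$seq, p$start + 1L, p$end)
    orig <- res$contig_seqs[[p$contig_id]]
    if (p$orient < 0L) orig <- Biostrings::reverseComplement(orig)
    expect_equal(as.character(sq), as.character(orig))
  }
  # total non-N length equals the summed placed contig lengths
  non_n <- sum(Biostrings::alphabetFrequency(ps$seq)[c("A", "C", "G", "T")])
  expect_equal(non_n, sum(ps$placements$end - ps$placements$start))
})

test_that("guide-only junctions are reported as unverified", {
  set.seed(44)
  mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  contigs <- Biostrings::DNAStringSet(c(A = mkseq(800), B = mkseq(700)))
  strings <- list(strings = list(
    list(string_id = "STR1",
         items = data.frame(contig_id = "A", orient = 1L, gap_after = NA,
                            source = "cgof", stringsAsFactors = FALSE),
         arc = data.frame(segment_id = "S1", orient = 1L,
                          stringsAsFactors = FALSE)),
    list(string_id = "STR2",
         items = data.frame(contig_id = "B", orient = 1L, gap_after = NA,
                            source = "cgof", stringsAsFactors = FALSE),
         arc = data.frame(segment_id = "S2", orient = 1L,
                          stringsAsFactors = FALSE))))
  guide <- list(seg_ids = c("S1", "S2"), seg_signs = c(1L, 1L),
                key = "+S1,+S2")
  ps <- build_pseudo_genome(strings, guide, contigs)
  # A, N gap, B, N gap around the circle; both junctions are guide-only
  expect_equal(nrow(ps$placements), 2L)
  expect_equal(length(ps$seq), 800L + 700L + 200L)   # two 100 N gaps
  expect_equal(nrow(ps$unverified), 2L)
  expect_true(all(ps$unverified$support == "cgof_guide_only"))
})

test_that("a string spanning every segment circularizes as-is", {
  set.seed(45)
  mkseq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  contigs <- Biostrings::DNAStringSet(c(A = mkseq(900)))
  strings <- list(strings = list(
    list(string_id = "STR1",
         items = data.frame(contig_id = "A", orient = 1L, gap_after = NA,
                            source = "cgof", stringsAsFactors = FALSE),
         arc = data.frame(segment_id = c("S1", "S2"), orient = c(1L, 1L),
                          stringsAsFactors = FALSE))))
  guide <- list(seg_ids = c("S1", "S2"), seg_signs = c(1L, 1L),
                key = "+S1,+S2")
  ps <- build_pseudo_genome(strings, guide, contigs)
  expect_equal(as.character(ps$seq), as.character(contigs[["A"]]))
  expect_null(ps$unverified)
})

test_that("re-running on the emitted pseudo-genome reproduces it", {
  set.seed(3)
  fx <- make_identity_fixture(3)
  res <- run_pipeline(fx$clusters, fx$contigs, fx$hits)
  ps <- Biostrings::DNAStringSet(res$pseudo$seq)
  names(ps) <- "pseudo"
  hits2 <- truth_gene_hits(
    list(target_coords = local({
      g <- fx$clusters[fx$clusters$genome_id == "R01", ]
      # locate genes on the pseudo-genome via the placements
      pl <- res$pseudo$placements
      orig <- fx$placements
      rows <- list()
      for (k in seq_len(nrow(pl))) {
        src <- orig[orig$contig_id == pl$contig_id[k], ]
        gg <- g[g$start >= src$start & g$end <= src$end, ]
        if (nrow(gg) == 0L) next
        if (pl$orient[k] > 0L) {
          gg$start2 <- pl$start[k] + (gg$start - src$start)
          gg$end2 <- pl$start[k] + (gg$end - src$start)
          gg$strand2 <- gg$strand
        } else {
          gg$start2 <- pl$start[k] + (src$end - gg$end)
          gg$end2 <- pl$start[k] + (src$end - gg$start)
          gg$strand2 <- -gg$strand
        }
        rows[[length(rows) + 1L]] <- data.frame(
          cluster_id = gg$cluster_id, genome_id = "target",
          replicon_id = "chr", start = gg$start2, end = gg$end2,
          strand = gg$strand2, stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })),
    data.frame(contig_id = "pseudo", start = 0,
               end = length(res$pseudo$seq), strand = 1L,
               stringsAsFactors = FALSE))
  res2 <- run_pipeline(fx$clusters, ps, hits2)
  expect_equal(res2$verdict, "pseudo-genome")
  expect_equal(as.character(res2$pseudo$seq), as.character(res$pseudo$seq))
})
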