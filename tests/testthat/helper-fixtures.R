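# Small simulated pipelines shared across test files.  Sizes are kept well
# below the acceptance-scale runs so unit files stay fast.

make_sim_inputs <- function(seed, n_refs = 4L, n_core = 60L,
                            n_segments = 3L, n_breaks = 12L,
                            coverage = 40, with_reads = TRUE,
                            target_mode = "reference",
                            n_dispensable = 10L, ...) {
  cfg <- sim_config(n_refs = n_refs, n_core = n_core,
                    n_segments = n_segments, n_breaks = n_breaks,
                    coverage = coverage, target_mode = target_mode,
                    n_dispensable = n_dispensable, seed = seed, ...)
  sim <- simulate_pangenome(cfg)
  frag <- fragment_target(sim$truth)
  hits <- truth_gene_hits(sim$truth, frag$placements)
  pairs <- NULL
  if (with_reads) {
    reads <- simulate_pe_reads(sim$truth)
    sam <- tempfile(fileext = ".sam")
    write_truth_sam(reads, frag$placements, sam)
    pairs <- read_pe_alignments(sam)
    unlink(sam)
  }
  list(cfg = cfg, sim = sim, frag = frag, hits = hits, pairs = pairs)
}

# a panel of identical references plus contigs that exactly tile one of
# them, broken only inside intergenic spacers so every contig carries genes
make_identity_fixture <- function(seed, n_core = 60L, n_contigs = 10L) {
  cfg <- sim_config(n_refs = 3L, n_core = n_core, n_segments = 2L,
                    n_dispensable = 0L, seed = seed)
  sim <- simulate_pangenome(cfg)
  ref <- sim$ref_seqs[["R01"]]
  cl <- sim$clusters[sim$clusters$genome_id == "R01", ]
  cl3 <- do.call(rbind, lapply(c("R01", "R02", "R03"), function(g) {
    x <- cl; x$genome_id <- g; x
  }))
  cl3 <- as_cluster_table(
    data.frame(cl3[c("cluster_id", "genome_id", "replicon_id",
                     "start", "end")],
               strand = ifelse(cl3$strand > 0L, "+", "-")),
    dialect = "zero_based")
  g <- cl[order(cl$start), ]
  step <- floor(n_core / n_contigs)
  bidx <- seq(step, by = step, length.out = n_contigs - 1L)
  breaks <- floor((g$end[bidx] + g$start[bidx + 1L]) / 2)
  bounds <- c(0, breaks, length(ref))
  ids <- sprintf("c%02d", sample(n_contigs))
  pl <- data.frame(contig_id = ids, start = bounds[-length(bounds)],
                   end = bounds[-1L], strand = 1L,
                   stringsAsFactors = FALSE)
  contigs <- Biostrings::DNAStringSet(ref, start = pl$start + 1L,
                                      end = pl$end)
  names(contigs) <- pl$contig_id
  hits <- truth_gene_hits(
    list(target_coords = cl3[cl3$genome_id == "R01", ]), pl)
  list(ref = ref, clusters = cl3, contigs = contigs, placements = pl,
       hits = hits)
}

seq_rotations_equal <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(b, b)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  grepl(a, doubled, fixed = TRUE) || grepl(rc, doubled, fixed = TRUE)
}
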