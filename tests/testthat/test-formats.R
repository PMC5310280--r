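test_that("cluster table normalizes coordinates and flags multi-copy rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tgenome_id\treplicon_id\tstart\tend\tstrand",
               "g1\tA\tchr\t101\t200\t+",
               "g2\tA\tchr\t300\t400\t-",
               "g2\tA\tchr\t500\t600\t-",
               "g1\tB\tchr\t11\t90\t+"), path)
  tab <- read_cluster_table(path, dialect = "one_based")
  r <- tab[tab$cluster_id == "g1" & tab$genome_id == "A", ]
  expect_equal(r$start, 100)                 # 1-based inclusive -> half-open
  expect_equal(r$end, 200)
  expect_false(any(tab$single_copy[tab$cluster_id == "g2"]))
  expect_equal(attr(tab, "multi_copy")$cluster_id, "g2")
  # round trip is the identity in both dialects
  out <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(tab, out, dialect = "one_based")
  back <- read_cluster_table(out, dialect = "one_based")
  expect_equal(back$start, tab$start)
  expect_equal(back$end, tab$end)
  expect_equal(back$strand, tab$strand)
})

test_that("empty and malformed cluster tables are handled", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(tab <- read_cluster_table(empty), "empty")
  expect_equal(nrow(tab), 0L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tgenome_id\treplicon_id\tstart\tend\tstrand",
               "g1\tA\tchr\tx\t200\t+"), bad)
  expect_error(read_cluster_table(bad), "line")
})

test_that("PSL hits compute identity and coverage from PSL arithmetic", {
  # 950 matches + 50 mismatches over a fully aligned 1000 bp gene
  psl <- paste(c(950, 50, 0, 0, 0, 0, 0, 0, "+", "geneA", 1000, 0, 1000,
                 "ctg1", 5000, 1200, 2200, 1, 1000, 0, 1200),
               collapse = "\t")
  path <- withr::local_tempfile(fileext = ".psl")
  writeLines(psl, path)
  h <- read_gene_hits(path, "psl")
  expect_equal(h$identity, 0.95)
  expect_equal(h$coverage, 1.0)
  expect_equal(h$strand, 1L)
  # partial span: coverage follows the query span
  psl2 <- paste(c(400, 0, 0, 0, 0, 0, 0, 0, "-", "geneB", 1000, 100, 500,
                  "ctg2", 5000, 0, 400, 1, 400, 100, 0),
                collapse = "\t")
  writeLines(psl2, path)
  h2 <- read_gene_hits(path, "psl")
  expect_equal(h2$identity, 1.0)
  expect_equal(h2$coverage, 0.4)
  expect_equal(h2$strand, -1L)
  expect_true(h2$tstart < h2$tend)          # target span stays ascending
})

test_that("tabular hits normalize strand and use qlen for coverage", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("geneA", "ctg1", "100.00", 500, 0, 0, 1, 500,
                     1001, 1500, "1e-50", 900, 500, sep = "\t"),
               paste("geneB", "ctg1", "98.00", 400, 8, 0, 1, 400,
                     2400, 2001, "1e-40", 700, 500, sep = "\t")), path)
  h <- read_gene_hits(path, "tabular")
  expect_equal(h$identity, c(1.0, 0.98))
  expect_equal(h$coverage, c(1.0, 0.8))
  expect_equal(h$strand, c(1L, -1L))
  expect_equal(h$tstart[2], 2000)           # minus hit, ascending span
  expect_equal(h$tend[2], 2400)
  # hits on unknown contigs are dropped with a warning
  expect_warning(h3 <- read_gene_hits(path, "tabular",
                                      known_contigs = "other"),
                 "dropped")
  expect_equal(nrow(h3), 0L)
})

test_that("SAM pairs are joined by name; orphans and mates handled", {
  path <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               "@SQ\tSN:ctg1\tLN:2000", "@SQ\tSN:ctg2\tLN:1500",
               paste("p1", 99, "ctg1", 101, 60, "100M", "=", 301, 300,
                     strrep("A", 100), strrep("I", 100), sep = "\t"),
               paste("p1", 147, "ctg1", 301, 60, "100M", "=", 101, -300,
                     strrep("A", 100), strrep("I", 100), sep = "\t"),
               paste("p2", 73, "ctg2", 51, 60, "100M", "*", 0, 0,
                     strrep("A", 100), strrep("I", 100), sep = "\t"),
               paste("p2", 133, "*", 0, 0, "*", "*", 0, 0,
                     strrep("A", 100), strrep("I", 100), sep = "\t"),
               paste("orphan", 65, "ctg1", 501, 60, "100M", "*", 0, 0,
                     strrep("A", 100), strrep("I", 100), sep = "\t")),
             path)
  pairs <- read_pe_alignments(path)
  expect_equal(nrow(pairs), 2L)
  expect_equal(attr(pairs, "n_orphans"), 1L)
  p1 <- pairs[pairs$pair_id == "p1", ]
  expect_equal(p1$pos_1, 100)               # SAM 1-based -> 0-based
  expect_true(p1$mapped_1 && p1$mapped_2)
  p2 <- pairs[pairs$pair_id == "p2", ]
  expect_false(p2$mapped_2)
})

test_that("segments and permutations TSVs round-trip exactly", {
  o1 <- core_order("R1", c("+g1", "+g2", "+g3", "+g4"), circular = FALSE)
  o2 <- core_order("R2", c("+g1", "+g2", "-g4", "-g3"), circular = FALSE)
  segs <- identify_segments(list(o1, o2), 2)
  perms <- derive_permutations(segs, list(o1, o2))
  d <- withr::local_tempdir()
  f1 <- file.path(d, "segments.tsv")
  f2 <- file.path(d, "permutations.tsv")
  write_segments_tsv(segs, f1)
  segs2 <- read_segments_tsv(f1)
  expect_equal(segs2$segments, segs$segments)
  expect_equal(segs2$gene_segment, segs$gene_segment)
  write_permutations_tsv(perms, f2)
  perms2 <- read_permutations_tsv(f2)
  expect_equal(lapply(perms2, `[`, c("genome_id", "seg_ids", "seg_signs")),
               lapply(perms, `[`, c("genome_id", "seg_ids", "seg_signs")))
})

test_that("AGP components tile the object with no overlap or gap", {
  pl <- data.frame(contig_id = c("c1", "c2", "c3"),
                   orient = c(1L, -1L, 1L),
                   start = c(0, 1200, 2500), end = c(1000, 2300, 3100))
  path <- withr::local_tempfile(fileext = ".agp")
  write_agp(pl, object_len = 3300, object_id = "obj", path = path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- do.call(rbind, strsplit(body, "\t"))
  starts <- as.numeric(f[, 2]); ends <- as.numeric(f[, 3])
  expect_equal(starts[1], 1)
  expect_equal(ends[length(ends)], 3300)
  expect_equal(starts[-1L], ends[-length(ends)] + 1)   # perfect tiling
  expect_equal(sum(f[, 5] == "W"), 3L)
  expect_equal(sum(f[, 5] == "N"), 3L)                 # 2 inner + 1 trailing
  expect_equal(f[f[, 5] == "W", 9], c("+", "-", "+"))
})
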