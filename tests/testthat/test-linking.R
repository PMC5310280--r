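pair_row <- function(c1, pos1, s1, c2, pos2, s2, id = "p1", w = 100L,
                     m1 = TRUE, m2 = TRUE) {
  data.frame(pair_id = id, contig_1 = c1, pos_1 = pos1, width_1 = w,
             strand_1 = s1, mapped_1 = m1,
             contig_2 = c2, pos_2 = pos2, width_2 = w, strand_2 = s2,
             mapped_2 = m2, stringsAsFactors = FALSE)
}

test_that("connection types follow the strand/end case table", {
  lens <- c(sc1 = 2000, sc2 = 2000)
  W <- 300
  # all 8 strand x end x mate-order cases, classified by hand:
  # forward mate near tail -> off tail; reverse mate near head -> off head
  cases <- list(
    list(p = pair_row("sc1", 1850, 1L, "sc2", 40, -1L),
         type = "tail-to-head"),                    # [sc1(+), sc2(+)]
    list(p = pair_row("sc1", 40, -1L, "sc2", 1850, 1L),
         type = "head-to-tail"),                    # mate order swapped
    list(p = pair_row("sc1", 40, -1L, "sc2", 100, -1L),
         type = "head-to-head"),                    # [sc1(-), sc2(+)]
    list(p = pair_row("sc1", 1850, 1L, "sc2", 1800, 1L),
         type = "tail-to-tail"),                    # [sc1(+), sc2(-)]
    list(p = pair_row("sc2", 40, -1L, "sc1", 1850, 1L),
         type = "tail-to-head"),                    # canonical order flips
    list(p = pair_row("sc2", 1850, 1L, "sc1", 40, -1L),
         type = "head-to-tail"),
    list(p = pair_row("sc2", 100, -1L, "sc1", 40, -1L),
         type = "head-to-head"),
    list(p = pair_row("sc2", 1800, 1L, "sc1", 1850, 1L),
         type = "tail-to-tail"))
  for (cs in cases) {
    e <- count_pe_links(cs$p, lens, window = W)
    expect_equal(nrow(e), 1L)
    expect_equal(e$type, cs$type)
    expect_equal(e$contig_a, "sc1")   # canonical endpoint order
  }
  # both mates on one contig: no edge
  expect_equal(nrow(count_pe_links(pair_row("sc1", 1850, 1L, "sc1", 40, -1L),
                                   lens, window = W)), 0L)
  # interior mate (beyond the window): no edge
  expect_equal(nrow(count_pe_links(pair_row("sc1", 900, 1L, "sc2", 40, -1L),
                                   lens, window = W)), 0L)
  # unmapped mate: no edge
  expect_equal(nrow(count_pe_links(
    pair_row("sc1", 1850, 1L, "sc2", 40, -1L, m2 = FALSE),
    lens, window = W)), 0L)
})

test_that("link counting matches the brute-force enumerator on random input", {
  set.seed(202)
  for (trial in 1:60) {
    rp <- random_pairs(sample(20:200, 1L), sample(2:6, 1L))
    W <- sample(c(100, 250, 500), 1L)
    got <- edges_to_oracle_form(count_pe_links(rp$pairs, rp$lens,
                                               window = W))
    want <- oracle_count_links(rp$pairs, rp$lens, W)
    norm <- function(x) if (length(x) == 0L) list() else x[order(names(x))]
    expect_equal(norm(got), norm(want), info = paste("trial", trial))
  }
})

test_that("the count cut-off is strictly greater-than", {
  e <- data.frame(contig_a = "a", end_a = "tail", contig_b = "b",
                  end_b = "head", n = c(5L, 6L, 1L),
                  type = "tail-to-head", stringsAsFactors = FALSE)
  expect_equal(filter_links(e[1, ], 5L)$n, integer(0))   # n = 5 dropped
  expect_equal(filter_links(e[2, ], 5L)$n, 6L)           # n = 6 kept
  expect_equal(nrow(filter_links(e, 0L)), 3L)            # cutoff 0 keeps all
})

test_that("edges classify against strings as consistent/conflicting/uninformative", {
  # one string A(+) B(+) C(+); D unindexed
  strings <- list(
    strings = list(list(
      string_id = "STR1",
      items = data.frame(contig_id = c("A", "B", "C"),
                         orient = c(1L, 1L, 1L),
                         gap_after = c(100, 100, NA),
                         stringsAsFactors = FALSE),
      arc = data.frame(segment_id = "S1", orient = 1L,
                       stringsAsFactors = FALSE))),
    indices = list(
      list(contig_id = "A", status = "indexed"),
      list(contig_id = "B", status = "indexed"),
      list(contig_id = "C", status = "indexed"),
      list(contig_id = "D", status = "unindexed")))
  mk_edge <- function(ca, ea, cb, eb, n = 10L) {
    data.frame(contig_a = ca, end_a = ea, contig_b = cb, end_b = eb,
               n = n, type = paste0(ea, "-to-", eb),
               stringsAsFactors = FALSE)
  }
  cls <- function(e) classify_adjacency(e, strings)$class
  expect_equal(cls(mk_edge("A", "tail", "B", "head")), "consistent")
  expect_equal(cls(mk_edge("A", "tail", "C", "head")), "conflicting")
  expect_equal(cls(mk_edge("A", "head", "B", "tail")), "conflicting")
  expect_equal(cls(mk_edge("C", "tail", "D", "head")), "uninformative")
  expect_equal(cls(mk_edge("A", "head", "C", "tail")), "uninformative")
})

test_that("confidence is 1/0/blended by class and always within [0, 1]", {
  e <- data.frame(contig_a = "a", end_a = "tail", contig_b = "b",
                  end_b = "head", n = c(100L, 1000L, 6L),
                  type = "tail-to-head",
                  class = c("consistent", "conflicting", "uninformative"),
                  stringsAsFactors = FALSE)
  got <- edge_confidence(e, alpha = 0.5, l_sat = 10)
  expect_equal(got$conf, c(1, 0, 0.5 * 0 + 0.5 * 0.6))
  expect_error(edge_confidence(e, alpha = 1.5), "alpha")
  expect_error(edge_confidence(e, alpha = 0.5, l_sat = 0), "l_sat")
})

test_that("an unindexed contig bridges a framework gap (recovery)", {
  strings <- list(
    strings = list(list(
      string_id = "STR1",
      items = data.frame(contig_id = c("A", "B"), orient = c(1L, 1L),
                         gap_after = c(800, NA),
                         stringsAsFactors = FALSE),
      arc = data.frame(segment_id = "S1", orient = 1L,
                       stringsAsFactors = FALSE))),
    indices = list(list(contig_id = "A", status = "indexed"),
                   list(contig_id = "B", status = "indexed"),
                   list(contig_id = "R", status = "unindexed")))
  edges <- data.frame(
    contig_a = c("A", "B"), end_a = c("tail", "head"),
    contig_b = c("R", "R"), end_b = c("head", "tail"),
    n = c(20L, 18L), type = c("tail-to-head", "head-to-tail"),
    class = "uninformative", conf = 0.5, stringsAsFactors = FALSE)
  res <- resolve_chains(strings, edges)
  expect_equal(res$strings[[1L]]$items$contig_id, c("A", "R", "B"))
  expect_equal(res$strings[[1L]]$items$orient, c(1L, 1L, 1L))
  expect_equal(res$strings[[1L]]$items$source, c("cgof", "pe", "cgof"))
})

test_that("competing edges resolve to the highest confidence", {
  strings <- list(
    strings = list(),
    indices = list(list(contig_id = "X", status = "unindexed"),
                   list(contig_id = "Y", status = "unindexed"),
                   list(contig_id = "Z", status = "unindexed")))
  edges <- data.frame(
    contig_a = c("X", "X"), end_a = c("tail", "tail"),
    contig_b = c("Y", "Z"), end_b = c("head", "head"),
    n = c(9L, 4L), type = "tail-to-head", class = "uninformative",
    conf = c(0.9, 0.4), stringsAsFactors = FALSE)
  res <- resolve_chains(strings, edges)
  chains <- lapply(res$strings, function(s) s$items$contig_id)
  expect_true(any(vapply(chains, function(x)
    identical(x, c("X", "Y")) || identical(x, c("Y", "X")), logical(1))))
  expect_true(any(vapply(chains, function(x) identical(x, "Z"),
                         logical(1))))
})

test_that("conflicting edges attach nothing", {
  strings <- list(
    strings = list(list(
      string_id = "STR1",
      items = data.frame(contig_id = c("A", "B"), orient = c(1L, 1L),
                         gap_after = c(100, NA), stringsAsFactors = FALSE),
      arc = data.frame(segment_id = "S1", orient = 1L,
                       stringsAsFactors = FALSE))),
    indices = list(list(contig_id = "A", status = "indexed"),
                   list(contig_id = "B", status = "indexed")))
  edges <- data.frame(contig_a = "A", end_a = "head", contig_b = "B",
                      end_b = "tail", n = 1000L, type = "head-to-tail",
                      class = "conflicting", conf = 0,
                      stringsAsFactors = FALSE)
  res <- resolve_chains(strings, edges)
  expect_equal(length(res$strings), 1L)
  expect_equal(res$strings[[1L]]$items$contig_id, c("A", "B"))
})

test_that("raising the cut-off never increases inter-contig joins", {
  set.seed(17)
  x <- make_sim_inputs(17)
  lens <- stats::setNames(Biostrings::width(x$frag$contigs),
                          names(x$frag$contigs))
  counts <- count_pe_links(x$pairs, lens)
  joins <- vapply(c(0L, 5L, 20L, 100L), function(cut)
    nrow(filter_links(counts, cut)), 0L)
  expect_true(all(diff(joins) <= 0))
})

test_that("non-repeat contig ends join at most one inter-contig edge", {
  set.seed(23)
  x <- make_sim_inputs(23)
  res <- run_pipeline(x$sim$clusters, x$frag$contigs, x$hits, x$pairs)
  reps <- res$strings$repeat_contigs
  occ <- list()
  for (s in res$strings$strings) {
    it <- s$items
    for (k in seq_len(nrow(it))) {
      cid <- it$contig_id[k]
      if (cid %in% reps) next
      occ[[cid]] <- (occ[[cid]] %||% 0L) + 1L
    }
  }
  expect_true(all(unlist(occ) <= 1L))
})
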