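#' Estimate the mean insert size from intra-contig pairs
#'
#' Uses properly oriented (forward/reverse) pairs with both mates on one
#' contig; the insert is the outer distance.  Falls back to \code{fallback}
#' when no such pair exists.
#'
#' @param pairs Pair table from [read_pe_alignments()].
#' @param fallback Value when no usable pair exists (default 500).
#' @return Numeric scalar.
#' @export
estimate_insert_size <- function(pairs, fallback = 500) {
  p <- pairs[pairs$mapped_1 & pairs$mapped_2 &
               pairs$contig_1 == pairs$contig_2, , drop = FALSE]
  if (nrow(p) == 0L) return(fallback)
  fwd_first <- p$strand_1 > 0L & p$strand_2 < 0L
  rev_first <- p$strand_1 < 0L & p$strand_2 > 0L
  ins <- c((p$pos_2 + p$width_2 - p$pos_1)[fwd_first],
           (p$pos_1 + p$width_1 - p$pos_2)[rev_first])
  ins <- ins[ins > 0]
  if (length(ins) == 0L) return(fallback)
  mean(ins)
}

#' Per-contig read depth from paired-end alignments
#'
#' @param pairs Pair table from [read_pe_alignments()].
#' @param contig_lengths Named numeric vector.
#' @return Named numeric vector of mean per-base depths.
#' @export
contig_depths <- function(pairs, contig_lengths) {
  bases <- stats::setNames(numeric(length(contig_lengths)),
                           names(contig_lengths))
  for (m in 1:2) {
    ok <- pairs[[paste0("mapped_", m)]]
    cg <- pairs[[paste0("contig_", m)]][ok]
    w <- pairs[[paste0("width_", m)]][ok]
    s <- tapply(w, cg, sum)
    bases[names(s)] <- bases[names(s)] + s
  }
  bases / unlist(contig_lengths)
}

# end of a contig a mate "points off": a forward mate near the tail points
# off the tail, a reverse mate near the head points off the head; NA when the
# mate sits in the interior (beyond the window)
mate_end <- function(pos, width, strand, contig_len, window) {
  ifelse(strand > 0L,
         ifelse(contig_len - (pos + width) <= window, "tail", NA_character_),
         ifelse(pos <= window, "head", NA_character_))
}

#' Count paired-end links between contig ends
#'
#' A pair links two contigs when both mates are mapped on different contigs
#' and each mate lies within \code{window} bp of a contig end, pointing off
#' that end.  Counts are accumulated per unordered contig pair per connection
#' type (the four head/tail end combinations).
#'
#' @param pairs Pair table from [read_pe_alignments()].
#' @param contig_lengths Named numeric vector.
#' @param window End window in bp; default the estimated mean insert size.
#' @return Data.frame of edges: \code{contig_a}, \code{end_a},
#'   \code{contig_b}, \code{end_b} (canonically ordered), \code{type},
#'   \code{n}.  Attribute \code{"n_discarded"} counts non-qualifying pairs.
#' @export
count_pe_links <- function(pairs, contig_lengths, window = NULL) {
  if (is.null(window)) window <- estimate_insert_size(pairs)
  p <- pairs[pairs$mapped_1 & pairs$mapped_2 &
               pairs$contig_1 != pairs$contig_2, , drop = FALSE]
  n_discarded <- nrow(pairs) - nrow(p)
  if (nrow(p) == 0L) {
    out <- empty_edges()
    attr(out, "n_discarded") <- n_discarded
    return(out)
  }
  len <- unlist(contig_lengths)
  e1 <- mate_end(p$pos_1, p$width_1, p$strand_1, len[p$contig_1], window)
  e2 <- mate_end(p$pos_2, p$width_2, p$strand_2, len[p$contig_2], window)
  ok <- !is.na(e1) & !is.na(e2)
  n_discarded <- n_discarded + sum(!ok)
  p <- p[ok, , drop = FALSE]; e1 <- e1[ok]; e2 <- e2[ok]
  if (nrow(p) == 0L) {
    out <- empty_edges()
    attr(out, "n_discarded") <- n_discarded
    return(out)
  }
  swap <- p$contig_1 > p$contig_2
  ca <- ifelse(swap, p$contig_2, p$contig_1)
  ea <- ifelse(swap, e2, e1)
  cb <- ifelse(swap, p$contig_1, p$contig_2)
  eb <- ifelse(swap, e1, e2)
  key <- paste(ca, ea, cb, eb, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(contig_a = vapply(parts, `[`, "", 1L),
                    end_a = vapply(parts, `[`, "", 2L),
                    contig_b = vapply(parts, `[`, "", 3L),
                    end_b = vapply(parts, `[`, "", 4L),
                    n = as.integer(tab), stringsAsFactors = FALSE)
  out$type <- paste0(out$end_a, "-to-", out$end_b)
  out <- out[order(out$contig_a, out$contig_b, out$end_a, out$end_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_discarded") <- n_discarded
  out
}

empty_edges <- function() {
  data.frame(contig_a = character(), end_a = character(),
             contig_b = character(), end_b = character(),
             n = integer(), type = character(), stringsAsFactors = FALSE)
}

#' Filter link edges by count cut-off
#'
#' Keeps edges whose link count is strictly greater than the cut-off
#' (default 5), excluding connections attributable to systematic error.
#'
#' @param edges Edge table from [count_pe_links()].
#' @param cutoff Non-negative integer (default 5).
#' @return Filtered edge table.
#' @export
filter_links <- function(edges, cutoff = 5L) {
  stopifnot(cutoff >= 0L)
  out <- edges[edges$n > cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

edge_key <- function(ca, ea, cb, eb) {
  swap <- ca > cb | (ca == cb & ea > eb)
  paste(ifelse(swap, cb, ca), ifelse(swap, eb, ea),
        ifelse(swap, ca, cb), ifelse(swap, ea, eb), sep = "\r")
}

# per-string placement map: for every placed contig, its string, position,
# orientation and which ends are interior (joined within the string)
string_placements <- function(strings) {
  rows <- list()
  adj <- character(0)
  for (s in strings$strings) {
    it <- s$items
    n <- nrow(it)
    for (k in seq_len(n)) {
      left <- if (it$orient[k] > 0L) "head" else "tail"
      right <- if (it$orient[k] > 0L) "tail" else "head"
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = it$contig_id[k], string_id = s$string_id, pos = k,
        orient = it$orient[k],
        left_end = left, right_end = right,
        left_interior = k > 1L, right_interior = k < n,
        stringsAsFactors = FALSE)
    }
    if (n > 1L) {
      for (k in seq_len(n - 1L)) {
        ra <- if (it$orient[k] > 0L) "tail" else "head"
        lb <- if (it$orient[k + 1L] > 0L) "head" else "tail"
        adj <- c(adj, edge_key(it$contig_id[k], ra,
                               it$contig_id[k + 1L], lb))
      }
    }
  }
  placements <- if (length(rows) > 0L) do.call(rbind, rows)
  else data.frame(contig_id = character(), string_id = character(),
                  pos = integer(), orient = integer(),
                  left_end = character(), right_end = character(),
                  left_interior = logical(), right_interior = logical(),
                  stringsAsFactors = FALSE)
  list(placements = placements, adjacencies = adj)
}

#' Classify link edges against the cGOF-ordered strings
#'
#' \code{consistent}: the edge joins the facing ends of contigs adjacent in a
#' string, confirming a framework-predicted adjacency.  \code{conflicting}:
#' both contigs are placed in strings and the edge contradicts a placement
#' (at least one endpoint is an interior end already joined within a string).
#' \code{uninformative}: at least one endpoint belongs to an unindexed contig,
#' or the edge joins string termini — nothing in the framework contradicts
#' it, but nothing supports it either.
#'
#' @param edges Edge table from [count_pe_links()] / [filter_links()].
#' @param strings \code{scaffold_strings} from [merge_strings()].
#' @return Edge table with a \code{class} column.
#' @export
classify_adjacency <- function(edges, strings) {
  sp <- string_placements(strings)
  pl <- sp$placements
  interior <- c(
    with(pl[pl$left_interior, ], paste(contig_id, left_end, sep = "\r")),
    with(pl[pl$right_interior, ], paste(contig_id, right_end, sep = "\r")))
  placed <- pl$contig_id
  cls <- character(nrow(edges))
  for (k in seq_len(nrow(edges))) {
    key <- edge_key(edges$contig_a[k], edges$end_a[k],
                    edges$contig_b[k], edges$end_b[k])
    enda <- paste(edges$contig_a[k], edges$end_a[k], sep = "\r")
    endb <- paste(edges$contig_b[k], edges$end_b[k], sep = "\r")
    if (key %in% sp$adjacencies) {
      cls[k] <- "consistent"
    } else if (edges$contig_a[k] %in% placed &&
               edges$contig_b[k] %in% placed &&
               (enda %in% interior || endb %in% interior)) {
      cls[k] <- "conflicting"
    } else {
      cls[k] <- "uninformative"
    }
  }
  edges$class <- cls
  edges
}

#' Edge confidence from framework consistency and link support
#'
#' The confidence of an inter-contig edge combines the framework
#' (permutation) term and the link term as
#' \code{c = a * permutation + (1 - a) * link}.  Edges confirming a
#' framework adjacency are fixed at 1 and edges contradicting it at 0; the
#' blended form applies to uninformative edges, whose permutation term is 0
#' and whose link term is the saturating ramp \code{min(1, n / l_sat)}.
#' Intra-contig head-tail edges always have confidence 1.
#'
#' @param edges Classified edge table.
#' @param alpha Weight of the permutation term, in \[0, 1\] (default 0.5).
#' @param l_sat Link count at which the link term saturates (default 10).
#' @return Edge table with a \code{conf} column.
#' @export
edge_confidence <- function(edges, alpha = 0.5, l_sat = 10) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be in [0, 1]")
  if (!is.numeric(l_sat) || l_sat < 1)
    stop("l_sat must be >= 1")
  link <- pmin(1, edges$n / l_sat)
  edges$conf <- ifelse(edges$class == "consistent", 1,
                       ifelse(edges$class == "conflicting", 0,
                              alpha * 0 + (1 - alpha) * link))
  edges
}

#' Resolve the link graph into extended scaffold strings
#'
#' Two moves, both governed by edge confidence:
#' \enumerate{
#'   \item Gap insertion: an unindexed contig whose two ends link the facing
#'     ends of a within-string adjacency is inserted into that gap,
#'     recovering contigs (often repeats) the framework could not place.  A
#'     repeat contig (read depth at least \code{repeat_depth_factor} times
#'     the median, with two or more disjoint edges of confidence >= 0.5) may
#'     be inserted at several gaps.
#'   \item Terminus matching: remaining edges are processed greedily by
#'     descending confidence (ties: higher count, then endpoint ids); an
#'     edge is attached iff its confidence is positive and both endpoints
#'     are still free (string termini or free unindexed-contig ends).
#' \item Chains of attachments are walked into extended strings; a cycle is
#'     broken at its lowest-confidence attachment.
#' }
#' Framework-confirmed adjacencies are never displaced.
#'
#' @param strings \code{scaffold_strings} from [merge_strings()].
#' @param edges Edge table with \code{class} and \code{conf} columns,
#'   already filtered by [filter_links()].
#' @param depths Named per-contig depths (see [contig_depths()]); NULL
#'   disables repeat reuse.
#' @param gap_default Gap length for PE-only joins (default 100).
#' @param repeat_depth_factor Depth ratio above which a contig counts as a
#'   repeat (default 1.5).
#' @return A \code{scaffold_strings} object with extended strings; each
#'   item gains a \code{source} column (\code{cgof} or \code{pe}).
#' @export
resolve_chains <- function(strings, edges, depths = NULL, gap_default = 100,
                           repeat_depth_factor = 1.5) {
  statuses <- vapply(strings$indices, `[[`, "", "status")
  names(statuses) <- vapply(strings$indices, `[[`, "", "contig_id")
  unindexed <- names(statuses)[statuses == "unindexed"]
  ed <- edges[edges$conf > 0, , drop = FALSE]
  is_repeat <- repeat_contigs(ed, depths, repeat_depth_factor)

  work <- lapply(strings$strings, function(s) {
    it <- s$items
    it$source <- "cgof"
    list(items = it, arc = s$arc)
  })
  used <- character(0)
  inserted <- character(0)
  repeat_pool <- intersect(unindexed, names(is_repeat)[is_repeat])

  # -- move 1: insert unindexed contigs into within-string gaps ------------
  # a gap may be bridged by a chain of up to max_path unindexed contigs
  for (w in seq_along(work)) {
    it <- work[[w]]$items
    k <- 1L
    while (k < nrow(it)) {
      ra <- if (it$orient[k] > 0L) "tail" else "head"
      lb <- if (it$orient[k + 1L] > 0L) "head" else "tail"
      cand <- gap_path(ed, it$contig_id[k], ra,
                       it$contig_id[k + 1L], lb,
                       union(setdiff(unindexed, used), repeat_pool))
      if (!is.null(cand)) {
        ins <- data.frame(contig_id = cand$contigs, orient = cand$orients,
                          gap_after = gap_default, source = "pe",
                          stringsAsFactors = FALSE)
        it$gap_after[k] <- gap_default
        it <- rbind(it[seq_len(k), ], ins,
                    it[seq(k + 1L, nrow(it)), ])
        rownames(it) <- NULL
        nonrep <- cand$contigs[!vapply(cand$contigs, function(x)
          isTRUE(is_repeat[x]), logical(1))]
        used <- c(used, nonrep)
        inserted <- c(inserted, cand$contigs)
        k <- k + 1L + length(cand$contigs)
      } else {
        k <- k + 1L
      }
    }
    work[[w]]$items <- it
  }

  # -- move 2: greedy terminus matching ------------------------------------
  nodes <- work
  free_unindexed <- setdiff(unindexed, union(used, inserted))
  for (u in sort(free_unindexed)) {
    nodes[[length(nodes) + 1L]] <- list(
      items = data.frame(contig_id = u, orient = 1L,
                         gap_after = NA_real_, source = "pe",
                         stringsAsFactors = FALSE),
      arc = NULL)
  }
  ends <- node_end_table(nodes)
  ed2 <- ed[ed$class != "consistent", , drop = FALSE]
  ed2 <- ed2[order(-ed2$conf, -ed2$n, ed2$contig_a, ed2$end_a,
                   ed2$contig_b, ed2$end_b), , drop = FALSE]
  attachments <- list()
  free <- rep(TRUE, nrow(ends))
  names(free) <- paste(ends$contig_id, ends$end, sep = "\r")
  for (k in seq_len(nrow(ed2))) {
    ka <- paste(ed2$contig_a[k], ed2$end_a[k], sep = "\r")
    kb <- paste(ed2$contig_b[k], ed2$end_b[k], sep = "\r")
    if (ka == kb) next
    if (is.na(free[ka]) || is.na(free[kb])) next
    if (!isTRUE(free[ka]) || !isTRUE(free[kb])) next
    free[ka] <- FALSE; free[kb] <- FALSE
    attachments[[length(attachments) + 1L]] <-
      data.frame(ka = ka, kb = kb, conf = ed2$conf[k], n = ed2$n[k],
                 stringsAsFactors = FALSE)
  }
  merged <- walk_attachments(nodes, ends, attachments, gap_default)
  out_strings <- lapply(seq_along(merged), function(i) {
    list(string_id = paste0("STR", i),
         items = merged[[i]]$items, arc = merged[[i]]$arc)
  })
  res <- strings
  res$strings <- out_strings
  res$repeat_contigs <- names(is_repeat)[is_repeat]
  res
}

repeat_contigs <- function(edges, depths, factor) {
  if (is.null(depths) || length(depths) == 0L)
    return(stats::setNames(logical(0), character(0)))
  med <- stats::median(depths)
  out <- stats::setNames(logical(length(depths)), names(depths))
  for (cid in names(depths)) {
    if (depths[[cid]] < factor * med) next
    inc <- edges[(edges$contig_a == cid | edges$contig_b == cid) &
                   edges$conf >= 0.5, , drop = FALSE]
    others <- unique(ifelse(inc$contig_a == cid, inc$contig_b,
                            inc$contig_a))
    out[cid] <- length(others) >= 2L
  }
  out
}

# best chain of unindexed contigs bridging ends (ca,ea)-(cb,eb), or NULL;
# shortest chain wins, ties by total link count, then contig ids
gap_path <- function(edges, ca, ea, cb, eb, pool, max_path = 4L) {
  pool <- sort(pool)
  best <- NULL
  consider <- function(contigs, orients, score) {
    cand <- list(contigs = contigs, orients = orients, score = score)
    if (is.null(best) || length(cand$contigs) < length(best$contigs) ||
        (length(cand$contigs) == length(best$contigs) &&
           (cand$score > best$score ||
              (cand$score == best$score &&
                 paste(cand$contigs, collapse = ",") <
                 paste(best$contigs, collapse = ","))))) {
      best <<- cand
    }
  }
  dfs <- function(from_c, from_e, contigs, orients, score) {
    if (length(contigs) >= 1L) {
      e_end <- edge_lookup(edges, from_c, from_e, cb, eb)
      if (!is.null(e_end)) consider(contigs, orients, score + e_end$n)
    }
    if (length(contigs) >= max_path) return()
    if (!is.null(best) && length(contigs) + 1L > length(best$contigs))
      return()
    for (r in setdiff(pool, contigs)) {
      for (x in c("head", "tail")) {
        e <- edge_lookup(edges, from_c, from_e, r, x)
        if (is.null(e)) next
        y <- if (x == "head") "tail" else "head"
        dfs(r, y, c(contigs, r),
            c(orients, if (x == "head") 1L else -1L), score + e$n)
      }
    }
  }
  dfs(ca, ea, character(0), integer(0), 0)
  best
}

edge_lookup <- function(edges, ca, ea, cb, eb) {
  key <- edge_key(ca, ea, cb, eb)
  keys <- edge_key(edges$contig_a, edges$end_a,
                   edges$contig_b, edges$end_b)
  i <- match(key, keys)
  if (is.na(i)) return(NULL)
  edges[i, , drop = FALSE]
}

node_end_table <- function(nodes) {
  rows <- lapply(seq_along(nodes), function(i) {
    it <- nodes[[i]]$items
    first <- it[1L, ]; last <- it[nrow(it), ]
    data.frame(
      node = c(i, i), side = c("L", "R"),
      contig_id = c(first$contig_id, last$contig_id),
      end = c(if (first$orient > 0L) "head" else "tail",
              if (last$orient > 0L) "tail" else "head"),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# merge nodes along attachments; breaks cycles at the weakest attachment
walk_attachments <- function(nodes, ends, attachments, gap_default) {
  if (length(attachments) > 0L) {
    at <- do.call(rbind, attachments)
    ekey <- paste(ends$contig_id, ends$end, sep = "\r")
    at$node_a <- ends$node[match(at$ka, ekey)]
    at$side_a <- ends$side[match(at$ka, ekey)]
    at$node_b <- ends$node[match(at$kb, ekey)]
    at$side_b <- ends$side[match(at$kb, ekey)]
    # drop self-links (both ends of a one-contig node) and cycle edges
    at <- at[at$node_a != at$node_b | at$side_a != at$side_b, , drop = FALSE]
    at <- at[order(-at$conf, -at$n), , drop = FALSE]
    comp <- seq_along(nodes)
    find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
    keep <- logical(nrow(at))
    side_used <- matrix(FALSE, nrow = length(nodes), ncol = 2,
                        dimnames = list(NULL, c("L", "R")))
    for (k in seq_len(nrow(at))) {
      a <- at$node_a[k]; b <- at$node_b[k]
      if (a == b) next                      # would close a cycle on one node
      if (side_used[a, at$side_a[k]] || side_used[b, at$side_b[k]]) next
      if (find(a) == find(b)) next          # would close a multi-node cycle
      keep[k] <- TRUE
      side_used[a, at$side_a[k]] <- TRUE
      side_used[b, at$side_b[k]] <- TRUE
      comp[find(a)] <- find(b)
    }
    at <- at[keep, , drop = FALSE]
  } else {
    at <- NULL
  }
  flip_node <- function(node) {
    it <- node$items
    it <- it[rev(seq_len(nrow(it))), , drop = FALSE]
    it$orient <- -it$orient
    it$gap_after <- c(it$gap_after[-1L], NA_real_)
    rownames(it) <- NULL
    arc <- node$arc
    if (!is.null(arc) && nrow(arc) > 0L) {
      arc <- arc[rev(seq_len(nrow(arc))), , drop = FALSE]
      arc$orient <- -arc$orient
      rownames(arc) <- NULL
    }
    list(items = it, arc = arc)
  }
  n_nodes <- length(nodes)
  link_of <- vector("list", n_nodes)
  for (i in seq_len(n_nodes)) link_of[[i]] <- list(L = NULL, R = NULL)
  if (!is.null(at)) {
    for (k in seq_len(nrow(at))) {
      link_of[[at$node_a[k]]][[at$side_a[k]]] <-
        list(node = at$node_b[k], side = at$side_b[k])
      link_of[[at$node_b[k]]][[at$side_b[k]]] <-
        list(node = at$node_a[k], side = at$side_a[k])
    }
  }
  visited <- logical(n_nodes)
  merged <- list()
  for (i in seq_len(n_nodes)) {
    if (visited[i]) next
    # find the leftmost node of this component
    cur <- i; side <- "L"
    steps <- 0L
    while (!is.null(link_of[[cur]][[side]]) && steps <= n_nodes) {
      nxt <- link_of[[cur]][[side]]
      cur <- nxt$node
      side <- if (nxt$side == "L") "R" else "L"
      steps <- steps + 1L
    }
    # walk rightward from cur, entering at 'side'
    chain <- list()
    entering <- side
    repeat {
      visited[cur] <- TRUE
      node <- nodes[[cur]]
      if (entering == "R") node <- flip_node(node)
      chain[[length(chain) + 1L]] <- node
      exit_side <- if (entering == "L") "R" else "L"
      nxt <- link_of[[cur]][[exit_side]]
      if (is.null(nxt) || visited[nxt$node]) break
      cur <- nxt$node
      entering <- nxt$side
    }
    items <- NULL; arc <- NULL
    for (node in chain) {
      if (!is.null(items))
        items$gap_after[nrow(items)] <- gap_default
      items <- rbind(items, node$items)
      if (!is.null(node$arc) && nrow(node$arc) > 0L)
        arc <- rbind(arc, node$arc)
    }
    rownames(items) <- NULL
    if (!is.null(arc)) rownames(arc) <- NULL
    merged[[length(merged) + 1L]] <- list(items = items, arc = arc)
  }
  merged
}
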