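#' Cycles in the amplicon graph
#'
#' A cycle is an ordered ring of oriented fragments together with the
#' junction (SV or spatial) edge entering each fragment. `junction i` is
#' the edge between fragment `i - 1` and fragment `i` of the ring
#' (cyclically, so junction 1 closes the ring from the last fragment into
#' the first). Entering a fragment at its tail traverses it in `+`
#' orientation and exits at the head; entering at the head traverses `-`
#' and exits at the tail.
#'
#' @name ec_cycle
NULL

.new_cycle <- function(fids, orients, eids, g, is_derived = FALSE,
                       constituents = character(0)) {
  e <- g$edges[match(eids, g$edges$edge_id), , drop = FALSE]
  f <- g$fragments[match(fids, g$fragments$fid), , drop = FALSE]
  structure(list(
    fids = as.integer(fids), orients = orients, eids = as.integer(eids),
    kinds = e$kind, svtypes = e$svtype, weights = e$weight,
    total_len = sum(f$end - f$start),
    canon_key = NA_character_, is_derived = is_derived,
    constituents = constituents), class = "ec_cycle")
}

#' @export
print.ec_cycle <- function(x, ...) {
  cat(if (x$is_derived) "derived" else "simple", "cycle:",
      paste0(x$fids, x$orients, collapse = " "),
      sprintf("(%d bp)\n", x$total_len))
  invisible(x)
}

.entry_side <- function(orient) if (orient == "+") "tail" else "head"
.exit_side <- function(orient) if (orient == "+") "head" else "tail"

# endpoint position of a vertex (tail = start, head = end)
.vertex_pos <- function(fragments, fid, side) {
  i <- match(fid, fragments$fid)
  if (side == "tail") fragments$start[i] else fragments$end[i]
}

# adjacency of non-fragment edges: for each vertex "fid:side", candidate
# steps ordered by descending weight, ties by (chrom, pos, sv < spatial,
# edge_id) of the far endpoint
.adjacency <- function(g) {
  e <- g$edges[g$edges$kind != "fragment", , drop = FALSE]
  if (nrow(e) == 0) return(list())
  both <- rbind(
    data.frame(from_fid = e$u_fid, from_side = e$u_side, to_fid = e$v_fid,
               to_side = e$v_side, weight = e$weight, kind = e$kind,
               edge_id = e$edge_id, stringsAsFactors = FALSE),
    data.frame(from_fid = e$v_fid, from_side = e$v_side, to_fid = e$u_fid,
               to_side = e$u_side, weight = e$weight, kind = e$kind,
               edge_id = e$edge_id, stringsAsFactors = FALSE))
  fr <- g$fragments
  i <- match(both$to_fid, fr$fid)
  both$to_chrom <- fr$chrom[i]
  both$to_pos <- ifelse(both$to_side == "tail", fr$start[i], fr$end[i])
  ord <- order(-both$weight, both$to_chrom, both$to_pos,
               match(both$kind, c("sv", "spatial")), both$edge_id)
  both <- both[ord, , drop = FALSE]
  split(both, paste0(both$from_fid, ":", both$from_side))
}

#' Enumerate unique simple cycles by weighted depth-first search
#'
#' Explores alternating walks (fragment edge, then SV/spatial edge, ...)
#' from every fragment, expanding neighbors in descending edge weight.
#' A cycle closes when a non-fragment edge from the current exit endpoint
#' reaches the entry endpoint of the fragment that started the walk; no
#' fragment is visited twice (simple). Each cycle is canonicalized and
#' duplicates are discarded, so the result is the unique simple-cycle set.
#' Enumeration is deterministic.
#'
#' @param g A pruned `amplicon_graph`.
#' @param max_cycles Safety cap on the number of distinct cycles.
#' @return List of `ec_cycle`, ordered by canonical key.
#' @export
find_simple_cycles <- function(g, max_cycles = 10000) {
  adj <- .adjacency(g)
  found <- new.env(parent = emptyenv())
  fr <- g$fragments
  start_order <- fr$fid[order(fr$chrom, fr$start, fr$fid)]
  for (start in start_order) {
    fids <- integer(0); orients <- character(0); eids <- integer(0)
    on_stack <- new.env(parent = emptyenv())
    dfs <- function(fid, orient) {
      fids[[length(fids) + 1]] <<- fid
      orients[[length(orients) + 1]] <<- orient
      assign(as.character(fid), TRUE, envir = on_stack)
      nb <- adj[[paste0(fid, ":", .exit_side(orient))]]
      for (j in seq_len(NROW(nb))) {
        to <- nb$to_fid[j]; side <- nb$to_side[j]
        if (to == start && side == "tail") {
          cyc <- .new_cycle(fids, orients, c(nb$edge_id[j], eids), g)
          cyc <- canonicalize(cyc, g)
          if (!cyc$canon_key %in% ls(found))
            assign(cyc$canon_key, cyc, envir = found)
          if (length(ls(found)) >= max_cycles) break
        } else if (to > start &&
                   !exists(as.character(to), envir = on_stack)) {
          eids[[length(eids) + 1]] <<- nb$edge_id[j]
          dfs(to, if (side == "tail") "+" else "-")
          eids <<- eids[-length(eids)]
        }
      }
      rm(list = as.character(fid), envir = on_stack)
      fids <<- fids[-length(fids)]
      orients <<- orients[-length(orients)]
    }
    dfs(start, "+")
    if (length(ls(found)) >= max_cycles) {
      warning("cycle cap of ", max_cycles, " reached; enumeration truncated")
      break
    }
  }
  keys <- sort(ls(found))
  lapply(keys, get, envir = found)
}

.rotate_cycle <- function(fids, orients, eids, k) {
  n <- length(fids)
  idx <- ((seq_len(n) + k - 2) %% n) + 1
  list(fids = fids[idx], orients = orients[idx], eids = eids[idx])
}

.reverse_cycle <- function(fids, orients, eids) {
  n <- length(fids)
  idx <- c(1, rev(seq_len(n))[-n])           # f1, fn, fn-1, ..., f2
  flip <- c("+" = "-", "-" = "+")
  # junction entering reversed-ring position j is the original edge
  # between f_{n+3-j} and f_{n+2-j}: e'_1 = e_2, e'_2 = e_1, e'_3 = e_n
  eidx <- ((n + 2 - seq_len(n)) %% n) + 1
  list(fids = fids[idx], orients = unname(flip[orients[idx]]),
       eids = eids[eidx])
}

#' Canonicalize a cycle
#'
#' Rotates the ring so the fragment at the 5'-leftmost genomic position
#' (smallest chromosome, start) comes first, tries both traversal
#' directions, and keeps the lexicographically smaller oriented-fragment
#' sequence. The canonical key is invariant under rotation and direction
#' reversal and identical rings hash identically. Idempotent.
#'
#' @param cycle An `ec_cycle`.
#' @param g The `amplicon_graph` it lives in.
#' @return The canonical `ec_cycle` with `canon_key` set.
#' @export
canonicalize <- function(cycle, g) {
  fr <- g$fragments
  n <- length(cycle$fids)
  i <- match(cycle$fids, fr$fid)
  rank <- order(order(fr$chrom, fr$start, fr$fid))[i]  # genomic rank per pos
  best <- NULL; best_enc <- NULL
  for (dir in 1:2) {
    cur <- if (dir == 1)
      list(fids = cycle$fids, orients = cycle$orients, eids = cycle$eids)
    else .reverse_cycle(cycle$fids, cycle$orients, cycle$eids)
    rk <- rank[match(cur$fids, cycle$fids)]
    for (k in which(rk == min(rk))) {
      rot <- .rotate_cycle(cur$fids, cur$orients, cur$eids, k)
      enc <- paste(sprintf("%08d%s", rot$fids,
                           ifelse(rot$orients == "+", "f", "r")),
                   collapse = "|")
      if (is.null(best_enc) || enc < best_enc) {
        best_enc <- enc
        best <- rot
      }
    }
  }
  out <- .new_cycle(best$fids, best$orients, best$eids, g,
                    cycle$is_derived, cycle$constituents)
  out$canon_key <- best_enc
  out
}

#' Validate that a cycle is a legal alternating closed walk
#'
#' Checks edge-by-edge that junction `i` is a non-fragment edge joining
#' the exit endpoint of fragment `i - 1` to the entry endpoint of
#' fragment `i`.
#'
#' @param cycle An `ec_cycle`.
#' @param g The graph.
#' @return `TRUE` or `FALSE`.
#' @export
validate_cycle <- function(cycle, g) {
  n <- length(cycle$fids)
  if (n == 0 || length(cycle$eids) != n) return(FALSE)
  for (i in seq_len(n)) {
    prev <- if (i == 1) n else i - 1
    e <- g$edges[match(cycle$eids[i], g$edges$edge_id), ]
    if (is.na(e$kind) || e$kind == "fragment") return(FALSE)
    from <- c(cycle$fids[prev], .exit_side(cycle$orients[prev]))
    to <- c(cycle$fids[i], .entry_side(cycle$orients[i]))
    fwd <- e$u_fid == from[1] && e$u_side == from[2] &&
      e$v_fid == to[1] && e$v_side == to[2]
    rev <- e$v_fid == from[1] && e$v_side == from[2] &&
      e$u_fid == to[1] && e$u_side == to[2]
    if (!fwd && !rev) return(FALSE)
  }
  TRUE
}

#' Partition cycles into fragment-sharing clusters
#'
#' Connected components of the "shares at least one genomic fragment"
#' relation over cycles. Clusters are pairwise fragment-disjoint and their
#' union is the input set.
#'
#' @param cycles List of canonical `ec_cycle`.
#' @return List of clusters, each a list with `cid`, `cycles` (list of
#'   simple cycles), `fragment_ids`.
#' @export
partition_cycles <- function(cycles) {
  if (length(cycles) == 0) return(list())
  n <- length(cycles)
  # bipartite incidence cycle -> fragment, components via igraph
  el <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(paste0("c", i), paste0("f", unique(cycles[[i]]$fids)))))
  gr <- igraph::graph_from_edgelist(el, directed = FALSE)
  comp <- igraph::components(gr)$membership
  cyc_comp <- comp[paste0("c", seq_len(n))]
  out <- list()
  for (k in sort(unique(cyc_comp))) {
    idx <- which(cyc_comp == k)
    out[[length(out) + 1]] <- list(
      cid = length(out) + 1L,
      cycles = cycles[idx],
      fragment_ids = sort(unique(unlist(lapply(cycles[idx],
                                               function(c) c$fids)))))
  }
  out
}

# Jaccard similarity of two fragment multisets
.multiset_jaccard <- function(a, b) {
  fids <- union(a, b)
  ca <- tabulate(match(a, fids), length(fids))
  cb <- tabulate(match(b, fids), length(fids))
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

# splice ring `c2` into ring `c1` at the shared fragment with the smallest
# genomic position; reverses c2 when the shared fragment's orientations
# disagree
.splice <- function(c1, c2, g) {
  shared <- intersect(c1$fids, c2$fids)
  if (length(shared) == 0) return(NULL)
  fr <- g$fragments
  i <- match(shared, fr$fid)
  sf <- shared[order(fr$chrom[i], fr$start[i], shared)][1]
  p1 <- which(c1$fids == sf)[1]
  p2 <- which(c2$fids == sf)[1]
  r2 <- list(fids = c2$fids, orients = c2$orients, eids = c2$eids)
  if (c2$orients[p2] != c1$orients[p1]) {
    r2 <- .reverse_cycle(r2$fids, r2$orients, r2$eids)
    p2 <- which(r2$fids == sf &
                  r2$orients == c1$orients[p1])[1]
  }
  r2 <- .rotate_cycle(r2$fids, r2$orients, r2$eids, p2)
  n1 <- length(c1$fids); n2 <- length(r2$fids)
  take1 <- seq_len(p1)
  rest1 <- if (p1 < n1) (p1 + 1):n1 else integer(0)
  ins <- if (n2 > 1) 2:n2 else integer(0)
  fids <- c(c1$fids[take1], r2$fids[ins], r2$fids[1], c1$fids[rest1])
  orients <- c(c1$orients[take1], r2$orients[ins], r2$orients[1],
               c1$orients[rest1])
  eids <- c(c1$eids[take1], r2$eids[ins], r2$eids[1], c1$eids[rest1])
  cons <- unique(c(if (length(c1$constituents)) c1$constituents else
    c1$canon_key, c2$canon_key))
  .new_cycle(fids, orients, eids, g, is_derived = TRUE,
             constituents = cons)
}

#' Generate derived cycles for a cluster
#'
#' Candidate simple cycles (at most `max_simple`, ranked by support = the
#' minimum junction weight, descending) are spliced pairwise, and up to
#' three at a time, at a shared fragment, producing merged rings that can
#' represent large interspersed duplications. Only sufficiently dissimilar
#' cycles are combined: the fragment-multiset Jaccard similarity of the
#' parts must be at most `dissim_threshold` (near-duplicates would explode
#' the feature space without adding structure). Results are canonicalized
#' and deduplicated against the simple set.
#'
#' @param cluster One element of [partition_cycles()] output.
#' @param g The graph.
#' @param max_simple Cap on simple cycles entering combinations.
#' @param dissim_threshold Maximum Jaccard similarity allowing a merge.
#' @return List of derived `ec_cycle` (possibly empty).
#' @export
derive_cycles <- function(cluster, g, max_simple = 8,
                          dissim_threshold = 0.8) {
  stopifnot(max_simple >= 1)
  cyc <- cluster$cycles
  if (length(cyc) > max_simple) {
    support <- vapply(cyc, function(c) min(c$weights), numeric(1))
    ord <- order(-support, vapply(cyc, function(c) c$canon_key,
                                  character(1)))
    dropped <- cyc[ord[-seq_len(max_simple)]]
    warning("cluster has ", length(cyc), " simple cycles; keeping top ",
            max_simple, " by support, dropping: ",
            paste(vapply(dropped, function(c)
              paste0(c$fids, c$orients, collapse = ","), character(1)),
              collapse = " | "))
    cyc <- cyc[ord[seq_len(max_simple)]]
  }
  simple_keys <- vapply(cyc, function(c) c$canon_key, character(1))
  seen <- new.env(parent = emptyenv())
  for (k in simple_keys) assign(k, TRUE, envir = seen)
  out <- list()
  mergeable <- function(a, b) {
    length(intersect(a$fids, b$fids)) >= 1 &&
      .multiset_jaccard(a$fids, b$fids) <= dissim_threshold
  }
  pairs <- list()
  n <- length(cyc)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!mergeable(cyc[[i]], cyc[[j]])) next
    d <- .splice(cyc[[i]], cyc[[j]], g)
    if (is.null(d)) next
    d <- canonicalize(d, g)
    pairs[[length(pairs) + 1]] <- d
    if (!exists(d$canon_key, envir = seen)) {
      assign(d$canon_key, TRUE, envir = seen)
      out[[length(out) + 1]] <- d
    }
  }
  for (d in pairs) for (k in seq_len(n)) {
    ck <- cyc[[k]]
    if (ck$canon_key %in% d$constituents) next
    if (!mergeable(d, ck)) next
    t3 <- .splice(d, ck, g)
    if (is.null(t3)) next
    t3 <- canonicalize(t3, g)
    if (!exists(t3$canon_key, envir = seen)) {
      assign(t3$canon_key, TRUE, envir = seen)
      out[[length(out) + 1]] <- t3
    }
  }
  out[order(vapply(out, function(c) c$canon_key, character(1)))]
}

#' Convert a cycle to its genomic ring representation
#'
#' @param cycle An `ec_cycle`.
#' @param fragments The fragment table of the graph.
#' @return data.frame with `chrom`, `start`, `end`, `orient`, `mean_cov`,
#'   `fragment_id`, one row per ring position in traversal order.
#' @export
cycle_ring <- function(cycle, fragments) {
  i <- match(cycle$fids, fragments$fid)
  data.frame(chrom = fragments$chrom[i], start = fragments$start[i],
             end = fragments$end[i], orient = cycle$orients,
             mean_cov = fragments$mean_cov[i],
             fragment_id = cycle$fids, stringsAsFactors = FALSE)
}
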