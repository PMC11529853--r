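#' Simplify a ring
#'
#' Merges consecutive (cyclically) ring fragments that are genomically
#' continuous in the traversal direction with equal orientation, so that
#' rings fragmented differently by two pipelines become comparable.
#'
#' @param ring data.frame `chrom`, `start`, `end`, `orient`.
#' @return The simplified ring.
#' @export
ring_simplify <- function(ring) {
  ring <- ring[, c("chrom", "start", "end", "orient")]
  repeat {
    n <- nrow(ring)
    if (n < 2) return(ring)
    merged <- FALSE
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      if (i == j) next
      a <- ring[i, ]; b <- ring[j, ]
      if (a$chrom == b$chrom && a$orient == b$orient) {
        if (a$orient == "+" && a$end == b$start) {
          ring$end[i] <- b$end
          ring <- ring[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
        if (a$orient == "-" && a$start == b$end) {
          ring$start[i] <- b$start
          ring <- ring[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    rownames(ring) <- NULL
    if (!merged) return(ring)
  }
}

#' Reverse a ring's traversal direction
#'
#' @param ring data.frame `chrom`, `start`, `end`, `orient`.
#' @export
ring_reverse <- function(ring) {
  n <- nrow(ring)
  idx <- c(1, rev(seq_len(n))[-n])
  out <- ring[idx, , drop = FALSE]
  out$orient <- ifelse(out$orient == "+", "-", "+")
  rownames(out) <- NULL
  out
}

.ring_total <- function(ring) sum(ring$end - ring$start)

.junc_match <- function(a, b, tol) {
  a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
    a$side1 == b$side1 && a$side2 == b$side2 &&
    abs(a$pos1 - b$pos1) <= tol && abs(a$pos2 - b$pos2) <= tol
}

.frag_match <- function(a, b, tol) {
  a$chrom == b$chrom && a$orient == b$orient &&
    abs(a$start - b$start) <= tol && abs(a$end - b$end) <= tol
}

# longest common contiguous stretch (bp) anchored at a matched junction
# pair (jr[i] ~ jt[k]; junction i sits between ring fragments i and
# i + 1). Fragments interior to the stretch must match within tol; the
# two stretch-end fragments contribute the shared prefix/suffix measured
# from the anchored junction breakend.
.stretch_from_anchor <- function(rec, jr, i, truth, jt, k, tol) {
  nr <- nrow(rec); nt <- nrow(truth)
  cap <- min(nr, nt)
  len <- 0
  full <- 0
  # forward: fragments entered by the matched junctions
  ri <- i %% nr + 1; tk <- k %% nt + 1
  while (full < cap) {
    if (.frag_match(rec[ri, ], truth[tk, ], tol)) {
      len <- len + (truth$end[tk] - truth$start[tk])
      full <- full + 1
      if (!.junc_match(jr[ri, ], jt[tk, ], tol)) break
      ri <- ri %% nr + 1; tk <- tk %% nt + 1
    } else {
      if (rec$chrom[ri] == truth$chrom[tk] &&
          rec$orient[ri] == truth$orient[tk])
        len <- len + min(rec$end[ri] - rec$start[ri],
                         truth$end[tk] - truth$start[tk])
      break
    }
  }
  if (full >= cap) return(min(len, .ring_total(truth)))
  # backward: fragments exiting into the matched junctions
  ri <- i; tk <- k
  while (full < cap) {
    if (.frag_match(rec[ri, ], truth[tk, ], tol)) {
      len <- len + (truth$end[tk] - truth$start[tk])
      full <- full + 1
      pr <- if (ri == 1) nr else ri - 1
      pt <- if (tk == 1) nt else tk - 1
      if (!.junc_match(jr[pr, ], jt[pt, ], tol)) break
      ri <- pr; tk <- pt
    } else {
      if (rec$chrom[ri] == truth$chrom[tk] &&
          rec$orient[ri] == truth$orient[tk])
        len <- len + min(rec$end[ri] - rec$start[ri],
                         truth$end[tk] - truth$start[tk])
      break
    }
  }
  min(len, .ring_total(truth))
}

#' Normalized largest contig of a reconstruction against a truth ring
#'
#' Both rings are expressed as circular sequences of oriented genomic
#' intervals (simplified first); the longest common contiguous stretch is
#' found over all rotations and both traversal directions, requiring
#' interval identity within a `tol` boundary tolerance and matching
#' orientation, with partial credit at the two stretch ends when a
#' boundary fragment is shared only in part. The score is the stretch
#' length divided by the truth's total length, 1 for a perfect
#' reconstruction.
#'
#' @param rec_ring,truth_ring data.frames `chrom`, `start`, `end`,
#'   `orient` (a `reconstruction`'s `ring` works).
#' @param tol Boundary tolerance in bp (default 50).
#' @return Numeric score in `[0, 1]` under the truth-loop cap.
#' @export
largest_contig_normalized <- function(rec_ring, truth_ring, tol = 50) {
  if (is.null(rec_ring) || nrow(rec_ring) == 0) return(0)
  truth <- ring_simplify(truth_ring)
  total <- .ring_total(truth)
  jt <- ring_junctions(truth)
  best <- 0
  for (dir in 1:2) {
    rec <- ring_simplify(if (dir == 1) rec_ring else
      ring_reverse(rec_ring))
    jr <- ring_junctions(rec)
    for (i in seq_len(nrow(rec))) for (k in seq_len(nrow(truth))) {
      if (.junc_match(jr[i, ], jt[k, ], tol))
        best <- max(best, .stretch_from_anchor(rec, jr, i, truth, jt, k,
                                               tol))
      # fragment-overlap candidate without any junction anchor
      a <- rec[i, ]; b <- truth[k, ]
      if (a$chrom == b$chrom && a$orient == b$orient)
        best <- max(best, max(0, min(a$end, b$end) -
                                max(a$start, b$start)))
    }
  }
  best / total
}

#' Junctions of a ring, for breakpoint-recovery scoring
#'
#' SV junctions (everything but plain genomic adjacency) of the
#' simplified ring, each as two breakends with sides.
#'
#' @param ring data.frame `chrom`, `start`, `end`, `orient`.
#' @return data.frame of junctions (see [ring_junctions()]).
#' @export
sv_junctions <- function(ring) {
  j <- ring_junctions(ring_simplify(ring))
  j <- j[j$kind != "adjacency", , drop = FALSE]
  rownames(j) <- NULL
  j
}

.junction_offset <- function(a, b, tol) {
  # unordered comparison: try both endpoint assignments
  o1 <- if (a$chrom1 == b$chrom1 && a$chrom2 == b$chrom2 &&
            a$side1 == b$side1 && a$side2 == b$side2)
    max(abs(a$pos1 - b$pos1), abs(a$pos2 - b$pos2)) else Inf
  o2 <- if (a$chrom1 == b$chrom2 && a$chrom2 == b$chrom1 &&
            a$side1 == b$side2 && a$side2 == b$side1)
    max(abs(a$pos1 - b$pos2), abs(a$pos2 - b$pos1)) else Inf
  o <- min(o1, o2)
  if (o <= tol) o else Inf
}

#' Breakpoint recall and precision of reconstructions against a truth
#'
#' A true junction is recovered when a reconstructed junction matches both
#' breakends (position within `tol`, same sides and chromosomes, in either
#' endpoint order). Matching is greedy one-to-one by smallest offset.
#' With no reconstructed junctions the recall is 0 and the precision is
#' reported as 1 by convention (flagged `vacuous`).
#'
#' @param recs List of `reconstruction` (or rings).
#' @param truth A `ground_truth`, list of rings, or list of
#'   `reconstruction`.
#' @param tol Breakend tolerance in bp (default 50).
#' @return List of class `eval_result`: `recall`, `precision`, `n_true`,
#'   `n_rec`, `matched_pairs` (data.frame with offsets), `vacuous`.
#' @export
breakpoint_recall <- function(recs, truth, tol = 50) {
  get_rings <- function(x) {
    if (inherits(x, "ground_truth")) return(x$templates)
    if (inherits(x, "reconstruction")) return(list(x$ring))
    if (is.data.frame(x)) return(list(x))
    unlist(lapply(x, get_rings), recursive = FALSE)
  }
  tj <- do.call(rbind, lapply(get_rings(truth), sv_junctions))
  rj_list <- lapply(get_rings(recs), sv_junctions)
  rj <- if (length(rj_list)) do.call(rbind, rj_list) else NULL
  n_true <- NROW(tj); n_rec <- NROW(rj)
  if (n_rec == 0 || n_true == 0) {
    return(structure(list(recall = 0, precision = 1, n_true = n_true,
                          n_rec = n_rec,
                          matched_pairs = data.frame(), vacuous = TRUE),
                     class = "eval_result"))
  }
  cand <- list()
  for (i in seq_len(n_true)) for (j in seq_len(n_rec)) {
    o <- .junction_offset(tj[i, ], rj[j, ], tol)
    if (is.finite(o))
      cand[[length(cand) + 1]] <- c(i = i, j = j, off = o)
  }
  matched <- data.frame(true_idx = integer(0), rec_idx = integer(0),
                        offset = numeric(0))
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand[, "off"], cand[, "i"], cand[, "j"]), ,
                 drop = FALSE]
    used_t <- logical(n_true); used_r <- logical(n_rec)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, "i"]; j <- cand[r, "j"]
      if (used_t[i] || used_r[j]) next
      used_t[i] <- TRUE; used_r[j] <- TRUE
      matched <- rbind(matched, data.frame(true_idx = i, rec_idx = j,
                                           offset = cand[r, "off"]))
    }
  }
  structure(list(recall = nrow(matched) / n_true,
                 precision = nrow(matched) / n_rec,
                 n_true = n_true, n_rec = n_rec,
                 matched_pairs = matched, vacuous = FALSE),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result: recall %.3f (%d true), precision %.3f (%d rec)%s\n",
              x$recall, x$n_true, x$precision, x$n_rec,
              if (x$vacuous) " [vacuous]" else ""))
  invisible(x)
}
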