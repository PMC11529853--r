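#' Ring junction geometry
#'
#' For each consecutive pair of oriented fragments in a ring (cyclically),
#' the junction is described by the exit breakend of the left fragment and
#' the entry breakend of the right fragment. A `+` fragment is entered at
#' its genomic start (`tail`) and exited at its end (`head`); a `-`
#' fragment the other way around. Junction kinds: `adjacency` (head to
#' tail, same chromosome, zero gap), `del` (head to tail, forward gap),
#' `dup` (head to tail, backward), `inv` (head-head or tail-tail), `bnd`
#' (across chromosomes).
#'
#' @param ring data.frame with `chrom`, `start`, `end`, `orient` in ring
#'   order.
#' @return data.frame with `chrom1`, `pos1`, `side1`, `chrom2`, `pos2`,
#'   `side2`, `kind`, `gap`; row `i` is the junction between ring rows `i`
#'   and `i + 1` (row `n` wraps to row 1).
#' @export
ring_junctions <- function(ring) {
  n <- nrow(ring)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- ring[i, ]
    b <- ring[if (i == n) 1 else i + 1, ]
    if (a$orient == "+") { p1 <- a$end; s1 <- "head" }
    else { p1 <- a$start; s1 <- "tail" }
    if (b$orient == "+") { p2 <- b$start; s2 <- "tail" }
    else { p2 <- b$end; s2 <- "head" }
    kind <- if (a$chrom != b$chrom) "bnd"
    else if (s1 == "head" && s2 == "tail") {
      if (p2 == p1) "adjacency" else if (p2 > p1) "del" else "dup"
    } else if (s1 == "tail" && s2 == "head") {
      if (p1 == p2) "adjacency" else if (p1 > p2) "del" else "dup"
    } else "inv"
    out[[i]] <- data.frame(chrom1 = a$chrom, pos1 = p1, side1 = s1,
                           chrom2 = b$chrom, pos2 = p2, side2 = s2,
                           kind = kind,
                           gap = if (a$chrom == b$chrom) abs(p2 - p1)
                           else NA_real_,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' The seven amplicon topology classes
#'
#' In increasing computational complexity: SimpleCircularization (1),
#' SimpleSVs (2), MixedSVs (3), Multiregion (4), Multichromosomal (5),
#' Duplications (6), Foldbacks (7).
#'
#' @export
TOPOLOGIES <- c("SimpleCircularization", "SimpleSVs", "MixedSVs",
                "Multiregion", "Multichromosomal", "Duplications",
                "Foldbacks")

#' Classify the topology of a circular reconstruction
#'
#' Predicates are evaluated from the highest rank down and the first match
#' wins (every topology can contain a mixture of lower-rank features):
#' *Foldbacks* - two consecutive ring fragments overlap genomically with
#' opposite orientations; *Duplications* - some genomic region longer than
#' `dup_min` bp is covered at least twice by the ring; *Multichromosomal*
#' - fragments from two or more chromosomes; *Multiregion* - one
#' chromosome but two or more blocks separated by at least `region_gap`;
#' *MixedSVs* - both inversion-type and deletion-type junctions;
#' *SimpleSVs* - only one of the two; *SimpleCircularization* - neither.
#' The single wrap-around junction inherent to any circle (one backward
#' head-to-tail junction) is not counted as an SV.
#'
#' @param ring data.frame with `chrom`, `start`, `end`, `orient`.
#' @param junction_types Optional character vector of VCF SV types, one
#'   per ring junction (junction `i` enters fragment `i`); when supplied,
#'   deletion/inversion predicates use them (`DEL` vs `INV`/`INVDUP`)
#'   instead of the geometric junction kinds.
#' @param region_gap Minimum genomic gap splitting "regions" (bp).
#' @param dup_min Minimum duplicated-region length (bp).
#' @return List with `name` and `rank`.
#' @export
classify_topology <- function(ring, junction_types = NULL,
                              region_gap = 1e4, dup_min = 50) {
  n <- nrow(ring)
  nxt <- c(seq_len(n)[-1], 1L)
  foldback <- any(ring$chrom == ring$chrom[nxt] &
                    ring$orient != ring$orient[nxt] &
                    ring$start < ring$end[nxt] & ring$end > ring$start[nxt])
  if (foldback) return(list(name = "Foldbacks", rank = 7L))

  dup <- FALSE
  for (chrom in unique(ring$chrom)) {
    r <- ring[ring$chrom == chrom, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(r$start + 1L, r$end))
    if (any(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 2] >
            dup_min)) dup <- TRUE
  }
  if (dup) return(list(name = "Duplications", rank = 6L))

  if (length(unique(ring$chrom)) >= 2)
    return(list(name = "Multichromosomal", rank = 5L))

  blocks <- IRanges::reduce(IRanges::IRanges(ring$start + 1L, ring$end),
                            min.gapwidth = region_gap)
  if (length(blocks) >= 2) return(list(name = "Multiregion", rank = 4L))

  if (is.null(junction_types)) {
    j <- ring_junctions(ring)
    kinds <- j$kind
    wrap <- which(kinds == "dup")
    if (length(wrap) > 0) kinds <- kinds[-wrap[1]]
    has_inv <- any(kinds == "inv")
    has_del <- any(kinds == "del")
  } else {
    has_inv <- any(junction_types %in% c("INV", "INVDUP"), na.rm = TRUE)
    has_del <- any(junction_types == "DEL", na.rm = TRUE)
  }
  if (has_inv && has_del) return(list(name = "MixedSVs", rank = 3L))
  if (has_inv || has_del) return(list(name = "SimpleSVs", rank = 2L))
  list(name = "SimpleCircularization", rank = 1L)
}
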