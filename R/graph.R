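#' Amplicon multigraph
#'
#' The weighted undirected multigraph over fragment endpoints. Each
#' fragment contributes a `tail` vertex (its start) and a `head` vertex
#' (its end) joined by a *fragment edge* weighted by mean coverage. SV
#' records add *SV edges* between boundary endpoints according to their
#' type, weighted by variant-read support. *Spatial edges* join
#' genomically consecutive fragments on a chromosome (head of the left
#' fragment to tail of the right), weighted by the junction-spanning read
#' count approximation. Traversing a fragment tail to head is `+`
#' (reference) orientation.
#'
#' @name amplicon_graph
NULL

.empty_edges <- function() {
  data.frame(edge_id = integer(0), kind = character(0),
             u_fid = integer(0), u_side = character(0),
             v_fid = integer(0), v_side = character(0),
             weight = numeric(0), svtype = character(0),
             sv_len = numeric(0), stringsAsFactors = FALSE)
}

.new_graph <- function(fragments, edges, max_gap = Inf) {
  edges$edge_id <- seq_len(nrow(edges))
  structure(list(fragments = fragments, edges = edges, max_gap = max_gap),
            class = "amplicon_graph")
}

#' @export
print.amplicon_graph <- function(x, ...) {
  k <- table(factor(x$edges$kind, levels = c("fragment", "sv", "spatial")))
  cat("amplicon_graph:", nrow(x$fragments), "fragments |",
      k[["fragment"]], "fragment,", k[["sv"]], "sv,", k[["spatial"]],
      "spatial edges\n")
  invisible(x)
}

# fid of the fragment ending (side "head") or starting (side "tail") at a
# 0-based boundary, NA when absent
.frag_at <- function(fragments, chrom, boundary, side) {
  i <- if (side == "head")
    which(fragments$chrom == chrom & fragments$end == boundary)
  else
    which(fragments$chrom == chrom & fragments$start == boundary)
  if (length(i) == 0) NA_integer_ else fragments$fid[i[1]]
}

#' Junction-spanning read count between two neighboring fragments
#'
#' Without an alignment file the count is approximated as the minimum of
#' the coverage on the two sides of the junction, `min(cov at left.end-1,
#' cov at right.start)`.
#'
#' @param left,right Single-row fragment data.frames (same chromosome,
#'   `left$end <= right$start`).
#' @param profile A [coverage_profile].
#' @param bam Optional BAM path; when given, reads spanning both sides of
#'   the junction are counted (requires the GenomicAlignments package).
#' @return Numeric read count.
#' @export
spatial_weight <- function(left, right, profile, bam = NULL) {
  if (left$chrom != right$chrom)
    stop("spatial weight requested across chromosomes")
  if (!is.null(bam)) {
    if (!requireNamespace("GenomicAlignments", quietly = TRUE))
      stop("BAM-based spanning counts need GenomicAlignments")
    rg <- GenomicRanges::GRanges(left$chrom,
                                 IRanges::IRanges(left$end, right$start + 1L))
    aln <- GenomicAlignments::readGAlignments(
      bam, param = Rsamtools::ScanBamParam(which = rg))
    return(sum(GenomicRanges::start(aln) <= left$end - 1L &
                 GenomicRanges::end(aln) >= right$start + 2L))
  }
  min(profile_value(profile, left$chrom, left$end - 1L),
      profile_value(profile, right$chrom, right$start))
}

# Spatial edges between consecutive retained fragments. The
# junction-spanning count is approximated by the minimum flanking
# coverage; reads supporting an SV breakend at either junction boundary
# cannot also span the reference junction, so their support is
# subtracted (clamped at zero).
.spatial_edges <- function(fragments, max_gap = Inf, bsup = NULL) {
  sup_at <- function(chrom, pos) {
    if (is.null(bsup)) return(0)
    s <- bsup$support[bsup$chrom == chrom & bsup$pos == pos]
    if (length(s) == 0) 0 else sum(s)
  }
  out <- list()
  for (chrom in unique(fragments$chrom)) {
    f <- fragments[fragments$chrom == chrom, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    if (nrow(f) < 2) next
    for (i in seq_len(nrow(f) - 1)) {
      gap <- f$start[i + 1] - f$end[i]
      if (gap > max_gap) next
      sub <- sup_at(chrom, f$end[i])
      if (f$start[i + 1] != f$end[i])
        sub <- sub + sup_at(chrom, f$start[i + 1])
      out[[length(out) + 1]] <- data.frame(
        edge_id = NA_integer_, kind = "spatial",
        u_fid = f$fid[i], u_side = "head",
        v_fid = f$fid[i + 1], v_side = "tail",
        weight = max(0, min(f$cov_end[i], f$cov_start[i + 1]) - sub),
        svtype = NA_character_, sv_len = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) .empty_edges() else do.call(rbind, out)
}

# decode a STRANDS-style annotation into endpoint sides; '+' attaches the
# junction to the head of the fragment ending at the boundary, '-' to the
# tail of the fragment starting there
.strand_sides <- function(strands, default = c("head", "tail")) {
  if (is.na(strands) || nchar(strands) != 2) return(default)
  vapply(strsplit(strands, "")[[1]],
         function(s) if (s == "+") "head" else "tail", character(1))
}

#' Build the amplicon multigraph
#'
#' Encodes fragments, SV junctions and genomic adjacency as a weighted
#' undirected multigraph. SV breakends are translated to clean breakpoints
#' via the merge mapping and must land on a fragment boundary. Encoding by
#' type: `BND`/`DEL` join head(left) to tail(right); `DUP` joins
#' tail(left) to head(right); `INV`/`INVDUP` add two edges, head-head and
#' tail-tail. `TRA` is treated as `BND`, honoring a `STRANDS` annotation
#' when present. `INS` records are ignored (they do not change segment
#' order on the amplicon).
#'
#' @param fragments Annotated fragments (see [annotate_coverage()]).
#' @param svs Filtered `sv_records`.
#' @param profile A [coverage_profile] (spatial-edge weights).
#' @param bp_map The `map` attribute of [merge_breakpoints()] output; when
#'   `NULL`, breakend positions are taken as already clean.
#' @param max_gap Maximum genomic gap for spatial adjacency (bp).
#' @return An `amplicon_graph`.
#' @export
build_graph <- function(fragments, svs, profile, bp_map = NULL,
                        max_gap = Inf) {
  frag_edges <- if (nrow(fragments) == 0) .empty_edges() else data.frame(
    edge_id = NA_integer_, kind = "fragment",
    u_fid = fragments$fid, u_side = "tail",
    v_fid = fragments$fid, v_side = "head",
    weight = fragments$mean_cov, svtype = NA_character_,
    sv_len = NA_real_, stringsAsFactors = FALSE)

  cp <- function(chrom, pos) {
    if (is.null(bp_map)) return(pos)
    p <- clean_pos(bp_map, chrom, pos)
    if (is.na(p)) pos else p
  }
  sv_edges <- list()
  add <- function(f1, s1, f2, s2, rec, len) {
    if (is.na(f1) || is.na(f2))
      stop("SV breakend of record '", rec$id,
           "' does not coincide with any fragment boundary")
    data.frame(edge_id = NA_integer_, kind = "sv",
               u_fid = f1, u_side = s1, v_fid = f2, v_side = s2,
               weight = if (is.na(rec$support)) 0 else rec$support,
               svtype = rec$svtype, sv_len = len,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(svs))) {
    rec <- svs[i, ]
    if (rec$svtype == "INS") next
    b1 <- cp(rec$chrom1, rec$pos1)
    b2 <- cp(rec$chrom2, rec$pos2)
    len <- if (!is.na(rec$sv_len)) abs(rec$sv_len) else
      if (rec$chrom1 == rec$chrom2) abs(b2 - b1) else NA_real_
    type <- if (rec$svtype == "TRA") "BND" else rec$svtype
    if (type %in% c("DEL", "BND")) {
      sides <- if (type == "BND")
        .strand_sides(rec$strands) else c("head", "tail")
      f1 <- .frag_at(fragments, rec$chrom1, b1,
                     if (sides[1] == "head") "head" else "tail")
      f2 <- .frag_at(fragments, rec$chrom2, b2,
                     if (sides[2] == "head") "head" else "tail")
      sv_edges[[length(sv_edges) + 1]] <-
        add(f1, sides[1], f2, sides[2], rec, len)
    } else if (type == "DUP") {
      f1 <- .frag_at(fragments, rec$chrom1, b1, "tail")
      f2 <- .frag_at(fragments, rec$chrom2, b2, "head")
      sv_edges[[length(sv_edges) + 1]] <-
        add(f1, "tail", f2, "head", rec, len)
    } else if (type %in% c("INV", "INVDUP")) {
      fh1 <- .frag_at(fragments, rec$chrom1, b1, "head")
      fh2 <- .frag_at(fragments, rec$chrom2, b2, "head")
      ft1 <- .frag_at(fragments, rec$chrom1, b1, "tail")
      ft2 <- .frag_at(fragments, rec$chrom2, b2, "tail")
      sv_edges[[length(sv_edges) + 1]] <-
        add(fh1, "head", fh2, "head", rec, len)
      sv_edges[[length(sv_edges) + 1]] <-
        add(ft1, "tail", ft2, "tail", rec, len)
    }
    # other types (if any) are ignored with the INS rationale
  }
  sv_edges <- if (length(sv_edges) == 0) .empty_edges() else
    do.call(rbind, sv_edges)
  non_ins <- svs[svs$svtype != "INS", , drop = FALSE]
  bsup <- if (nrow(non_ins) == 0) NULL else {
    b <- data.frame(
      chrom = c(non_ins$chrom1, non_ins$chrom2),
      pos = c(vapply(seq_len(nrow(non_ins)), function(i)
        cp(non_ins$chrom1[i], non_ins$pos1[i]), numeric(1)),
        vapply(seq_len(nrow(non_ins)), function(i)
          cp(non_ins$chrom2[i], non_ins$pos2[i]), numeric(1))),
      support = rep(ifelse(is.na(non_ins$support), 0, non_ins$support), 2),
      stringsAsFactors = FALSE)
    stats::aggregate(support ~ chrom + pos, b, sum)
  }
  edges <- rbind(frag_edges, sv_edges,
                 .spatial_edges(fragments, max_gap, bsup))
  g <- .new_graph(fragments, edges, max_gap)
  g$bsup <- bsup
  g
}

#' Prune unusable fragments from the graph
#'
#' Iterates to a fixpoint: fragments with mean coverage at or below
#' `min_cov` are removed; spatial adjacency is recomputed so fragments
#' separated only by pruned fragments become neighbors; fragments whose
#' endpoints touch no SV and no spatial edge (standalone) are removed.
#'
#' @param g An `amplicon_graph`.
#' @param min_cov Coverage threshold (strictly `<=` removed), default 5.
#' @return The pruned `amplicon_graph`.
#' @export
prune_graph <- function(g, min_cov = 5) {
  frags <- g$fragments
  svs <- g$edges[g$edges$kind == "sv", , drop = FALSE]
  repeat {
    keep <- frags$mean_cov > min_cov
    frags2 <- frags[keep, , drop = FALSE]
    svs2 <- svs[svs$u_fid %in% frags2$fid & svs$v_fid %in% frags2$fid, ,
                drop = FALSE]
    sp2 <- .spatial_edges(frags2, g$max_gap, g$bsup)
    touched <- unique(c(svs2$u_fid, svs2$v_fid, sp2$u_fid, sp2$v_fid))
    frags3 <- frags2[frags2$fid %in% touched, , drop = FALSE]
    stable <- nrow(frags3) == nrow(frags)
    frags <- frags3
    svs <- svs[svs$u_fid %in% frags$fid & svs$v_fid %in% frags$fid, ,
               drop = FALSE]
    if (stable) break
  }
  frag_edges <- if (nrow(frags) == 0) .empty_edges() else data.frame(
    edge_id = NA_integer_, kind = "fragment",
    u_fid = frags$fid, u_side = "tail",
    v_fid = frags$fid, v_side = "head",
    weight = frags$mean_cov, svtype = NA_character_, sv_len = NA_real_,
    stringsAsFactors = FALSE)
  out <- .new_graph(frags,
                    rbind(frag_edges, svs,
                          .spatial_edges(frags, g$max_gap, g$bsup)),
                    g$max_gap)
  out$bsup <- g$bsup
  out
}

#' Serialize / read back an amplicon graph
#'
#' Tab-separated edge list with the fragment table in `#fragment` header
#' lines; the round trip reproduces vertices, edges and weights exactly.
#'
#' @param g An `amplicon_graph`.
#' @param path Output (input) file path.
#' @return `write_graph` the path, invisibly; `read_graph` the graph.
#' @export
write_graph <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  f <- g$fragments
  for (i in seq_len(nrow(f)))
    writeLines(sprintf("#fragment\t%d\t%s\t%d\t%d\t%.10g\t%.10g\t%.10g",
                       f$fid[i], f$chrom[i], f$start[i], f$end[i],
                       f$mean_cov[i], f$cov_start[i], f$cov_end[i]), con)
  writeLines(sprintf("#max_gap\t%.10g", g$max_gap), con)
  writeLines(paste(c("edge_id", "kind", "fid_u", "side_u", "fid_v",
                     "side_v", "weight", "svtype"), collapse = "\t"), con)
  e <- g$edges
  for (i in seq_len(nrow(e)))
    writeLines(sprintf("%d\t%s\t%d\t%s\t%d\t%s\t%.10g\t%s",
                       e$edge_id[i], e$kind[i], e$u_fid[i], e$u_side[i],
                       e$v_fid[i], e$v_side[i], e$weight[i],
                       ifelse(is.na(e$svtype[i]), ".", e$svtype[i])), con)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  fl <- lines[startsWith(lines, "#fragment")]
  mg <- lines[startsWith(lines, "#max_gap")]
  body <- lines[!startsWith(lines, "#")]
  frags <- if (length(fl) == 0)
    data.frame(fid = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), mean_cov = numeric(0),
               cov_start = numeric(0), cov_end = numeric(0),
               stringsAsFactors = FALSE)
  else {
    p <- do.call(rbind, strsplit(fl, "\t", fixed = TRUE))
    data.frame(fid = as.integer(p[, 2]), chrom = p[, 3],
               start = as.integer(p[, 4]), end = as.integer(p[, 5]),
               mean_cov = as.numeric(p[, 6]),
               cov_start = as.numeric(p[, 7]),
               cov_end = as.numeric(p[, 8]), stringsAsFactors = FALSE)
  }
  max_gap <- if (length(mg) == 1)
    as.numeric(strsplit(mg, "\t")[[1]][2]) else Inf
  edges <- if (length(body) <= 1) .empty_edges() else {
    p <- do.call(rbind, strsplit(body[-1], "\t", fixed = TRUE))
    data.frame(edge_id = as.integer(p[, 1]), kind = p[, 2],
               u_fid = as.integer(p[, 3]), u_side = p[, 4],
               v_fid = as.integer(p[, 5]), v_side = p[, 6],
               weight = as.numeric(p[, 7]),
               svtype = ifelse(p[, 8] == ".", NA_character_, p[, 8]),
               sv_len = NA_real_, stringsAsFactors = FALSE)
  }
  g <- structure(list(fragments = frags, edges = edges, max_gap = max_gap),
                 class = "amplicon_graph")
  g
}
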