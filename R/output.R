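#' Reconstruction records
#'
#' A reconstruction is one selected circular element: its ring of genomic
#' fragments in traversal order, the estimated proportion (copy-coverage),
#' the annotated topology and the ecDNA/circular label.
#'
#' @param circ_id Integer identifier.
#' @param ring data.frame `chrom`, `start`, `end`, `orient`, `mean_cov`,
#'   `fragment_id`.
#' @param proportion Estimated proportion (x).
#' @param topology Topology name (see [TOPOLOGIES]).
#' @param label `"ecDNA"` or `"circular"`.
#' @return An object of class `reconstruction`.
#' @export
reconstruction <- function(circ_id, ring, proportion, topology, label) {
  structure(list(circ_id = as.integer(circ_id), ring = ring,
                 proportion = proportion, topology = topology,
                 label = label,
                 total_len = sum(ring$end - ring$start)),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("reconstruction %d [%s, %s]: %d fragment(s), %d bp, %.1fx\n",
              x$circ_id, x$topology, x$label, nrow(x$ring), x$total_len,
              x$proportion))
  invisible(x)
}

.bed_header <- paste("#chrom", "start", "end", "circ_id", "fragment_id",
                     "strand", "coverage", "estimated_proportion",
                     "topology", "label", sep = "\t")

#' Write reconstruction threads in BED-like format
#'
#' One row per fragment per reconstruction, grouped by `circ_id` in ring
#' order; 0-based half-open coordinates; ten tab-separated columns with a
#' header line.
#'
#' @param recs List of `reconstruction`.
#' @param path Output file.
#' @export
write_bed <- function(recs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.bed_header, con)
  for (r in recs) {
    rg <- r$ring
    for (i in seq_len(nrow(rg)))
      writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%s\t%.6g\t%.6g\t%s\t%s",
                         rg$chrom[i], rg$start[i], rg$end[i], r$circ_id,
                         rg$fragment_id[i], rg$orient[i], rg$mean_cov[i],
                         r$proportion, r$topology, r$label), con)
  }
  invisible(path)
}

#' Read reconstruction threads back from BED-like format
#'
#' Inverse of [write_bed()].
#'
#' @param path File written by [write_bed()] (or the simulator's truth
#'   BED, which uses the same layout).
#' @return List of `reconstruction`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) return(list())
  p <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  if (ncol(p) != 10)
    stop("expected 10 columns in thread BED, found ", ncol(p))
  df <- data.frame(chrom = p[, 1], start = as.integer(p[, 2]),
                   end = as.integer(p[, 3]), circ_id = as.integer(p[, 4]),
                   fragment_id = as.integer(p[, 5]), orient = p[, 6],
                   mean_cov = as.numeric(p[, 7]),
                   proportion = as.numeric(p[, 8]), topology = p[, 9],
                   label = p[, 10], stringsAsFactors = FALSE)
  lapply(unique(df$circ_id), function(id) {
    d <- df[df$circ_id == id, , drop = FALSE]
    reconstruction(id, d[, c("chrom", "start", "end", "orient", "mean_cov",
                             "fragment_id")],
                   d$proportion[1], d$topology[1], d$label[1])
  })
}

#' Write reconstruction sequences in FASTA format
#'
#' One record per reconstruction (`id` = circ_id); the sequence is the
#' concatenation of fragment sequences in ring order, reverse-complemented
#' for `-` fragments, so its length equals the ring's total length.
#'
#' @param recs List of `reconstruction`.
#' @param ref Reference genome: a [Biostrings::DNAStringSet] or FASTA
#'   path.
#' @param path Output FASTA.
#' @export
write_fasta <- function(recs, ref, path) {
  if (is.character(ref)) ref <- Biostrings::readDNAStringSet(ref)
  names(ref) <- sub("\\s.*", "", names(ref))
  seqs <- lapply(recs, function(r) {
    pieces <- lapply(seq_len(nrow(r$ring)), function(i) {
      rg <- r$ring[i, ]
      if (!rg$chrom %in% names(ref) || rg$end > length(ref[[rg$chrom]]))
        stop("fragment ", rg$chrom, ":", rg$start, "-", rg$end,
             " outside reference")
      s <- Biostrings::subseq(ref[[rg$chrom]], rg$start + 1L, rg$end)
      if (rg$orient == "-") Biostrings::reverseComplement(s) else s
    })
    do.call(Biostrings::xscat, pieces)
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- vapply(recs, function(r)
    sprintf("circ_%d len=%d proportion=%.6g topology=%s", r$circ_id,
            r$total_len, r$proportion, r$topology), character(1))
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Write the summary table of circular elements
#'
#' One row per reconstruction: id, fragment count, total length,
#' estimated proportion, topology, label and the chromosomes involved.
#'
#' @param recs List of `reconstruction`.
#' @param path Output TSV.
#' @export
write_summary <- function(recs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("circ_id", "n_fragments", "total_len", "proportion",
                   "topology", "label", "chromosomes", sep = "\t"), con)
  for (r in recs)
    writeLines(sprintf("%d\t%d\t%d\t%.6g\t%s\t%s\t%s", r$circ_id,
                       nrow(r$ring), r$total_len, r$proportion,
                       r$topology, r$label,
                       paste(unique(r$ring$chrom), collapse = ",")), con)
  invisible(path)
}
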