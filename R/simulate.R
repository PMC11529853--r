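#' Template specification for the ecDNA simulator
#'
#' Probabilistic variables governing template generation: chromosome
#' weights, number and length of amplified regions, and per-rearrangement
#' ratios (probability that a template carries at least one event of that
#' type). Lengths are sampled uniformly from the given ranges (bp).
#' Defaults: regions of 50-500 kb, small deletions of 0.1-5 kb,
#' inversions and tandem duplications of 1-20 kb, foldback segments of
#' 2-20 kb; these emulate focal amplicons with sub-region-scale
#' rearrangements.
#'
#' @param chrom_sizes Named vector of chromosome lengths (the toy genome:
#'   two 5-Mb chromosomes).
#' @param chrom_weights Sampling probability per chromosome.
#' @param n_regions Number of amplified regions (overridden by the target
#'   topology where it dictates one).
#' @param region_len,del_len,inv_len,dup_len,foldback_len Length ranges.
#' @param del_ratio,inv_ratio,dup_ratio,foldback_ratio Event
#'   probabilities.
#' @param target_topology Optional topology name to rejection-sample for.
#' @param seed Integer seed; templates are deterministic given the spec.
#' @param max_retry Rejection-sampling cap.
#' @return List of class `template_spec`.
#' @export
template_spec <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6),
                          chrom_weights = NULL, n_regions = 1,
                          region_len = c(5e4, 5e5),
                          del_len = c(100, 5000),
                          inv_len = c(1000, 20000),
                          dup_len = c(1000, 20000),
                          foldback_len = c(2000, 20000),
                          del_ratio = 0.3, inv_ratio = 0.3,
                          dup_ratio = 0.3, foldback_ratio = 0.1,
                          target_topology = NULL, seed = 1,
                          max_retry = 100) {
  if (is.null(chrom_weights))
    chrom_weights <- rep(1 / length(chrom_sizes), length(chrom_sizes))
  stopifnot(abs(sum(chrom_weights) - 1) < 1e-8,
            all(c(del_ratio, inv_ratio, dup_ratio, foldback_ratio) >= 0),
            all(c(del_ratio, inv_ratio, dup_ratio, foldback_ratio) <= 1))
  if (!is.null(target_topology))
    target_topology <- match.arg(target_topology, TOPOLOGIES)
  structure(as.list(environment()), class = "template_spec")
}

.runifint <- function(n, lo, hi) as.integer(floor(stats::runif(n, lo, hi + 1)))

.pick_fragment <- function(ring, need) {
  ok <- which(ring$orient == "+" & (ring$end - ring$start) >= need)
  if (length(ok) == 0) return(NA_integer_)
  ok[.runifint(1, 1, length(ok))]
}

.split_replace <- function(ring, i, pieces) {
  top <- if (i > 1) ring[seq_len(i - 1), , drop = FALSE] else ring[0, ]
  bot <- if (i < nrow(ring)) ring[(i + 1):nrow(ring), , drop = FALSE]
  else ring[0, ]
  out <- rbind(top, pieces, bot)
  rownames(out) <- NULL
  out
}

.frag_row <- function(chrom, start, end, orient) {
  data.frame(chrom = chrom, start = start, end = end, orient = orient,
             stringsAsFactors = FALSE)
}

.apply_del <- function(ring, len, margin = 300) {
  i <- .pick_fragment(ring, len + 2 * margin)
  if (is.na(i)) return(ring)
  f <- ring[i, ]
  a <- .runifint(1, f$start + margin, f$end - len - margin)
  .split_replace(ring, i, rbind(.frag_row(f$chrom, f$start, a, "+"),
                                .frag_row(f$chrom, a + len, f$end, "+")))
}

.apply_inv <- function(ring, len, margin = 300) {
  i <- .pick_fragment(ring, len + 2 * margin)
  if (is.na(i)) return(ring)
  f <- ring[i, ]
  a <- .runifint(1, f$start + margin, f$end - len - margin)
  .split_replace(ring, i, rbind(.frag_row(f$chrom, f$start, a, "+"),
                                .frag_row(f$chrom, a, a + len, "-"),
                                .frag_row(f$chrom, a + len, f$end, "+")))
}

.apply_dup <- function(ring, len, margin = 300) {
  i <- .pick_fragment(ring, len + 2 * margin)
  if (is.na(i)) return(ring)
  f <- ring[i, ]
  a <- .runifint(1, f$start + margin, f$end - len - margin)
  .split_replace(ring, i, rbind(.frag_row(f$chrom, f$start, a, "+"),
                                .frag_row(f$chrom, a, a + len, "+"),
                                .frag_row(f$chrom, a, a + len, "+"),
                                .frag_row(f$chrom, a + len, f$end, "+")))
}

# insert an inverted copy of the fragment's own terminal segment after it
.apply_foldback <- function(ring, len, margin = 300) {
  i <- .pick_fragment(ring, len + margin)
  if (is.na(i)) return(ring)
  f <- ring[i, ]
  .split_replace(ring, i, rbind(f, .frag_row(f$chrom, f$end - len, f$end,
                                             "-")))
}

.sample_regions <- function(spec, target) {
  cs <- spec$chrom_sizes
  n <- spec$n_regions
  gap_needed <- 2e4   # keeps multiregion blocks well past the region gap
  if (!is.null(target)) {
    if (target == "Multichromosomal") {
      chroms <- sample(names(cs), 2, prob = spec$chrom_weights)
      n <- 2
    } else if (target == "Multiregion") {
      n <- max(2, n)
      chroms <- rep(sample(names(cs), 1, prob = spec$chrom_weights), n)
    } else {
      n <- 1
      chroms <- sample(names(cs), 1, prob = spec$chrom_weights)
    }
  } else {
    chroms <- sample(names(cs), n, replace = TRUE,
                     prob = spec$chrom_weights)
  }
  lens <- .runifint(n, spec$region_len[1], spec$region_len[2])
  out <- vector("list", n)
  # lay regions out per chromosome: distribute the spare bp among the
  # leading margin and the inter-region gaps, so everything stays within
  # the chromosome with gaps of at least gap_needed
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    k <- length(idx)
    spare <- cs[[ch]] - 2e4 - sum(lens[idx]) - (k - 1) * gap_needed
    if (spare < 0) stop("chromosome ", ch, " too short for ", k,
                        " regions of the requested lengths")
    cuts <- sort(stats::runif(k, 0, spare))
    pos <- 1e4
    prev_cut <- 0
    for (j in seq_len(k)) {
      pos <- pos + (cuts[j] - prev_cut) +
        (if (j > 1) gap_needed else 0)
      prev_cut <- cuts[j]
      st <- as.integer(floor(pos))
      out[[idx[j]]] <- .frag_row(ch, st, st + lens[idx[j]], "+")
      pos <- st + lens[idx[j]]
    }
  }
  do.call(rbind, out)
}

.build_template_once <- function(spec) {
  target <- spec$target_topology
  ring <- .sample_regions(spec, target)
  counts <- list(del = 0, inv = 0, dup = 0, fold = 0)
  r <- stats::runif(4)
  if (is.null(target)) {
    counts$del <- stats::rbinom(1, 2, spec$del_ratio)
    counts$inv <- stats::rbinom(1, 2, spec$inv_ratio)
    counts$dup <- stats::rbinom(1, 2, spec$dup_ratio)
    counts$fold <- stats::rbinom(1, 1, spec$foldback_ratio)
  } else if (target == "SimpleCircularization") {
  } else if (target == "SimpleSVs") {
    if (stats::runif(1) < 0.5) counts$del <- .runifint(1, 1, 3)
    else counts$inv <- .runifint(1, 1, 3)
  } else if (target == "MixedSVs") {
    counts$del <- .runifint(1, 1, 2)
    counts$inv <- .runifint(1, 1, 2)
  } else if (target %in% c("Multiregion", "Multichromosomal")) {
    counts$del <- as.integer(r[1] < spec$del_ratio)
    counts$inv <- as.integer(r[2] < spec$inv_ratio)
  } else if (target == "Duplications") {
    counts$dup <- 1L
    counts$del <- as.integer(r[1] < spec$del_ratio)
    counts$inv <- as.integer(r[2] < spec$inv_ratio)
  } else if (target == "Foldbacks") {
    counts$fold <- 1L
    counts$del <- as.integer(r[1] < spec$del_ratio)
    counts$inv <- as.integer(r[2] < spec$inv_ratio)
    counts$dup <- as.integer(r[3] < spec$dup_ratio)
  }
  for (k in seq_len(counts$del))
    ring <- .apply_del(ring, .runifint(1, spec$del_len[1],
                                       spec$del_len[2]))
  for (k in seq_len(counts$inv))
    ring <- .apply_inv(ring, .runifint(1, spec$inv_len[1],
                                       spec$inv_len[2]))
  for (k in seq_len(counts$dup))
    ring <- .apply_dup(ring, .runifint(1, spec$dup_len[1],
                                       spec$dup_len[2]))
  for (k in seq_len(counts$fold))
    ring <- .apply_foldback(ring, .runifint(1, spec$foldback_len[1],
                                            spec$foldback_len[2]))
  ring
}

#' Simulate one ecDNA template ring
#'
#' Samples amplified region(s) by the chromosome weights, then applies
#' small deletions, inversions, tandem duplications and foldbacks per the
#' spec ratios (or the mixture a requested target topology dictates).
#' When a target topology is requested the draw is rejection-sampled
#' until the resulting ring classifies as that topology.
#'
#' @param spec A [template_spec()].
#' @return data.frame ring (`chrom`, `start`, `end`, `orient`) with
#'   attribute `topology`.
#' @export
simulate_template <- function(spec) {
  set.seed(spec$seed)
  for (try in seq_len(spec$max_retry)) {
    ring <- .build_template_once(spec)
    topo <- classify_topology(ring)$name
    if (is.null(spec$target_topology) || topo == spec$target_topology) {
      attr(ring, "topology") <- topo
      return(ring)
    }
  }
  stop("could not hit target topology '", spec$target_topology,
       "' within ", spec$max_retry, " draws (seed ", spec$seed, ")")
}

#' Bundle templates into a ground truth
#'
#' @param templates List of template rings.
#' @param proportions Per-template copy-coverage (x).
#' @param background Linear-genome background coverage (x).
#' @param chrom_sizes Named chromosome lengths.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(templates, proportions, background = 5,
                         chrom_sizes = c(chr1 = 5e6, chr2 = 5e6)) {
  stopifnot(length(templates) == length(proportions))
  structure(list(templates = templates, proportions = proportions,
                 background = background, chrom_sizes = chrom_sizes),
            class = "ground_truth")
}

#' Noise specification for fixture emission
#'
#' @param cov_sigma Gaussian coverage noise s.d. (x), applied within the
#'   amplicon footprint on 100-bp bins.
#' @param bp_jitter Uniform breakend jitter half-width (bp).
#' @param fn_rate Probability of dropping a junction record (false
#'   negative).
#' @export
noise_spec <- function(cov_sigma = 0, bp_jitter = 0, fn_rate = 0) {
  list(cov_sigma = cov_sigma, bp_jitter = bp_jitter, fn_rate = fn_rate)
}

# translate a ring's junction geometry into Sniffles-style records;
# head-head/tail-tail pairs over one boundary pair collapse to one INV
.ring_to_svs <- function(ring) {
  j <- ring_junctions(ring)
  n <- nrow(ring)
  recs <- list()
  emit <- function(chrom1, pos1, chrom2, pos2, svtype, strands = NA) {
    recs[[length(recs) + 1]] <<- data.frame(
      chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
      svtype = svtype, strands = strands, stringsAsFactors = FALSE)
  }
  inv_seen <- character(0)
  for (i in seq_len(nrow(j))) {
    x <- j[i, ]
    if (x$kind == "adjacency") next
    if (x$kind %in% c("del", "dup")) {
      emit(x$chrom1, min(x$pos1, x$pos2), x$chrom1, max(x$pos1, x$pos2),
           toupper(x$kind))
    } else if (x$kind == "bnd") {
      emit(x$chrom1, x$pos1, x$chrom2, x$pos2, "BND",
           paste0(if (x$side1 == "head") "+" else "-",
                  if (x$side2 == "head") "+" else "-"))
    } else {                          # inversion-type (hh or tt)
      key <- paste(x$chrom1, min(x$pos1, x$pos2), max(x$pos1, x$pos2))
      if (x$pos1 != x$pos2) {
        if (key %in% inv_seen) next   # second junction of a paired INV
        mate <- which(j$kind == "inv" & j$chrom1 == x$chrom1 &
                        pmin(j$pos1, j$pos2) == min(x$pos1, x$pos2) &
                        pmax(j$pos1, j$pos2) == max(x$pos1, x$pos2))
        if (length(mate) >= 2) inv_seen <- c(inv_seen, key)
        emit(x$chrom1, min(x$pos1, x$pos2), x$chrom1,
             max(x$pos1, x$pos2), "INV")
      } else {
        # fold at a single boundary: record the inverted fragment extent
        inv_frag <- if (x$side2 == "head") ring[if (i == n) 1 else i + 1, ]
        else ring[i, ]
        emit(inv_frag$chrom, inv_frag$start, inv_frag$chrom, inv_frag$end,
             "INVDUP")
      }
    }
  }
  if (length(recs) == 0)
    return(data.frame(chrom1 = character(0), pos1 = integer(0),
                      chrom2 = character(0), pos2 = integer(0),
                      svtype = character(0), strands = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, recs)
}

.write_sv_vcf <- function(recs, chrom_sizes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=ecdecon-simulator",
               sprintf("##contig=<ID=%s,length=%d>", names(chrom_sizes),
                       as.integer(chrom_sizes)),
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
               "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"Mate chromosome\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Mate position\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
               "##INFO=<ID=STRANDS,Number=1,Type=String,Description=\"Breakend sides\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"Reference reads\">",
               "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"Variant reads\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "SAMPLE"),
                     collapse = "\t")), con)
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    len <- if (r$chrom1 == r$chrom2) abs(r$pos2 - r$pos1) else 0
    info <- sprintf("SVTYPE=%s;CHR2=%s;END=%d;SVLEN=%d", r$svtype,
                    r$chrom2, as.integer(r$pos2), as.integer(len))
    if (!is.na(r$strands)) info <- paste0(info, ";STRANDS=", r$strands)
    writeLines(sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\t%s\tGT:DR:DV\t./.:%d:%d",
                       r$chrom1, as.integer(r$pos1), paste0("sim", i),
                       r$svtype, info, as.integer(r$dr),
                       as.integer(r$support)), con)
  }
  invisible(path)
}

# expected coverage of the truth as one Rle per chromosome
.truth_coverage <- function(truth) {
  cs <- truth$chrom_sizes
  cov <- lapply(names(cs), function(ch)
    S4Vectors::Rle(truth$background, as.integer(cs[[ch]])))
  names(cov) <- names(cs)
  for (k in seq_along(truth$templates)) {
    ring <- truth$templates[[k]]
    p <- truth$proportions[k]
    for (ch in unique(ring$chrom)) {
      r <- ring[ring$chrom == ch, , drop = FALSE]
      add <- IRanges::coverage(IRanges::IRanges(r$start + 1L, r$end),
                               width = as.integer(cs[[ch]]))
      cov[[ch]] <- cov[[ch]] + p * add
    }
  }
  cov
}

#' Emit an idealized fixture for a ground truth
#'
#' Writes what upstream read simulation, alignment and SV calling would
#' yield under ideal conditions: a Sniffles-style VCF (one record per
#' template junction, support = rounded template proportion, breakends
#' jittered), a bedGraph coverage track (background plus
#' proportion-weighted fragment multiplicity, Gaussian noise within the
#' amplicon footprint) and the truth rings in thread-BED format.
#'
#' @param truth A [ground_truth()].
#' @param noise A [noise_spec()].
#' @param dir Output directory (created).
#' @return List with `vcf`, `coverage`, `truth_bed` paths and the emitted
#'   record table `svs`. Uses the current RNG stream.
#' @export
emit_fixture <- function(truth, noise = noise_spec(), dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  all_svs <- list()
  for (k in seq_along(truth$templates)) {
    svs <- .ring_to_svs(truth$templates[[k]])
    if (nrow(svs) == 0) next
    svs$support <- round(truth$proportions[k])
    all_svs[[length(all_svs) + 1]] <- svs
  }
  svs <- if (length(all_svs) == 0)
    data.frame(chrom1 = character(0), pos1 = integer(0),
               chrom2 = character(0), pos2 = integer(0),
               svtype = character(0), strands = character(0),
               support = numeric(0), stringsAsFactors = FALSE)
  else do.call(rbind, all_svs)
  if (nrow(svs) > 0) {
    # identical junctions from different templates collapse, support sums
    key <- paste(svs$chrom1, svs$pos1, svs$chrom2, svs$pos2, svs$svtype)
    agg <- stats::aggregate(svs$support, list(key = key), sum)
    svs <- svs[!duplicated(key), , drop = FALSE]
    svs$support <- agg$x[match(paste(svs$chrom1, svs$pos1, svs$chrom2,
                                     svs$pos2, svs$svtype), agg$key)]
    if (noise$fn_rate > 0)
      svs <- svs[stats::runif(nrow(svs)) >= noise$fn_rate, , drop = FALSE]
    if (noise$bp_jitter > 0 && nrow(svs) > 0) {
      svs$pos1 <- svs$pos1 + .runifint(nrow(svs), -noise$bp_jitter,
                                       noise$bp_jitter)
      svs$pos2 <- svs$pos2 + .runifint(nrow(svs), -noise$bp_jitter,
                                       noise$bp_jitter)
    }
    svs$dr <- rep(round(truth$background), nrow(svs))
  } else svs$dr <- numeric(0)
  vcf <- file.path(dir, "sv.vcf")
  .write_sv_vcf(svs, truth$chrom_sizes, vcf)

  cov <- .truth_coverage(truth)
  grl <- lapply(names(cov), function(ch) {
    r <- cov[[ch]]
    gr <- GenomicRanges::GRanges(ch, IRanges::ranges(r), score =
                                   S4Vectors::runValue(r))
    gr
  })
  gr <- suppressWarnings(do.call(c, grl))
  if (noise$cov_sigma > 0) {
    foot <- list()
    for (k in seq_along(truth$templates)) {
      ring <- truth$templates[[k]]
      foot[[k]] <- GenomicRanges::GRanges(ring$chrom,
                                          IRanges::IRanges(ring$start + 1L,
                                                           ring$end))
    }
    foot <- GenomicRanges::reduce(do.call(c, foot))
    bins <- unlist(GenomicRanges::tile(foot, width = 100))
    pieces <- GenomicRanges::disjoin(c(GenomicRanges::granges(gr), bins))
    hit <- GenomicRanges::findOverlaps(pieces, gr,
                                       type = "within", select = "first")
    val <- gr$score[hit]
    noisy <- S4Vectors::queryHits(GenomicRanges::findOverlaps(pieces, foot,
                                                              type = "within"))
    val[noisy] <- pmax(0, val[noisy] +
                         stats::rnorm(length(noisy), 0, noise$cov_sigma))
    pieces$score <- val
    gr <- pieces
  }
  GenomeInfoDb::seqlengths(gr) <-
    truth$chrom_sizes[GenomeInfoDb::seqlevels(gr)]
  covpath <- file.path(dir, "coverage.bedGraph")
  rtracklayer::export(gr, covpath, format = "bedGraph")

  truth_bed <- file.path(dir, "truth.bed")
  recs <- truth_reconstructions(truth)
  write_bed(recs, truth_bed)
  list(vcf = vcf, coverage = covpath, truth_bed = truth_bed, svs = svs)
}

#' Truth templates as reconstruction records
#'
#' @param truth A [ground_truth()].
#' @return List of `reconstruction` (circ_id = template index, coverage =
#'   expected coverage per fragment, topology from [classify_topology()]).
#' @export
truth_reconstructions <- function(truth) {
  cov <- .truth_coverage(truth)
  lapply(seq_along(truth$templates), function(k) {
    ring <- truth$templates[[k]]
    mc <- vapply(seq_len(nrow(ring)), function(i) {
      r <- cov[[ring$chrom[i]]]
      as.numeric(mean(S4Vectors::window(r, ring$start[i] + 1L,
                                        ring$end[i])))
    }, numeric(1))
    rg <- data.frame(ring, mean_cov = mc,
                     fragment_id = seq_len(nrow(ring)),
                     stringsAsFactors = FALSE)
    topo <- classify_topology(ring)$name
    reconstruction(k, rg, truth$proportions[k], topo,
                   if (sum(ring$end - ring$start) > 1e5) "ecDNA"
                   else "circular")
  })
}

#' Mix ground truths at given ratios
#'
#' Template proportions are scaled by the per-truth ratios and the truths
#' are concatenated; emitting the mixture sums the scaled coverage tracks
#' and merges the scaled-support VCF records, mirroring in silico BAM
#' dilution and merging.
#'
#' @param truths List of [ground_truth()] (same chromosome sizes).
#' @param ratios Numeric in (0, 1], one per truth.
#' @return A combined `ground_truth`.
#' @export
mix_fixtures <- function(truths, ratios) {
  if (length(truths) != length(ratios))
    stop("need exactly one ratio per ground truth")
  stopifnot(all(ratios > 0), all(ratios <= 1))
  templates <- list()
  props <- numeric(0)
  bg <- 0
  for (i in seq_along(truths)) {
    templates <- c(templates, truths[[i]]$templates)
    props <- c(props, truths[[i]]$proportions * ratios[i])
    bg <- bg + truths[[i]]$background * ratios[i]
  }
  ground_truth(templates, props, bg, truths[[1]]$chrom_sizes)
}

#' Generate a toy reference genome
#'
#' A seeded random DNA sequence per chromosome, used only when sequence
#' output (FASTA) is requested; simulation and reconstruction otherwise
#' operate on coordinates alone.
#'
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Integer seed.
#' @return A [Biostrings::DNAStringSet].
#' @export
toy_genome <- function(chrom_sizes = c(chr1 = 5e6, chr2 = 5e6), seed = 1) {
  set.seed(seed)
  seqs <- vapply(chrom_sizes, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = ""), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(chrom_sizes)
  out
}
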