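#' Coverage profiles
#'
#' A coverage profile holds the per-base alignment coverage of a long-read
#' whole-genome sequencing run as one run-length-encoded vector per
#' chromosome. Coordinates are 0-based half-open throughout the package;
#' positions outside the stored extent read as 0.
#'
#' @param gr A [GenomicRanges::GRanges] with a numeric `score` column
#'   (as returned by [rtracklayer::import()] for bedGraph/BigWig tracks).
#' @return An object of class `coverage_profile`: a list with elements
#'   `cov` (named list of [S4Vectors::Rle], one per chromosome) and
#'   `genome_mean` (mean coverage over the covered extent).
#' @export
coverage_profile <- function(gr) {
  stopifnot(methods::is(gr, "GRanges"))
  if (!"score" %in% names(S4Vectors::mcols(gr)))
    stop("coverage track has no 'score' column")
  cov <- as.list(GenomicRanges::coverage(gr, weight = "score"))
  structure(list(cov = cov, genome_mean = .profile_genome_mean(cov)),
            class = "coverage_profile")
}

.profile_genome_mean <- function(cov) {
  tot <- sum(vapply(cov, function(r) as.numeric(sum(r)), numeric(1)))
  len <- sum(vapply(cov, length, numeric(1)))
  if (len == 0) 0 else tot / len
}

#' Read a coverage track (bedGraph or BigWig)
#'
#' @param path Path to a 4-column bedGraph or a BigWig file. The format is
#'   guessed from the extension unless given.
#' @param format One of `"auto"`, `"bedGraph"`, `"bigWig"`.
#' @return A [coverage_profile].
#' @export
read_coverage <- function(path, format = c("auto", "bedGraph", "bigWig")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE))
      "bigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = format)
  coverage_profile(gr)
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile:", length(x$cov), "chromosome(s), genome mean",
      format(x$genome_mean, digits = 4), "x\n")
  invisible(x)
}

#' Mean coverage over an interval
#'
#' Length-weighted mean of the profile over `[start, end)` (0-based);
#' bases beyond the stored extent contribute 0.
#'
#' @param profile A [coverage_profile].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return A single numeric mean coverage.
#' @export
profile_mean <- function(profile, chrom, start, end) {
  if (end <= start) stop("zero-length interval [", start, ",", end, ")")
  r <- profile$cov[[chrom]]
  n <- end - start
  if (is.null(r)) return(0)
  s <- start + 1L
  e <- min(end, length(r))
  if (s > e) return(0)
  as.numeric(sum(S4Vectors::window(r, s, e))) / n
}

#' Coverage value at a single base
#'
#' @inheritParams profile_mean
#' @param pos 0-based position.
#' @export
profile_value <- function(profile, chrom, pos) {
  r <- profile$cov[[chrom]]
  if (is.null(r) || pos < 0 || pos + 1 > length(r)) return(0)
  as.numeric(r[pos + 1L])
}

#' Background (linear genome) coverage estimate
#'
#' Median coverage over positions outside the supplied regions, used as the
#' operational "WGS mean coverage" default when filtering cycle candidates.
#' Falls back to the genome-wide median when the regions cover everything.
#'
#' @param profile A [coverage_profile].
#' @param exclude Optional data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) of regions to exclude (typically the amplified
#'   regions).
#' @return Median background coverage.
#' @export
background_coverage <- function(profile, exclude = NULL) {
  vals <- numeric(0)
  lens <- numeric(0)
  for (chrom in names(profile$cov)) {
    r <- profile$cov[[chrom]]
    keep <- IRanges::IRanges(1L, length(r))
    if (!is.null(exclude)) {
      ex <- exclude[exclude$chrom == chrom, , drop = FALSE]
      if (nrow(ex) > 0) {
        exr <- IRanges::IRanges(ex$start + 1L, ex$end)
        keep <- IRanges::setdiff(keep, exr)
      }
    }
    if (length(keep) == 0) next
    v <- r[keep]
    vals <- c(vals, S4Vectors::runValue(v))
    lens <- c(lens, S4Vectors::runLength(v))
  }
  if (length(vals) == 0) {  # regions cover everything: genome-wide median
    for (chrom in names(profile$cov)) {
      r <- profile$cov[[chrom]]
      vals <- c(vals, S4Vectors::runValue(r))
      lens <- c(lens, S4Vectors::runLength(r))
    }
  }
  .weighted_median(vals, lens)
}

.weighted_median <- function(v, w) {
  if (length(v) == 0) return(0)
  o <- order(v)
  v <- v[o]; w <- w[o]
  cw <- cumsum(w)
  v[which(cw >= sum(w) / 2)[1]]
}

#' Amplified regions of the genome
#'
#' Regions worth segmenting: the union of intervals where coverage strictly
#' exceeds `min_cov` (reduced with `merge_gap`), plus a `pad` window around
#' every clean breakpoint so that each breakpoint lies strictly inside a
#' region. Genome-wide segmentation is wasteful because low-coverage
#' fragments are pruned downstream anyway.
#'
#' @param profile A [coverage_profile].
#' @param breakpoints Optional data.frame with `chrom`, `pos` (clean
#'   breakpoints, 0-based boundaries).
#' @param min_cov Coverage threshold (default 5, matching fragment pruning).
#' @param pad Half-width of the window added around each breakpoint (bp).
#' @param merge_gap Regions closer than this are merged (bp).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   sorted.
#' @export
amplified_regions <- function(profile, breakpoints = NULL, min_cov = 5,
                              pad = 500, merge_gap = 1000) {
  out <- list()
  chroms <- union(names(profile$cov),
                  if (is.null(breakpoints)) character(0) else
                    unique(breakpoints$chrom))
  for (chrom in chroms) {
    r <- profile$cov[[chrom]]
    ir <- if (is.null(r)) IRanges::IRanges() else
      IRanges::ranges(IRanges::slice(r, lower = min_cov,
                                     includeLower = FALSE))
    if (!is.null(breakpoints)) {
      bp <- breakpoints[breakpoints$chrom == chrom, , drop = FALSE]
      if (nrow(bp) > 0)
        ir <- c(ir, IRanges::IRanges(pmax(1L, bp$pos - pad + 1L),
                                     bp$pos + pad))
    }
    if (length(ir) == 0) next
    ir <- IRanges::reduce(ir, min.gapwidth = merge_gap)
    out[[chrom]] <- data.frame(chrom = chrom,
                               start = IRanges::start(ir) - 1L,
                               end = IRanges::end(ir),
                               stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
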