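#' Segment amplified regions into non-overlapping fragments
#'
#' Within each contiguous region, `n` clean breakpoints strictly inside the
#' region split it into exactly `n + 1` fragments tiling the region without
#' gap or overlap. Breakpoint positions are 0-based boundaries; a
#' breakpoint falling outside every region (and not on a region edge) is
#' dropped with a warning.
#'
#' @param breakpoints data.frame with `chrom`, `pos` from
#'   [merge_breakpoints()].
#' @param regions data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [amplified_regions()].
#' @return data.frame with `fid`, `chrom`, `start`, `end`, `mean_cov`
#'   (`NA` until [annotate_coverage()]), sorted by `(chrom, start)`,
#'   `fid` = row number.
#' @export
fragment_genome <- function(breakpoints, regions) {
  used <- rep(FALSE, nrow(breakpoints))
  frags <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    inside <- which(breakpoints$chrom == rg$chrom &
                      breakpoints$pos > rg$start & breakpoints$pos < rg$end)
    on_edge <- which(breakpoints$chrom == rg$chrom &
                       (breakpoints$pos == rg$start |
                          breakpoints$pos == rg$end))
    used[inside] <- TRUE
    used[on_edge] <- TRUE
    bnd <- sort(unique(c(rg$start, breakpoints$pos[inside], rg$end)))
    frags[[i]] <- data.frame(chrom = rg$chrom,
                             start = bnd[-length(bnd)],
                             end = bnd[-1],
                             stringsAsFactors = FALSE)
  }
  if (any(!used) && nrow(breakpoints) > 0) {
    drop <- breakpoints[!used, , drop = FALSE]
    if (nrow(drop) > 0)
      warning(nrow(drop), " breakpoint(s) outside every region dropped: ",
              paste(paste0(drop$chrom, ":", drop$pos), collapse = ", "))
  }
  out <- if (length(frags) == 0)
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, frags)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- data.frame(fid = seq_len(nrow(out)), out, mean_cov = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Annotate fragments with mean coverage
#'
#' Sets `mean_cov` to the length-weighted mean of the profile over each
#' fragment, and records the boundary coverages `cov_start` (value at
#' `start`) and `cov_end` (value at `end - 1`) used to approximate
#' junction-spanning read counts for spatial edges.
#'
#' @param fragments data.frame from [fragment_genome()].
#' @param profile A [coverage_profile].
#' @return The fragments with `mean_cov`, `cov_start`, `cov_end` filled in.
#' @export
annotate_coverage <- function(fragments, profile) {
  if (nrow(fragments) > 0 && any(fragments$end <= fragments$start))
    stop("zero-length fragment in input")
  n <- nrow(fragments)
  mc <- numeric(n); cs <- numeric(n); ce <- numeric(n)
  for (i in seq_len(n)) {
    mc[i] <- profile_mean(profile, fragments$chrom[i], fragments$start[i],
                          fragments$end[i])
    cs[i] <- profile_value(profile, fragments$chrom[i], fragments$start[i])
    ce[i] <- profile_value(profile, fragments$chrom[i],
                           fragments$end[i] - 1L)
  }
  fragments$mean_cov <- mc
  fragments$cov_start <- cs
  fragments$cov_end <- ce
  fragments
}

#' Export breakpoints or fragments as BED
#'
#' Clean breakpoints become 1-bp BED3 features; fragments become BED4
#' (`name` = fid).
#'
#' @param x Breakpoints (columns `chrom`, `pos`) or fragments (`chrom`,
#'   `start`, `end`, `fid`).
#' @param path Output file.
#' @export
write_bed3 <- function(x, path) {
  if ("pos" %in% names(x)) {
    df <- data.frame(x$chrom, x$pos, x$pos + 1L)
  } else {
    df <- data.frame(x$chrom, x$start, x$end, x$fid)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
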