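#' Run configuration
#'
#' Aggregates the pipeline thresholds with their defaults: SV on-target
#' coverage >= 5x, VAF >= 0.01, 50-bp breakpoint merge window, fragment
#' pruning at <= 5x, LASSO penalty 0.1, ecDNA label above 0.1 Mb,
#' multiregion gap 10 kb, at most 8 simple cycles per cluster entering
#' combinations, Jaccard dissimilarity threshold 0.8, evaluation breakend
#' tolerance 50 bp.
#'
#' @param min_sv_cov,min_vaf,merge_window,prune_cov,alpha,min_ecdna_len
#'   See description.
#' @param region_gap,max_simple,dissim_threshold,eval_tol See description.
#' @param wgs_mean `"auto"` (median background coverage outside amplified
#'   regions) or a number.
#' @param max_gap Maximum spatial-adjacency gap (bp), unlimited by
#'   default.
#' @param pad,merge_gap Amplified-region construction parameters.
#' @param seed Optional integer seed echoed to the log.
#' @return List of class `run_config`.
#' @export
run_config <- function(min_sv_cov = 5, min_vaf = 0.01, merge_window = 50,
                       prune_cov = 5, alpha = 0.1, min_ecdna_len = 1e5,
                       region_gap = 1e4, max_simple = 8,
                       dissim_threshold = 0.8, eval_tol = 50,
                       wgs_mean = "auto", max_gap = Inf, pad = 500,
                       merge_gap = 1000, seed = NULL) {
  structure(as.list(environment()), class = "run_config")
}

.log_line <- function(lines, ...) c(lines, paste0(...))

#' Reconstruct circular elements from SV calls and coverage
#'
#' Runs the full pipeline: parse and filter SVs, merge breakpoints,
#' segment amplified regions into fragments, build and prune the amplicon
#' multigraph, enumerate simple cycles, cluster them, generate derived
#' cycles, fit the per-cluster LASSO, select and filter candidates,
#' classify topologies and write the outputs (`reconstructions.bed`,
#' `summary.txt`, `fits.tsv`, `log.txt`, and `reconstructions.fasta` when
#' a reference is given). A run with no surviving SVs or candidates
#' succeeds with empty outputs.
#'
#' @param vcf Path to the SV VCF.
#' @param coverage Path to the coverage track (bedGraph/BigWig).
#' @param outdir Output directory (created).
#' @param reference Optional reference FASTA (or DNAStringSet) for
#'   sequence output.
#' @param config A [run_config()].
#' @return Invisibly, a list with `reconstructions` (list of
#'   `reconstruction`), `counts` (per-stage tallies), `paths`.
#' @export
run_reconstruct <- function(vcf, coverage, outdir,
                            reference = NULL, config = run_config()) {
  if (!file.exists(vcf)) stop("missing input VCF: ", vcf)
  if (!file.exists(coverage)) stop("missing coverage track: ", coverage)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .log_line(log, "config: ", paste(names(config), "=",
                                          vapply(config, function(x)
                                            paste(format(x), collapse = ","),
                                            character(1)),
                                          collapse = "; "))
  svs <- parse_sv_vcf(vcf)
  profile <- read_coverage(coverage)
  svs_f <- filter_svs(svs, config$min_sv_cov, config$min_vaf,
                      profile = profile)
  log <- .log_line(log, "svs: ", nrow(svs), " parsed, ", nrow(svs_f),
                   " after filters")

  finish <- function(recs, counts) {
    paths <- list(bed = file.path(outdir, "reconstructions.bed"),
                  summary = file.path(outdir, "summary.txt"),
                  fits = file.path(outdir, "fits.tsv"),
                  log = file.path(outdir, "log.txt"))
    write_bed(recs, paths$bed)
    write_summary(recs, paths$summary)
    if (!is.null(reference) && length(recs) > 0) {
      paths$fasta <- file.path(outdir, "reconstructions.fasta")
      write_fasta(recs, reference, paths$fasta)
    }
    writeLines(log, paths$log)
    invisible(list(reconstructions = recs, counts = counts,
                   paths = paths))
  }

  if (nrow(svs_f) == 0) {
    log <- .log_line(log, "no SVs pass the filters; no circular elements")
    return(finish(list(), list(n_sv = nrow(svs), n_sv_filtered = 0)))
  }

  bps <- merge_breakpoints(svs_f, config$merge_window)
  regions <- amplified_regions(profile, bps, min_cov = config$prune_cov,
                               pad = config$pad,
                               merge_gap = config$merge_gap)
  frags <- annotate_coverage(fragment_genome(bps, regions), profile)
  log <- .log_line(log, "fragmentation: ", nrow(bps),
                   " clean breakpoints, ", nrow(regions), " regions, ",
                   nrow(frags), " fragments")

  g <- build_graph(frags, svs_f, profile, attr(bps, "map"),
                   config$max_gap)
  g <- prune_graph(g, config$prune_cov)
  log <- .log_line(log, "graph: ", nrow(g$fragments),
                   " fragments after pruning, ", nrow(g$edges), " edges")

  cycles <- find_simple_cycles(g)
  clusters <- partition_cycles(cycles)
  log <- .log_line(log, "cycles: ", length(cycles), " simple in ",
                   length(clusters), " cluster(s)")
  wgs_mean <- if (identical(config$wgs_mean, "auto"))
    background_coverage(profile, regions) else as.numeric(config$wgs_mean)
  log <- .log_line(log, "wgs mean coverage: ", format(wgs_mean))

  recs <- list()
  fit_rows <- list()
  for (cl in clusters) {
    derived <- derive_cycles(cl, g, config$max_simple,
                             config$dissim_threshold)
    all_cycles <- c(cl$cycles, derived)
    dm <- build_design_matrix(all_cycles, g$fragments)
    fit <- fit_lasso(dm, config$alpha, beta0 = wgs_mean)
    sel <- select_cycles(fit, dm)
    cand <- filter_candidates(sel, wgs_mean, config$min_ecdna_len)
    log <- .log_line(log, "cluster ", cl$cid, ": ", length(cl$cycles),
                     " simple + ", length(derived), " derived cycles, ",
                     sum(cand$selected), " candidate(s), objective ",
                     format(fit$objective))
    fit_rows[[length(fit_rows) + 1]] <- data.frame(
      cluster = cl$cid, canon_key = sel$canon_key,
      beta = sel$proportion, threshold = sel$threshold,
      selected = sel$selected, alpha = fit$alpha,
      objective = fit$objective, stringsAsFactors = FALSE)
    kept <- attr(cand, "cycles")
    for (ci in seq_along(kept)) {
      cyc <- kept[[ci]]
      ring <- cycle_ring(cyc, g$fragments)
      topo <- classify_topology(ring[, c("chrom", "start", "end",
                                         "orient")],
                                region_gap = config$region_gap)
      recs[[length(recs) + 1]] <- reconstruction(
        0L, ring, cand$proportion[ci], topo$name, cand$label[ci])
    }
  }
  if (length(recs) > 0) {
    ord <- order(-vapply(recs, function(r) r$proportion, numeric(1)))
    recs <- recs[ord]
    for (i in seq_along(recs)) recs[[i]]$circ_id <- i
  }
  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else
    data.frame()
  utils::write.table(fits, file.path(outdir, "fits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- .log_line(log, "output: ", length(recs), " circular element(s)")
  finish(recs, list(n_sv = nrow(svs), n_sv_filtered = nrow(svs_f),
                    n_breakpoints = nrow(bps), n_fragments = nrow(frags),
                    n_pruned_fragments = nrow(g$fragments),
                    n_cycles = length(cycles),
                    n_clusters = length(clusters),
                    n_reconstructions = length(recs)))
}

#' Simulate templates and emit fixtures
#'
#' @param n Number of templates (one fixture directory each).
#' @param outdir Output directory; per-template subdirectories `sim_i`.
#' @param topology Optional target topology for all templates.
#' @param proportion Range the per-template copy-coverage is drawn from.
#' @param background Background coverage (x).
#' @param noise A [noise_spec()].
#' @param seed Integer master seed; template `i` uses `seed + i`.
#' @param spec_args Extra arguments passed to [template_spec()].
#' @return Invisibly, list with per-template `dir`, `truth`, `paths`;
#'   a `manifest.tsv` in `outdir` lists seeds and topologies.
#' @export
run_simulate <- function(n, outdir, topology = NULL,
                         proportion = c(20, 80), background = 5,
                         noise = noise_spec(), seed = 1,
                         spec_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- vector("list", n)
  man <- list()
  for (i in seq_len(n)) {
    si <- seed + i
    spec <- do.call(template_spec,
                    c(list(target_topology = topology, seed = si),
                      spec_args))
    ring <- simulate_template(spec)
    p <- stats::runif(1, proportion[1], proportion[2])
    truth <- ground_truth(list(ring), p, background, spec$chrom_sizes)
    d <- file.path(outdir, sprintf("sim_%03d", i))
    paths <- emit_fixture(truth, noise, d)
    out[[i]] <- list(dir = d, truth = truth, paths = paths)
    man[[i]] <- data.frame(sim = i, seed = si,
                           topology = attr(ring, "topology"),
                           proportion = p, n_fragments = nrow(ring),
                           stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, man),
                     file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Evaluate reconstructions against a truth
#'
#' Scores every truth ring with its best normalized largest contig over
#' the reconstructions and pools breakpoint recall/precision.
#'
#' @param truth_bed Thread-BED of the truth (from [emit_fixture()]) or a
#'   list of `reconstruction`.
#' @param rec_bed Thread-BED written by [run_reconstruct()] or a list of
#'   `reconstruction`.
#' @param tol Breakend/boundary tolerance (bp).
#' @param report Optional path for a TSV report.
#' @return List with `per_truth` (data.frame: circ_id,
#'   largest_contig_norm), `recall`, `precision`, `mean_contig`,
#'   `sd_contig`.
#' @export
run_evaluate <- function(truth_bed, rec_bed, tol = 50, report = NULL) {
  truths <- if (is.character(truth_bed)) read_bed(truth_bed) else truth_bed
  recs <- if (is.character(rec_bed)) read_bed(rec_bed) else rec_bed
  per <- lapply(truths, function(tr) {
    scores <- vapply(recs, function(r)
      largest_contig_normalized(r$ring, tr$ring, tol), numeric(1))
    data.frame(circ_id = tr$circ_id,
               largest_contig_norm = if (length(scores)) max(scores) else 0)
  })
  per <- do.call(rbind, per)
  br <- breakpoint_recall(recs, truths, tol)
  res <- list(per_truth = per, recall = br$recall,
              precision = br$precision,
              mean_contig = mean(per$largest_contig_norm),
              sd_contig = stats::sd(per$largest_contig_norm))
  if (!is.null(report)) {
    df <- per
    df$recall <- br$recall
    df$precision <- br$precision
    utils::write.table(df, report, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  res
}

#' Simulate, reconstruct and score a batch of templates
#'
#' The benchmark loop used for performance evaluation: for each template,
#' simulate under the requested topology, emit an idealized fixture with
#' the given noise, run the full reconstruction with default thresholds
#' and score the best normalized largest contig against the truth ring.
#'
#' @param topologies Character vector; templates cycle through it.
#' @param n_per Templates per topology.
#' @param noise A [noise_spec()].
#' @param seed Master seed.
#' @param proportion,background Fixture intensity parameters.
#' @param dir Working directory for fixtures/outputs (default temp).
#' @param config A [run_config()].
#' @return data.frame with `topology`, `seed`, `largest_contig_norm`,
#'   `recall`, `n_reconstructions`.
#' @export
run_benchmark <- function(topologies, n_per, noise = noise_spec(),
                          seed = 1, proportion = c(20, 80),
                          background = 5, dir = tempfile(),
                          config = run_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  idx <- 0
  for (topo in topologies) for (i in seq_len(n_per)) {
    idx <- idx + 1
    si <- (seed * 10000L + idx * 13L) %% .Machine$integer.max
    spec <- template_spec(target_topology = topo, seed = si)
    ring <- simulate_template(spec)
    p <- stats::runif(1, proportion[1], proportion[2])
    truth <- ground_truth(list(ring), p, background, spec$chrom_sizes)
    d <- file.path(dir, sprintf("bench_%04d", idx))
    fx <- emit_fixture(truth, noise, d)
    res <- run_reconstruct(fx$vcf, fx$coverage, file.path(d, "out"),
                           config = config)
    ev <- run_evaluate(truth_reconstructions(truth),
                       res$reconstructions, tol = config$eval_tol)
    rows[[idx]] <- data.frame(
      topology = topo, seed = si,
      largest_contig_norm = ev$per_truth$largest_contig_norm[1],
      recall = ev$recall,
      n_reconstructions = length(res$reconstructions),
      stringsAsFactors = FALSE)
    unlink(d, recursive = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
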