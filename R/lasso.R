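#' Build the per-cluster design matrix
#'
#' Rows are the fragments composing the cluster's cycles (sorted by
#' genomic position), columns are the candidate cycles (simple then
#' derived); entry `x[j, i]` counts how many times fragment `j` occurs in
#' cycle `i`'s ring. `y[j]` is the fragment's mean coverage.
#'
#' @param cycles List of `ec_cycle` (simple and derived) of one cluster.
#' @param fragments Annotated fragment table.
#' @return List with `X` (count matrix), `y` (coverage vector), `cycles`
#'   (the column cycles), `fragments` (the row fragments), of class
#'   `design_matrix`.
#' @export
build_design_matrix <- function(cycles, fragments) {
  stopifnot(length(cycles) > 0)
  # cycles with the exact same fragment multiset (e.g. a
  # reference-continuity path shadowing an inverted path, or the two
  # orientation readings of a segment) give identical occurrence columns
  # and are indistinguishable to the regression; keep the representative
  # whose junctions carry the most read support
  min_sup <- vapply(cycles, function(c) min(c$weights), numeric(1))
  mean_sup <- vapply(cycles, function(c) mean(c$weights), numeric(1))
  keys <- vapply(cycles, function(c) c$canon_key, character(1))
  cycles <- cycles[order(-min_sup, -mean_sup, keys)]
  colkey <- vapply(cycles, function(c)
    paste(sort(c$fids), collapse = ","), character(1))
  cycles <- cycles[!duplicated(colkey)]
  fids <- sort(unique(unlist(lapply(cycles, function(c) c$fids))))
  fr <- fragments[match(fids, fragments$fid), , drop = FALSE]
  fr <- fr[order(fr$chrom, fr$start), , drop = FALSE]
  if (any(is.na(fr$mean_cov)))
    stop("cluster fragments lack mean coverage; run annotate_coverage()")
  X <- vapply(cycles, function(c) tabulate(match(c$fids, fr$fid),
                                           nrow(fr)),
              numeric(nrow(fr)))
  X <- matrix(X, nrow = nrow(fr))
  colnames(X) <- vapply(cycles, function(c) c$canon_key, character(1))
  structure(list(X = X, y = fr$mean_cov, cycles = cycles, fragments = fr),
            class = "design_matrix")
}

#' Fit the non-negative LASSO of coverage on cycle membership
#'
#' Minimizes `mean((y - b0 - X b)^2) + alpha * sum(b)` over `b >= 0` with
#' an unpenalized intercept `b0` (the linear-genome background coverage),
#' by cyclic coordinate descent. Columns are not standardized so the
#' coefficients stay in coverage units and read directly as estimated
#' cycle proportions.
#'
#' @details With `beta0 = NULL` the intercept is free (unpenalized). The
#' intercept is only identifiable when the cluster's fragments are not
#' uniformly explained by the cycles; for a uniform-coverage cluster the
#' free intercept absorbs the whole signal. The reconstruction pipeline
#' therefore fixes `beta0` to the background coverage measured outside
#' the amplified regions, which is where the linear-genome level is
#' actually observable.
#'
#' @param dm A `design_matrix`.
#' @param alpha L1 penalty weight (default 0.1).
#' @param beta0 `NULL` for a free intercept, or a fixed value (the
#'   measured linear-genome background coverage).
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Iteration cap.
#' @return List of class `lasso_fit`: `beta` (one per cycle), `beta0`,
#'   `alpha`, `objective`, `n_iter`, `converged`.
#' @export
fit_lasso <- function(dm, alpha = 0.1, beta0 = NULL, tol = 1e-6,
                      max_iter = 1e5) {
  stopifnot(alpha >= 0)
  X <- dm$X; y <- dm$y
  n <- length(y); p <- ncol(X)
  beta <- numeric(p)
  fixed_b0 <- !is.null(beta0)
  beta0 <- if (fixed_b0) beta0 else mean(y)
  xtx <- colSums(X^2)
  fitted <- as.vector(X %*% beta)
  it <- 0L
  repeat {
    it <- it + 1L
    delta <- 0
    if (!fixed_b0) {
      b0_new <- mean(y - fitted)
      delta <- max(delta, abs(b0_new - beta0))
      beta0 <- b0_new
    }
    for (j in seq_len(p)) {
      if (xtx[j] == 0) next
      r <- y - beta0 - fitted + X[, j] * beta[j]
      bj <- max(0, (sum(X[, j] * r) - alpha * n / 2) / xtx[j])
      if (bj != beta[j]) {
        fitted <- fitted + X[, j] * (bj - beta[j])
        delta <- max(delta, abs(bj - beta[j]))
        beta[j] <- bj
      }
    }
    if (delta < tol) break
    if (it >= max_iter)
      stop("LASSO coordinate descent did not converge after ", max_iter,
           " sweeps (last max update ", format(delta), ")")
  }
  obj <- lasso_objective(X, y, beta, beta0, alpha)
  structure(list(beta = beta, beta0 = beta0, alpha = alpha,
                 objective = obj, n_iter = it, converged = TRUE),
            class = "lasso_fit")
}

#' Evaluate the LASSO cost function
#'
#' `mean((y - b0 - X b)^2) + alpha * sum(abs(b))`; exposed so the reported
#' objective can be recomputed independently of the solver.
#'
#' @param X,y Design matrix and response.
#' @param beta,beta0 Coefficients and intercept.
#' @param alpha Penalty weight.
#' @export
lasso_objective <- function(X, y, beta, beta0, alpha) {
  mean((y - beta0 - as.vector(X %*% beta))^2) + alpha * sum(abs(beta))
}

# Redistribute weight held by derived cycles whose constituent simple
# cycles also hold weight. A derived column equals the sum of its
# constituents' columns, so the fit is unchanged; a derived cycle kept
# alongside a positive constituent is re-read as co-occurring separate
# elements rather than one merged structure.
.unmerge_redundant <- function(beta, cycles, eps = 1e-8) {
  keys <- vapply(cycles, function(c) c$canon_key, character(1))
  repeat {
    fired <- FALSE
    for (i in seq_along(cycles)) {
      c <- cycles[[i]]
      if (!c$is_derived || beta[i] <= eps) next
      ci <- match(c$constituents, keys)
      if (any(is.na(ci))) next
      if (any(beta[ci] > eps)) {
        beta[ci] <- beta[ci] + beta[i]
        beta[i] <- 0
        fired <- TRUE
      }
    }
    if (!fired) break
  }
  beta
}

#' Select likely cycles from a fit
#'
#' Per cycle the minimum fragment coverage `m_i = min(mean_cov)` over its
#' fragments is computed; the selection threshold is `t = max(m_i) / 4`
#' over the cluster's cycles, and cycles with coefficient strictly above
#' `t` are kept, sorted by decreasing coefficient (the higher the
#' coefficient, the more likely the cycle). Before thresholding, weight
#' held jointly by a derived cycle and one of its constituents is
#' redistributed onto the constituents (see Details).
#'
#' @details A derived cycle's occurrence column is exactly the sum of its
#' constituents' columns, so the L1 optimum is degenerate between "one
#' merged structure" and "separate co-occurring structures". When the
#' data force a constituent to carry weight of its own, the merged reading
#' cannot explain the coverage alone and the separate-elements reading is
#' reported; a derived cycle whose constituents all sit at zero is the
#' signature of a genuine interspersed duplication and is kept merged.
#'
#' @param fit A `lasso_fit`.
#' @param dm The `design_matrix` it was fitted on.
#' @param unmerge Apply the redistribution step (default `TRUE`).
#' @return data.frame with columns `canon_key`, `proportion`, `min_cov`,
#'   `threshold`, `selected`, plus the cycle objects in the
#'   `cycles` attribute, sorted by decreasing proportion.
#' @export
select_cycles <- function(fit, dm, unmerge = TRUE) {
  beta <- fit$beta
  if (unmerge) beta <- .unmerge_redundant(beta, dm$cycles)
  m <- vapply(seq_along(dm$cycles), function(i)
    min(dm$fragments$mean_cov[dm$X[, i] > 0]), numeric(1))
  thr <- max(m) / 4
  out <- data.frame(
    canon_key = vapply(dm$cycles, function(c) c$canon_key, character(1)),
    proportion = beta, min_cov = m, threshold = thr,
    selected = beta > thr, stringsAsFactors = FALSE)
  ord <- order(-out$proportion, out$canon_key)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cycles") <- dm$cycles[ord]
  out
}

#' Global candidate filters
#'
#' Drops cycles whose estimated proportion is at or below the WGS mean
#' coverage, and labels the survivors: circular elements longer than
#' `min_ecdna_len` (default 0.1 Mb) are `"ecDNA"`, shorter ones stay in
#' the output labeled `"circular"`.
#'
#' @param selection Output of [select_cycles()] (rows with
#'   `selected == TRUE` are considered).
#' @param wgs_mean WGS mean (background) coverage.
#' @param min_ecdna_len ecDNA length threshold in bp.
#' @return The retained rows with a `label` column; cycles attribute
#'   subset accordingly.
#' @export
filter_candidates <- function(selection, wgs_mean, min_ecdna_len = 1e5) {
  stopifnot(wgs_mean >= 0)
  cycles <- attr(selection, "cycles")
  keep <- selection$selected & selection$proportion > wgs_mean
  out <- selection[keep, , drop = FALSE]
  kept_cycles <- cycles[keep]
  out$total_len <- vapply(kept_cycles, function(c) c$total_len, numeric(1))
  out$label <- ifelse(out$total_len > min_ecdna_len, "ecDNA", "circular")
  rownames(out) <- NULL
  attr(out, "cycles") <- kept_cycles
  out
}
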