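# a design_matrix assembled without a graph, for solver-level tests
mk_dm <- function(X, y) {
  cycles <- lapply(seq_len(ncol(X)), function(i)
    structure(list(fids = which(X[, i] > 0), canon_key = paste0("c", i),
                   weights = 1, is_derived = FALSE,
                   constituents = character(0), total_len = 1e5),
              class = "ec_cycle"))
  frags <- data.frame(fid = seq_len(nrow(X)), chrom = "chr1",
                      start = (seq_len(nrow(X)) - 1) * 1e5,
                      end = seq_len(nrow(X)) * 1e5, mean_cov = y)
  structure(list(X = X, y = y, cycles = cycles, fragments = frags),
            class = "design_matrix")
}

het_design <- function() {
  # elements ABC and BD sharing B, plus the merged ABDBC ring
  g <- fig_shared_footprint_graph()
  cl <- partition_cycles(find_simple_cycles(g))[[1]]
  der <- derive_cycles(cl, g)
  build_design_matrix(c(cl$cycles, der), g$fragments)
}

test_that("occurrence counts tally fragment multiplicity per ring", {
  dm <- het_design()
  keys <- vapply(dm$cycles, function(c) cycle_normal_form(c),
                 character(1))
  abdbc <- ring_normal_form(c(1, 2, 4, 2, 3), rep("+", 5))
  i <- which(keys == abdbc)
  expect_length(i, 1)
  brow <- which(dm$fragments$fid == 2)
  expect_equal(unname(dm$X[brow, i]), 2)  # B twice on the merged ring
  # independent recount from the rings
  for (k in seq_along(dm$cycles))
    expect_equal(dm$X[, k],
                 vapply(dm$fragments$fid, function(f)
                   sum(dm$cycles[[k]]$fids == f), numeric(1)))
  # a single cycle over one fragment gives X = [[1]]
  dm1 <- mk_dm(matrix(1, 1, 1), 40)
  expect_equal(unname(dm1$X), matrix(1, 1, 1))
})

test_that("noiseless shared-footprint coverage recovers both proportions", {
  dm <- het_design()
  fit <- fit_lasso(dm, alpha = 0.1)
  sel <- select_cycles(fit, dm)
  picked <- sel[sel$proportion > 1, ]
  expect_equal(nrow(picked), 2)
  expect_equal(sort(picked$proportion), c(20, 30), tolerance = 0.05)
  expect_equal(fit$beta0, 5, tolerance = 0.2)
  # alpha -> 0 recovers the exact solution
  fit0 <- fit_lasso(dm, alpha = 1e-9)
  sel0 <- select_cycles(fit0, dm)
  expect_equal(sort(sel0$proportion[sel0$proportion > 1]), c(20, 30),
               tolerance = 1e-5)
})

test_that("coordinate descent matches glmnet and non-negative least squares", {
  skip_if_not_installed("glmnet")
  skip_if_not_installed("pracma")
  set.seed(14)
  for (rep in 1:5) {
    n <- 6; p <- 3
    X <- matrix(rpois(n * p, 1), n, p)
    X[cbind(seq_len(p), seq_len(p))] <- X[cbind(seq_len(p),
                                                seq_len(p))] + 1
    b <- runif(p, 10, 50)
    y <- as.vector(X %*% b) + 5
    dm <- mk_dm(X, y)
    alpha <- 0.1
    fit <- fit_lasso(dm, alpha)
    # glmnet objective is (1/2n)RSS + lambda L1: lambda = alpha / 2
    gl <- glmnet::glmnet(X, y, lambda = alpha / 2, lower.limits = 0,
                         standardize = FALSE, intercept = TRUE,
                         thresh = 1e-14)
    expect_equal(fit$beta, as.vector(gl$beta), tolerance = 1e-3)
    expect_equal(fit$beta0, as.numeric(gl$a0), tolerance = 1e-3)
    # with alpha -> 0, the fit approaches NNLS with a free intercept
    fit0 <- fit_lasso(dm, 1e-10)
    nn <- pracma::lsqnonneg(cbind(1, X), y)$x
    expect_equal(fit0$beta, nn[-1], tolerance = 1e-4)
  }
})

test_that("degenerate responses give zero fits and exact objectives", {
  X <- matrix(c(1, 0, 0, 1), 2, 2)
  dm <- mk_dm(X, c(0, 0))
  fit <- fit_lasso(dm, 0.1)
  expect_equal(fit$beta, c(0, 0))
  expect_equal(fit$beta0, 0)
  # one cycle, uniform coverage: the explained level is split with the
  # intercept but their sum reproduces the coverage
  dm2 <- mk_dm(matrix(1, 3, 1), rep(40, 3))
  fit2 <- fit_lasso(dm2, 0.1)
  expect_equal(fit2$beta + fit2$beta0, 40, tolerance = 1e-6)
  expect_equal(fit2$objective,
               mean((rep(40, 3) - fit2$beta0 - fit2$beta)^2) +
                 0.1 * abs(fit2$beta), tolerance = 1e-8)
})

test_that("reported objective matches independent recomputation", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:8, 1); p <- sample(2:4, 1)
    X <- matrix(rpois(n * p, 1), n, p)
    X[, 1] <- X[, 1] + 1
    y <- as.vector(X %*% runif(p, 5, 40)) + rnorm(n, 0, 2) + 5
    dm <- mk_dm(X, pmax(y, 0))
    fit <- fit_lasso(dm, 0.1)
    expect_equal(fit$objective,
                 lasso_objective(dm$X, dm$y, fit$beta, fit$beta0, 0.1),
                 tolerance = 1e-8)
  }
})

test_that("selection threshold is a quarter of the best cycle's weakest fragment", {
  X <- matrix(c(1, 1, 0, 0, 0, 1), 3, 2)   # cycle1 over f1,f2; cycle2 f3
  dm <- mk_dm(X, c(35, 55, 25))
  fit <- structure(list(beta = c(30, 20), beta0 = 5, alpha = 0.1,
                        objective = 0), class = "lasso_fit")
  sel <- select_cycles(fit, dm)
  expect_equal(unique(sel$threshold), 35 / 4)
  expect_true(all(sel$selected))
  expect_equal(sel$proportion, c(30, 20))   # sorted descending
  # a coefficient exactly at the threshold is excluded (strict >)
  fit2 <- structure(list(beta = c(35 / 4, 20), beta0 = 5, alpha = 0.1,
                         objective = 0), class = "lasso_fit")
  sel2 <- select_cycles(fit2, dm)
  expect_false(sel2$selected[sel2$canon_key == "c1"])
  # all-zero coefficients select nothing
  fit3 <- structure(list(beta = c(0, 0), beta0 = 5, alpha = 0.1,
                         objective = 0), class = "lasso_fit")
  expect_false(any(select_cycles(fit3, dm)$selected))
})

test_that("candidate filters drop weak cycles and label ecDNA by size", {
  X <- diag(3)
  dm <- mk_dm(X, c(171, 7, 30))
  dm$cycles[[1]]$total_len <- 150000
  dm$cycles[[2]]$total_len <- 150000
  dm$cycles[[3]]$total_len <- 90000
  sel <- data.frame(canon_key = c("c1", "c2", "c3"),
                    proportion = c(171, 7, 30), min_cov = c(171, 7, 30),
                    threshold = 1, selected = TRUE,
                    stringsAsFactors = FALSE)
  attr(sel, "cycles") <- dm$cycles
  out <- filter_candidates(sel, wgs_mean = 8)
  # proportion 7 <= 8 is gone; 171 on >0.1 Mb is ecDNA; short one stays
  # in the output labeled circular
  expect_false("c2" %in% out$canon_key)
  expect_equal(out$label[out$canon_key == "c1"], "ecDNA")
  expect_equal(out$label[out$canon_key == "c3"], "circular")
})

test_that("increasing the penalty never selects more cycles", {
  dm <- het_design()
  n_sel <- vapply(c(0.01, 0.1, 1, 5, 20), function(a) {
    fit <- fit_lasso(dm, a)
    sum(select_cycles(fit, dm)$selected)
  }, numeric(1))
  expect_true(all(diff(n_sel) <= 0))
})

test_that("scaling coverage by k scales the fit by k", {
  # with the cost mean((y - b0 - Xb)^2) + alpha * sum(b), substituting
  # b' = k b shows the penalty must scale linearly in k for equivalence
  dm <- het_design()
  k <- 3
  dm2 <- dm
  dm2$y <- dm$y * k
  dm2$fragments$mean_cov <- dm$fragments$mean_cov * k
  f1 <- fit_lasso(dm, 0.1)
  f2 <- fit_lasso(dm2, 0.1 * k)
  expect_equal(f2$beta, k * f1$beta, tolerance = 1e-4)
  expect_equal(f2$beta0, k * f1$beta0, tolerance = 1e-4)
})

test_that("proportions are recovered under Gaussian coverage noise", {
  # clusters drawn as overlapping interval rings along a fragment chain
  # (the structure real cycle columns have), identifiable by design
  set.seed(77)
  ok <- 0
  trials <- 200
  for (rep in seq_len(trials)) {
    repeat {
      nf <- sample(4:8, 1)
      p <- sample(2:min(5, nf - 1), 1)
      cols <- unique(replicate(p, {
        a <- sample(nf, 1); b <- sample(a:nf, 1)
        replace(numeric(nf), a:b, 1)
      }, simplify = FALSE))
      X <- do.call(cbind, cols)
      if (qr(X)$rank < ncol(X)) next
      # require a well-posed cluster: coefficient variance bounded
      v <- diag(solve(crossprod(X)))
      if (max(v) <= 0.25) break
    }
    b <- runif(ncol(X), 10, 60)
    y <- pmax(0, 5 + as.vector(X %*% b) + rnorm(nf, 0, 2))
    fit <- fit_lasso(mk_dm(X, y), 0.1, beta0 = 5)
    ok <- ok + all(abs(fit$beta - b) <= pmax(0.1 * b, 2))
  }
  expect_gte(ok / trials, 0.95)
})
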