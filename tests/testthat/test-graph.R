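mk_recs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id %||% "x", chrom1 = r$c1 %||% "chr1",
               pos1 = r$p1, chrom2 = r$c2 %||% "chr1", pos2 = r$p2,
               svtype = r$t, filter = "PASS", support = r$s %||% 40,
               ref_cov = 5, vaf = 0.9, strands = r$strands %||% NA,
               sv_len = NA, stringsAsFactors = FALSE)))
}

test_that("a single-fragment duplication yields parallel edges", {
  fr <- frag_table(1, cov = 45)
  svs <- mk_recs(list(p1 = 0, p2 = 1e5, t = "DUP"))
  g <- build_graph(fr, svs, flat_profile(45))
  e <- g$edges
  expect_equal(sum(e$kind == "fragment"), 1)
  expect_equal(sum(e$kind == "sv"), 1)
  sv <- e[e$kind == "sv", ]
  # the SV edge parallels the fragment edge between tail and head
  expect_setequal(c(sv$u_side, sv$v_side), c("tail", "head"))
  expect_equal(sv$u_fid, sv$v_fid)
})

test_that("DEL joins head of the left fragment to tail of the right", {
  fr <- frag_table(3, cov = 45)   # A [0,1e5) B [1e5,2e5) C [2e5,3e5)
  svs <- mk_recs(list(p1 = 1e5, p2 = 2e5, t = "DEL"))
  g <- build_graph(fr, svs, flat_profile(45, 3e5))
  sv <- g$edges[g$edges$kind == "sv", ]
  expect_equal(nrow(sv), 1)
  expect_equal(sv$u_fid, 1); expect_equal(sv$u_side, "head")
  expect_equal(sv$v_fid, 3); expect_equal(sv$v_side, "tail")
})

test_that("INV adds head-head and tail-tail edges", {
  fr <- frag_table(3, cov = 45)
  svs <- mk_recs(list(p1 = 1e5, p2 = 2e5, t = "INV"))
  g <- build_graph(fr, svs, flat_profile(45, 3e5))
  sv <- g$edges[g$edges$kind == "sv", ]
  expect_equal(nrow(sv), 2)
  expect_setequal(paste(sv$u_side, sv$v_side),
                  c("head head", "tail tail"))
  hh <- sv[sv$u_side == "head", ]
  expect_setequal(c(hh$u_fid, hh$v_fid), c(1, 2))
  tt <- sv[sv$u_side == "tail", ]
  expect_setequal(c(tt$u_fid, tt$v_fid), c(2, 3))
})

test_that("a breakend off every fragment boundary is an error", {
  fr <- frag_table(2, cov = 45)
  svs <- mk_recs(list(p1 = 12345, p2 = 2e5, t = "DEL"))
  expect_error(build_graph(fr, svs, flat_profile(45, 2e5)),
               "fragment boundary")
})

test_that("INS records do not enter the graph", {
  fr <- frag_table(2, cov = 45)
  svs <- mk_recs(list(p1 = 1e5, p2 = 1e5, t = "INS"))
  g <- build_graph(fr, svs, flat_profile(45, 2e5))
  expect_equal(sum(g$edges$kind == "sv"), 0)
})

test_that("pruning removes low-coverage and standalone fragments to a fixpoint", {
  # fragment 2 at exactly the 5x default threshold is removed (strict <=)
  fr <- frag_table(3, cov = c(45, 5, 45))
  svs <- mk_recs(list(p1 = 0, p2 = 3e5, t = "DUP"))
  g <- build_graph(fr, svs, flat_profile(45, 3e5))
  pg <- prune_graph(g)
  expect_setequal(pg$fragments$fid, c(1, 3))
  # fragments bridged by the pruned one become spatial neighbors
  sp <- pg$edges[pg$edges$kind == "spatial", ]
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$u_fid, sp$v_fid), c(1, 3))
  # an isolated fragment on its own chromosome is standalone
  fr2 <- rbind(frag_table(2, cov = 45),
               data.frame(fid = 3, chrom = "chr2", start = 0, end = 1e5,
                          mean_cov = 45, cov_start = 45, cov_end = 45))
  g2 <- build_graph(fr2, mk_recs(list(p1 = 0, p2 = 2e5, t = "DUP")),
                    flat_profile(45, 2e5, c("chr1", "chr2")))
  pg2 <- prune_graph(g2)
  expect_false(3 %in% pg2$fragments$fid)
  # pruning an already-pruned graph changes nothing
  pg3 <- prune_graph(pg2)
  expect_equal(pg3$fragments, pg2$fragments)
  expect_equal(nrow(pg3$edges), nrow(pg2$edges))
})

test_that("spanning-read approximation takes the minimum flank coverage", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 101), c(100, 200)),
                               score = c(10, 30))
  p <- coverage_profile(gr)
  left <- data.frame(chrom = "chr1", start = 0, end = 100)
  right <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(spatial_weight(left, right, p), 10)
  expect_equal(spatial_weight(left, right, flat_profile(40)), 40)
  zero <- coverage_profile(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 100), score = 10))
  expect_equal(spatial_weight(left, right, zero), 0)
  expect_error(spatial_weight(left, data.frame(chrom = "chr2", start = 100,
                                               end = 200), p),
               "chromosome")
})

test_that("vertex bookkeeping: two vertices and one fragment edge per fragment", {
  g <- fig_shared_footprint_graph()
  expect_equal(sum(g$edges$kind == "fragment"), nrow(g$fragments))
  pg <- prune_graph(g)
  expect_equal(sum(pg$edges$kind == "fragment"), nrow(pg$fragments))
  # without SV edges the rest is a per-chromosome path of spatial links
  sp <- g$edges[g$edges$kind == "spatial", ]
  expect_true(all(sp$u_side == "head" & sp$v_side == "tail"))
  expect_equal(sp$v_fid, sp$u_fid + 1L)
})

test_that("graph serialization round-trips vertices, edges and weights", {
  g <- fig_shared_footprint_graph()
  path <- tempfile(fileext = ".tsv")
  write_graph(g, path)
  g2 <- read_graph(path)
  expect_equal(g2$fragments[, c("fid", "chrom", "start", "end",
                                "mean_cov")],
               g$fragments[, c("fid", "chrom", "start", "end",
                               "mean_cov")])
  cols <- c("edge_id", "kind", "u_fid", "u_side", "v_fid", "v_side",
            "weight", "svtype")
  expect_equal(g2$edges[, cols], g$edges[, cols])
})
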