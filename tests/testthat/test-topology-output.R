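ring_df <- function(chrom, start, end, orient) {
  data.frame(chrom = chrom, start = start, end = end, orient = orient,
             stringsAsFactors = FALSE)
}

test_that("topology predicates rank from foldbacks down to simple circles", {
  # single fragment, single circularizing junction
  expect_equal(classify_topology(
    ring_df("chr1", 0, 2e5, "+"))$name, "SimpleCircularization")
  # series of deletions only
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 1100, 2500), c(1000, 2000, 4000),
            c("+", "+", "+")))$name, "SimpleSVs")
  # inversion only
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 1000, 2000), c(1000, 2000, 3000),
            c("+", "-", "+")))$name, "SimpleSVs")
  # deletion + inversion (the inverted segment away from the gap)
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 1100, 2000, 2500), c(1000, 2000, 2500, 3000),
            c("+", "+", "-", "+")))$name, "MixedSVs")
  # two blocks past the region gap
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 50000), c(1000, 51000), c("+", "+")))$name,
    "Multiregion")
  # two chromosomes outrank multiregion
  expect_equal(classify_topology(
    ring_df(c("chr1", "chr2"), c(0, 0), c(1000, 1000),
            c("+", "+")))$name, "Multichromosomal")
  # interspersed duplication: B twice, same orientation, |B| > 50 bp
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 1000, 3000, 1000, 2000),
            c(1000, 2000, 4000, 2000, 3000), rep("+", 5)))$name,
    "Duplications")
  # consecutive overlapping fragments with opposite orientation
  expect_equal(classify_topology(
    ring_df("chr1", c(0, 1500), c(2000, 2000), c("+", "-")))$name,
    "Foldbacks")
})

test_that("every ring evaluates cleanly under all lower-rank predicates", {
  rings <- list(
    ring_df("chr1", 0, 2e5, "+"),
    ring_df("chr1", c(0, 1500), c(2000, 2000), c("+", "-")),
    ring_df(c("chr1", "chr2"), c(0, 0), c(1000, 1000), c("+", "+")))
  for (r in rings) {
    res <- classify_topology(r)
    expect_true(res$name %in% TOPOLOGIES)
    expect_equal(res$rank, match(res$name, TOPOLOGIES))
  }
})

test_that("explicit junction types drive the deletion/inversion predicates", {
  r <- ring_df("chr1", c(0, 1000), c(1000, 2000), c("+", "+"))
  expect_equal(classify_topology(r, junction_types = c("DEL", NA))$name,
               "SimpleSVs")
  expect_equal(classify_topology(r, junction_types = c("DEL", "INV"))$name,
               "MixedSVs")
  expect_equal(classify_topology(r, junction_types = c(NA, NA))$name,
               "SimpleCircularization")
})

test_that("thread BED output round-trips reconstructions losslessly", {
  r1 <- reconstruction(1, data.frame(
    chrom = "chr1", start = c(0, 100000), end = c(100000, 250000),
    orient = c("+", "-"), mean_cov = c(45.5, 30.25),
    fragment_id = c(1L, 2L)), 40.5, "SimpleSVs", "ecDNA")
  r2 <- reconstruction(2, data.frame(
    chrom = "chr2", start = 0, end = 90000, orient = "+",
    mean_cov = 20, fragment_id = 3L), 12, "SimpleCircularization",
    "circular")
  path <- tempfile(fileext = ".bed")
  write_bed(list(r1, r2), path)
  lines <- readLines(path)
  expect_match(lines[1], "^#chrom\t")
  expect_length(lines, 4)   # header + 2 + 1 fragment rows
  back <- read_bed(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$ring$start, r1$ring$start)
  expect_equal(back[[1]]$ring$orient, r1$ring$orient)
  expect_equal(back[[1]]$proportion, r1$proportion)
  expect_equal(back[[2]]$topology, r2$topology)
  expect_equal(back[[2]]$label, "circular")
  # empty set: header-only file
  empty <- tempfile(fileext = ".bed")
  write_bed(list(), empty)
  expect_length(readLines(empty), 1)
  expect_length(read_bed(empty), 0)
})

test_that("summary rows agree with the BED threads", {
  recs <- list(
    reconstruction(1, data.frame(chrom = "chr1", start = c(0, 1000),
                                 end = c(1000, 3000),
                                 orient = c("+", "+"),
                                 mean_cov = 40, fragment_id = 1:2),
                   33, "SimpleSVs", "circular"))
  sp <- tempfile(); bp <- tempfile()
  write_summary(recs, sp)
  write_bed(recs, bp)
  s <- read.delim(sp)
  expect_equal(nrow(s), 1)
  expect_equal(s$n_fragments, 2)
  b <- read_bed(bp)[[1]]
  expect_equal(s$total_len, sum(b$ring$end - b$ring$start))
  # empty set: header only
  write_summary(list(), sp)
  expect_length(readLines(sp), 1)
})

test_that("FASTA sequences concatenate oriented fragments", {
  ref <- toy_genome(c(chrA = 5000), seed = 4)
  fwd <- reconstruction(1, data.frame(chrom = "chrA", start = 100,
                                      end = 200, orient = "+",
                                      mean_cov = 1, fragment_id = 1L),
                        1, "SimpleCircularization", "circular")
  rev <- reconstruction(2, data.frame(chrom = "chrA", start = 100,
                                      end = 200, orient = "-",
                                      mean_cov = 1, fragment_id = 1L),
                        1, "SimpleCircularization", "circular")
  ring <- reconstruction(3, data.frame(
    chrom = "chrA", start = c(0, 1000, 3000, 1000, 2000),
    end = c(1000, 2000, 4000, 2000, 3000), orient = rep("+", 5),
    mean_cov = 1, fragment_id = 1:5), 1, "Duplications", "ecDNA")
  path <- tempfile(fileext = ".fa")
  write_fasta(list(fwd, rev, ring), ref, path)
  out <- Biostrings::readDNAStringSet(path)
  sub <- Biostrings::subseq(ref[["chrA"]], 101, 200)
  expect_equal(as.character(out[[1]]), as.character(sub))
  expect_equal(as.character(out[[2]]),
               as.character(Biostrings::reverseComplement(sub)))
  # ring ABDBC: length counts the duplicated fragment twice
  expect_equal(length(out[[3]]), 5000)
  expect_equal(length(out[[3]]), ring$total_len)
  # fragment outside the reference errors with the fragment named
  bad <- reconstruction(4, data.frame(chrom = "chrA", start = 4900,
                                      end = 5100, orient = "+",
                                      mean_cov = 1, fragment_id = 1L),
                        1, "SimpleCircularization", "circular")
  expect_error(write_fasta(list(bad), ref, tempfile()), "outside")
})
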