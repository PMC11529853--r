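test_that("a circularizing duplication on one fragment is the smallest cycle", {
  fr <- frag_table(1, cov = 45)
  g <- make_graph(fr, nfe(1, "tail", 1, "head", 40, svtype = "DUP"))
  cyc <- find_simple_cycles(g)
  expect_length(cyc, 1)
  expect_equal(cyc[[1]]$fids, 1L)
  expect_equal(cyc[[1]]$orients, "+")
  expect_equal(cyc[[1]]$total_len, 1e5)
})

test_that("shared-footprint fixture yields both co-occurring cycles", {
  g <- fig_shared_footprint_graph()
  cyc <- find_simple_cycles(g)
  keys <- vapply(cyc, cycle_normal_form, character(1))
  abc <- ring_normal_form(c(1, 2, 3), c("+", "+", "+"))
  bd <- ring_normal_form(c(2, 4), c("+", "+"))
  expect_true(abc %in% keys)
  expect_true(bd %in% keys)
})

test_that("enumeration equals brute force on random small graphs", {
  for (seed in 1:40) {
    g <- random_graph(seed)
    got <- sort(vapply(find_simple_cycles(g), cycle_normal_form,
                       character(1)))
    expect_equal(got, oracle_simple_cycles(g), info = paste("seed", seed))
  }
})

test_that("enumeration is deterministic and monotone under edge addition", {
  g <- random_graph(101)
  k1 <- vapply(find_simple_cycles(g), function(c) c$canon_key,
               character(1))
  k2 <- vapply(find_simple_cycles(g), function(c) c$canon_key,
               character(1))
  expect_identical(k1, k2)
  # adding an SV edge never removes a found cycle
  extra <- nfe(1, "tail", 2, "head", 33, svtype = "DUP")
  frags <- g$fragments
  nf <- g$edges[g$edges$kind != "fragment",
                c("kind", "u_fid", "u_side", "v_fid", "v_side", "weight",
                  "svtype")]
  g2 <- make_graph(frags, rbind(nf, extra))
  k3 <- vapply(find_simple_cycles(g2), cycle_normal_form, character(1))
  expect_true(all(vapply(find_simple_cycles(g), cycle_normal_form,
                         character(1)) %in% k3))
})

test_that("canonical keys are invariant under rotation and reversal", {
  g <- fig_shared_footprint_graph()
  cyc <- find_simple_cycles(g)
  abc <- cyc[[which(vapply(cyc, function(c) length(c$fids), integer(1))
                    == 3)[1]]]
  rot <- ecdecon:::.rotate_cycle(abc$fids, abc$orients, abc$eids, 2)
  c_rot <- ecdecon:::.new_cycle(rot$fids, rot$orients, rot$eids, g)
  expect_equal(canonicalize(c_rot, g)$canon_key, abc$canon_key)
  rev <- ecdecon:::.reverse_cycle(abc$fids, abc$orients, abc$eids)
  c_rev <- ecdecon:::.new_cycle(rev$fids, rev$orients, rev$eids, g)
  expect_equal(canonicalize(c_rev, g)$canon_key, abc$canon_key)
  # canonicalization is idempotent
  expect_equal(canonicalize(abc, g)$canon_key, abc$canon_key)
  # rotation and reversal preserve walk legality
  expect_true(validate_cycle(c_rot, g))
  expect_true(validate_cycle(c_rev, g))
})

test_that("genuinely different rings over the same fragments get distinct keys", {
  # ring ABC vs ACB: all rotations/reflections enumerated exhaustively
  ks <- ring_normal_form(c(1, 2, 3), c("+", "+", "+"))
  ks2 <- ring_normal_form(c(1, 3, 2), c("+", "+", "+"))
  expect_false(ks == ks2)
  # all-'+' rings on 4 fragments: reversal flips every orientation, so
  # the 3! = 6 orders stay 6 distinct classes; with the reversed
  # orientations supplied explicitly each ring meets its mirror
  perms <- .perms(2:4)
  keys <- vapply(perms, function(p) ring_normal_form(c(1, p),
                                                     rep("+", 4)),
                 character(1))
  expect_equal(length(unique(keys)), 6)
  expect_equal(ring_normal_form(c(1, 4, 3, 2), rep("-", 4)),
               ring_normal_form(c(1, 2, 3, 4), rep("+", 4)))
})

test_that("cycle clusters equal union-find components", {
  g <- fig_shared_footprint_graph()
  cyc <- find_simple_cycles(g)
  cl <- partition_cycles(cyc)
  # ABC and BD share fragment B: a single cluster
  expect_length(cl, 1)
  expect_setequal(cl[[1]]$fragment_ids, 1:4)
  set.seed(21)
  for (rep in 1:10) {
    fake <- lapply(1:8, function(i) {
      f <- sort(sample(1:10, sample(1:3, 1)))
      structure(list(fids = f, canon_key = paste(i)), class = "ec_cycle")
    })
    got <- partition_cycles(fake)
    want <- oracle_partition(fake)
    got_sets <- lapply(got, function(cl)
      sort(match(vapply(cl$cycles, function(c) c$canon_key, character(1)),
                 vapply(fake, function(c) c$canon_key, character(1)))))
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
  }
})

test_that("cycles on disjoint chromosomes form separate clusters", {
  fr <- rbind(frag_table(1, cov = 45),
              data.frame(fid = 2, chrom = "chr2", start = 0, end = 1e5,
                         mean_cov = 45, cov_start = 45, cov_end = 45))
  g <- make_graph(fr, rbind(nfe(1, "tail", 1, "head", 40, svtype = "DUP"),
                            nfe(2, "tail", 2, "head", 40,
                                svtype = "DUP")))
  cl <- partition_cycles(find_simple_cycles(g))
  expect_length(cl, 2)
})

test_that("splicing shared-fragment cycles yields the interspersed duplication ring", {
  g <- fig_shared_footprint_graph()
  cl <- partition_cycles(find_simple_cycles(g))[[1]]
  der <- derive_cycles(cl, g)
  keys <- vapply(der, cycle_normal_form, character(1))
  abdbc <- ring_normal_form(c(1, 2, 4, 2, 3), c("+", "+", "+", "+", "+"))
  expect_true(abdbc %in% keys)
  # every derived cycle is a legal alternating walk and not a simple one
  for (d in der) {
    expect_true(validate_cycle(d, g))
    expect_true(d$is_derived)
  }
  simple_keys <- vapply(cl$cycles, function(c) c$canon_key, character(1))
  expect_false(any(vapply(der, function(d) d$canon_key, character(1))
                   %in% simple_keys))
})

test_that("a cluster with one simple cycle derives nothing", {
  fr <- frag_table(1, cov = 45)
  g <- make_graph(fr, nfe(1, "tail", 1, "head", 40, svtype = "DUP"))
  cl <- partition_cycles(find_simple_cycles(g))[[1]]
  expect_length(derive_cycles(cl, g), 0)
})

test_that("near-duplicate cycles are not merged (dissimilarity rule)", {
  j <- ecdecon:::.multiset_jaccard
  expect_equal(j(c(1, 2, 3), c(2, 4)), 0.25)
  expect_equal(j(c(1, 2, 3), c(1, 2, 3)), 1)
  # two cycles over identical fragment multisets are too similar to merge
  g <- fig_shared_footprint_graph()
  cl <- partition_cycles(find_simple_cycles(g))[[1]]
  der0 <- derive_cycles(cl, g, dissim_threshold = 0)
  expect_length(der0, 0)
})
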