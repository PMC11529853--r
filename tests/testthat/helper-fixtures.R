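# Shared fixtures and independent oracles.

# --- fixture builders -------------------------------------------------------

# a bare graph from explicit fragment and non-fragment edge tables
make_graph <- function(frags, edges) {
  frags$mean_cov <- frags$mean_cov %||% 40
  frags$cov_start <- frags$cov_start %||% frags$mean_cov
  frags$cov_end <- frags$cov_end %||% frags$mean_cov
  frag_edges <- data.frame(
    edge_id = NA_integer_, kind = "fragment",
    u_fid = frags$fid, u_side = "tail", v_fid = frags$fid,
    v_side = "head", weight = frags$mean_cov, svtype = NA_character_,
    sv_len = NA_real_, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    edges$edge_id <- NA_integer_
    edges$svtype <- edges$svtype %||% NA_character_
    edges$sv_len <- NA_real_
    edges <- edges[, names(frag_edges)]
  }
  ecdecon:::.new_graph(frags, rbind(frag_edges, edges), Inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frag_table <- function(n, chrom = "chr1", width = 1e5, cov = 40) {
  data.frame(fid = seq_len(n), chrom = chrom,
             start = (seq_len(n) - 1) * width, end = seq_len(n) * width,
             mean_cov = cov, cov_start = cov, cov_end = cov,
             stringsAsFactors = FALSE)
}

nfe <- function(u_fid, u_side, v_fid, v_side, weight = 10,
                kind = "sv", svtype = NA_character_) {
  data.frame(kind = kind, u_fid = u_fid, u_side = u_side, v_fid = v_fid,
             v_side = v_side, weight = weight, svtype = svtype,
             stringsAsFactors = FALSE)
}

# the two-element heterogeneity fixture: elements ABC and BD share B
fig_shared_footprint_graph <- function() {
  fr <- frag_table(4, cov = c(35, 55, 35, 25))
  edges <- rbind(
    nfe(1, "tail", 3, "head", 30, svtype = "DUP"),   # wrap of ABC
    nfe(2, "head", 4, "tail", 20, svtype = "DEL"),   # B -> D jump
    nfe(2, "tail", 4, "head", 20, svtype = "DUP"),   # wrap of BD
    nfe(1, "head", 2, "tail", 15, kind = "spatial"),
    nfe(2, "head", 3, "tail", 15, kind = "spatial"),
    nfe(3, "head", 4, "tail", 15, kind = "spatial"))
  make_graph(fr, edges)
}

# uniform coverage profile over given chromosomes
flat_profile <- function(value, len = 1e6, chroms = "chr1") {
  gr <- GenomicRanges::GRanges(chroms, IRanges::IRanges(1, len),
                               score = value)
  coverage_profile(gr)
}

write_mini_vcf <- function(path, rows,
                           header_extra = character(0)) {
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"t\">",
               "##FORMAT=<ID=DR,Number=1,Type=Integer,Description=\"t\">",
               "##FORMAT=<ID=DV,Number=1,Type=Integer,Description=\"t\">",
               header_extra,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", "S1"), collapse = "\t"),
               rows), path)
  path
}

# --- independent oracles ----------------------------------------------------

# normal form of an oriented ring, invariant under rotation and reversal:
# minimum over all rotations of both directions (independent of the
# package's leftmost-fragment canonical form, usable to compare sets)
ring_normal_form <- function(fids, orients) {
  enc <- function(f, o) paste(sprintf("%08d%s", f,
                                      ifelse(o == "+", "f", "r")),
                              collapse = "|")
  n <- length(fids)
  cands <- character(0)
  for (k in seq_len(n)) {
    idx <- ((seq_len(n) + k - 2) %% n) + 1
    cands <- c(cands, enc(fids[idx], orients[idx]))
  }
  rf <- rev(fids); ro <- rev(ifelse(orients == "+", "-", "+"))
  for (k in seq_len(n)) {
    idx <- ((seq_len(n) + k - 2) %% n) + 1
    cands <- c(cands, enc(rf[idx], ro[idx]))
  }
  min(cands)
}

cycle_normal_form <- function(cycle) ring_normal_form(cycle$fids,
                                                      cycle$orients)

.perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (p in .perms(x[-i])) out[[length(out) + 1]] <- c(x[i], p)
  out
}

# brute-force enumeration of all simple alternating closed walks: every
# subset, every cyclic order, every orientation assignment, junction
# edges checked for existence
oracle_simple_cycles <- function(g) {
  fids <- g$fragments$fid
  edges <- g$edges[g$edges$kind != "fragment", , drop = FALSE]
  has_edge <- function(f1, s1, f2, s2) {
    any((edges$u_fid == f1 & edges$u_side == s1 &
           edges$v_fid == f2 & edges$v_side == s2) |
          (edges$v_fid == f1 & edges$v_side == s1 &
             edges$u_fid == f2 & edges$u_side == s2))
  }
  exit_side <- function(o) if (o == "+") "head" else "tail"
  entry_side <- function(o) if (o == "+") "tail" else "head"
  keys <- character(0)
  for (k in seq_along(fids)) {
    for (sub in utils::combn(fids, k, simplify = FALSE)) {
      for (p in .perms(sub[-1])) {
        ring <- c(sub[1], p)
        m <- length(ring)
        for (bits in 0:(2^m - 1)) {
          orients <- ifelse(bitwAnd(bits, 2^(seq_len(m) - 1)) > 0,
                            "-", "+")
          ok <- TRUE
          for (i in seq_len(m)) {
            prev <- if (i == 1) m else i - 1
            if (!has_edge(ring[prev], exit_side(orients[prev]),
                          ring[i], entry_side(orients[i]))) {
              ok <- FALSE
              break
            }
          }
          if (ok) keys <- c(keys, ring_normal_form(ring, orients))
        }
      }
    }
  }
  sort(unique(keys))
}

# random graphs with <= max_frags fragments for oracle comparisons
random_graph <- function(seed, max_frags = 6) {
  set.seed(seed)
  n <- sample(2:max_frags, 1)
  fr <- frag_table(n, cov = round(stats::runif(n, 10, 80)))
  sides <- c("tail", "head")
  m <- sample(1:(n + 2), 1)
  ed <- do.call(rbind, lapply(seq_len(m), function(i) {
    u <- sample(n, 1); v <- sample(n, 1)
    nfe(u, sample(sides, 1), v, sample(sides, 1),
        weight = round(stats::runif(1, 5, 60)))
  }))
  sp <- do.call(rbind, lapply(seq_len(n - 1), function(i)
    nfe(i, "head", i + 1, "tail", round(stats::runif(1, 1, 40)),
        kind = "spatial")))
  make_graph(fr, rbind(ed, sp))
}

# union-find over cycles sharing fragments
oracle_partition <- function(cycles) {
  n <- length(cycles)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j &&
        length(intersect(cycles[[i]]$fids, cycles[[j]]$fids)) > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), comp))
}

# exhaustive maximum one-to-one matching between junction sets
oracle_max_matching <- function(tj, rj, tol) {
  nt <- NROW(tj); nr <- NROW(rj)
  compat <- matrix(FALSE, nt, nr)
  for (i in seq_len(nt)) for (j in seq_len(nr))
    compat[i, j] <- is.finite(ecdecon:::.junction_offset(tj[i, ],
                                                         rj[j, ], tol))
  best <- 0
  recurse <- function(i, used) {
    if (i > nt) { best <<- max(best, sum(used)); return(invisible()) }
    recurse(i + 1, used)                       # leave i unmatched
    for (j in which(compat[i, ])) if (!used[j]) {
      used[j] <- TRUE
      recurse(i + 1, used)
      used[j] <- FALSE
    }
  }
  recurse(1, logical(nr))
  best
}
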