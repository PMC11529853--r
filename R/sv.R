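#' Parse structural-variant calls from a Sniffles-style VCF
#'
#' Reads one SV record per VCF line and normalizes the two breakends.
#' Intra-chromosomal records are ordered so that `pos1 <= pos2`. The mate
#' coordinate comes from `INFO/CHR2` + `INFO/END`; for BND records lacking
#' them it is parsed from the bracketed ALT allele. Variant-supporting read
#' counts are taken from `INFO/DV`, `INFO/RE` or `INFO/SUPPORT`, or the
#' first sample's `FORMAT/DV`; reference reads from `INFO/DR` or
#' `FORMAT/DR`. The variant allele fraction is `support / (support +
#' ref_cov)` when both counts are present, else `INFO/AF`, else `NA`.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return data.frame of class `sv_records` with columns `id`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `svtype`, `filter`, `support`, `ref_cov`,
#'   `vaf`, `strands`, `sv_len`. Positions are 1-based as in the VCF.
#' @export
parse_sv_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- v@fix
  empty <- data.frame(id = character(0), chrom1 = character(0),
                      pos1 = integer(0), chrom2 = character(0),
                      pos2 = integer(0), svtype = character(0),
                      filter = character(0), support = numeric(0),
                      ref_cov = numeric(0), vaf = numeric(0),
                      strands = character(0), sv_len = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("sv_records", "data.frame")
  if (is.null(fix) || nrow(fix) == 0) return(empty)

  info <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else as.character(x)
  }
  fmt <- function(key) {
    if (ncol(v@gt) < 2) return(rep(NA_character_, nrow(fix)))
    x <- tryCatch(vcfR::extract.gt(v, element = key),
                  error = function(e) NULL)
    if (is.null(x)) rep(NA_character_, nrow(fix)) else as.character(x[, 1])
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  svtype <- info("SVTYPE")
  chr2 <- info("CHR2")
  end <- num(info("END"))
  sv_len <- num(info("SVLEN"))
  strands <- info("STRANDS")
  af <- num(info("AF"))
  support <- num(info("DV"))
  support[is.na(support)] <- num(info("RE"))[is.na(support)]
  support[is.na(support)] <- num(info("SUPPORT"))[is.na(support)]
  fdv <- num(fmt("DV"))
  support[is.na(support)] <- fdv[is.na(support)]
  ref_cov <- num(info("DR"))
  fdr <- num(fmt("DR"))
  ref_cov[is.na(ref_cov)] <- fdr[is.na(ref_cov)]

  alt <- fix[, "ALT"]
  m <- regexpr("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]", alt, perl = TRUE)
  mate_chr <- rep(NA_character_, nrow(fix))
  mate_pos <- rep(NA_real_, nrow(fix))
  idx <- which(m > 0)
  if (length(idx) > 0) {
    inner <- sub("^[][]", "", sub("[][]$", "", regmatches(alt, m)))
    parts <- strsplit(inner, ":", fixed = TRUE)
    mate_chr[idx] <- vapply(parts, `[`, character(1), 1)
    mate_pos[idx] <- as.numeric(vapply(parts, `[`, character(1), 2))
  }
  chrom2 <- ifelse(is.na(chr2), mate_chr, chr2)
  pos2 <- ifelse(is.na(end), mate_pos, end)
  # CHR2 present but END missing: BND mate position from ALT
  pos2[is.na(pos2)] <- mate_pos[is.na(pos2)]

  chrom1 <- fix[, "CHROM"]
  pos1 <- num(fix[, "POS"])
  chrom2[is.na(chrom2)] <- chrom1[is.na(chrom2)]
  bad <- is.na(pos2) | is.na(svtype)
  if (any(bad)) {
    warning(sum(bad), " record(s) lacking SVTYPE or both END and mate ALT",
            " were skipped (lines: ",
            paste(which(bad), collapse = ", "), ")")
  }
  vaf <- ifelse(!is.na(support) & !is.na(ref_cov) & (support + ref_cov) > 0,
                support / (support + ref_cov), af)

  rec <- data.frame(
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0("sv", seq_len(nrow(fix))), fix[, "ID"]),
    chrom1 = chrom1, pos1 = as.integer(pos1),
    chrom2 = chrom2, pos2 = as.integer(pos2),
    svtype = svtype,
    filter = ifelse(is.na(fix[, "FILTER"]), ".", fix[, "FILTER"]),
    support = support, ref_cov = ref_cov, vaf = vaf,
    strands = strands, sv_len = sv_len,
    stringsAsFactors = FALSE)
  rec <- rec[!bad, , drop = FALSE]

  # normalize intra-chromosomal breakend order
  swap <- rec$chrom1 == rec$chrom2 & rec$pos1 > rec$pos2
  if (any(swap)) {
    tmp <- rec$pos1[swap]
    rec$pos1[swap] <- rec$pos2[swap]
    rec$pos2[swap] <- tmp
    rec$strands[swap] <- vapply(rec$strands[swap], function(s) {
      if (is.na(s) || nchar(s) != 2) s else
        paste0(substr(s, 2, 2), substr(s, 1, 1))
    }, character(1))
  }
  rownames(rec) <- NULL
  class(rec) <- c("sv_records", "data.frame")
  rec
}

#' Filter structural-variant records
#'
#' Keeps records whose FILTER label is allowed, whose on-target coverage
#' is at least `min_cov` and whose variant allele fraction is at least
#' `min_vaf`. On-target coverage is `support + ref_cov` when both read
#' counts are available, else the coverage profile value at the first
#' breakend; records where neither source is available are dropped.
#' Input order is preserved.
#'
#' @param records An `sv_records` data.frame from [parse_sv_vcf()].
#' @param min_cov Minimum on-target coverage (x), default 5.
#' @param min_vaf Minimum variant allele fraction, default 0.01.
#' @param allowed_filters FILTER labels to keep.
#' @param profile Optional [coverage_profile] used when read counts are
#'   absent.
#' @return The retained subset, same class and column layout.
#' @export
filter_svs <- function(records, min_cov = 5, min_vaf = 0.01,
                       allowed_filters = c("PASS", "STRANDBIAS"),
                       profile = NULL) {
  stopifnot(min_cov >= 0, min_vaf >= 0, min_vaf <= 1)
  if (nrow(records) == 0) return(records)
  cov <- ifelse(!is.na(records$support) & !is.na(records$ref_cov),
                records$support + records$ref_cov, NA_real_)
  if (!is.null(profile)) {
    miss <- which(is.na(cov))
    for (i in miss)
      cov[i] <- profile_value(profile, records$chrom1[i], records$pos1[i])
  }
  keep <- records$filter %in% allowed_filters &
    !is.na(cov) & cov >= min_cov &
    !is.na(records$vaf) & records$vaf >= min_vaf
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby breakends into clean breakpoints
#'
#' Both breakends of every record are clustered per chromosome by single
#' linkage: two breakends join the same cluster when their gap is at most
#' `window`. Each cluster is represented by its median position (rounded
#' down). The raw-breakend to clean-breakpoint mapping is attached as the
#' `"map"` attribute for graph construction.
#'
#' @param records An `sv_records` data.frame.
#' @param window Merge window in bp (default 50).
#' @return data.frame with `chrom`, `pos`, `n_merged`, sorted by
#'   `(chrom, pos)`, with attribute `map`: data.frame `chrom`, `raw_pos`,
#'   `clean_pos`.
#' @export
merge_breakpoints <- function(records, window = 50) {
  stopifnot(window >= 0)
  be <- data.frame(chrom = c(records$chrom1, records$chrom2),
                   pos = c(records$pos1, records$pos2),
                   stringsAsFactors = FALSE)
  be <- be[!is.na(be$pos), , drop = FALSE]
  if (nrow(be) == 0) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      n_merged = integer(0), stringsAsFactors = FALSE)
    attr(out, "map") <- data.frame(chrom = character(0),
                                   raw_pos = integer(0),
                                   clean_pos = integer(0))
    return(out)
  }
  res <- list()
  maps <- list()
  for (chrom in sort(unique(be$chrom))) {
    p <- sort(unique(be$pos[be$chrom == chrom]))
    cl <- cumsum(c(1L, as.integer(diff(p) > window)))
    clean <- vapply(split(p, cl),
                    function(x) as.integer(floor(stats::median(x))),
                    integer(1))
    n <- vapply(split(p, cl), length, integer(1))
    res[[chrom]] <- data.frame(chrom = chrom, pos = unname(clean),
                               n_merged = unname(n),
                               stringsAsFactors = FALSE)
    maps[[chrom]] <- data.frame(chrom = chrom, raw_pos = p,
                                clean_pos = unname(clean)[cl],
                                stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  map <- do.call(rbind, maps)
  rownames(map) <- NULL
  attr(out, "map") <- map
  out
}

#' Look up the clean breakpoint for a raw breakend
#'
#' @param map The `map` attribute of [merge_breakpoints()] output.
#' @param chrom,pos Raw breakend coordinate.
#' @return The clean position, or `NA` when unmapped.
#' @keywords internal
clean_pos <- function(map, chrom, pos) {
  i <- which(map$chrom == chrom & map$raw_pos == pos)
  if (length(i) == 0) NA_integer_ else map$clean_pos[i[1]]
}
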