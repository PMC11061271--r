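# Pairwise IBD segment detection from two-sample genotypes: an
# identity-by-state (IBS) sliding-window scan. At each retained site the IBS
# state (0/1/2 shared alleles) is recorded together with w, the fraction of
# IBS = 0 sites within 1 Mb up- and downstream; maximal runs of sites with
# small w that are long enough (variant count and genetic span) are reported
# as IBD segments.

#' Filter variant sites for IBD analysis
#'
#' Keeps biallelic SNVs where both samples have high-quality, non-missing
#' genotype calls: `FILTER == "PASS"`, both depths strictly greater than
#' `min_dp`, both genotype qualities strictly greater than `min_gq`.
#'
#' @param sites A `variant_sites` data frame (see [read_vcf_pair()],
#'   [sim_pair()]): columns `chrom`, `pos`, `ref`, `alt`, `g1`, `g2`
#'   (allele dosages 0/1/2 or NA), `filter`, `dp1`, `dp2`, `gq1`, `gq2`,
#'   `cm`.
#' @param min_dp,min_gq Exclusive lower bounds on per-sample depth and
#'   genotype quality (defaults DP > 10, GQ > 50).
#' @return The subset of passing sites, order preserved.
#' @export
filter_sites <- function(sites, min_dp = 10, min_gq = 50) {
  if (nrow(sites) == 0) return(sites)
  snv <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1 &
    !grepl(",", sites$alt, fixed = TRUE)
  keep <- sites$filter == "PASS" &
    sites$dp1 > min_dp & sites$dp2 > min_dp &
    sites$gq1 > min_gq & sites$gq2 > min_gq &
    !is.na(sites$g1) & !is.na(sites$g2) & snv
  sites[which(keep), , drop = FALSE]
}

#' Identity-by-state of a genotype pair
#'
#' Number of alleles (0, 1 or 2) the two diploid genotypes share by state,
#' i.e. the size of the intersection of their allele multisets; for dosages
#' this is `2 - |g1 - g2|`.
#'
#' @param g1,g2 Allele dosages in `{0, 1, 2}` (vectorized).
#' @return Integer vector of IBS states.
#' @export
ibs_state <- function(g1, g2) {
  if (any(is.na(g1)) || any(is.na(g2)))
    stop("missing dosage; filter sites first")
  if (any(!g1 %in% 0:2) || any(!g2 %in% 0:2))
    stop("dosages must be 0, 1 or 2")
  as.integer(2 - abs(g1 - g2))
}

#' Local discordance statistic w
#'
#' For every site, the fraction of sites on the same chromosome within
#' `radius_bp` (1 Mb by default) up- or downstream — including the site
#' itself by default — whose IBS state is 0. Inside a true IBD segment
#' opposite homozygotes are impossible up to genotyping error, so w stays
#' near zero.
#'
#' @param sites Sites sorted by (chrom, pos).
#' @param radius_bp Window radius in bp.
#' @param include_self Count the site in its own window (default `TRUE`).
#' @return Numeric vector of w values, one per site.
#' @export
neighborhood_w <- function(sites, radius_bp = 1e6, include_self = TRUE) {
  n <- nrow(sites)
  if (n == 0) return(numeric(0))
  ibs0 <- as.numeric(ibs_state(sites$g1, sites$g2) == 0)
  w <- numeric(n)
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    pos <- sites$pos[i]
    if (is.unsorted(pos)) stop("sites must be sorted by (chrom, pos)")
    cs <- cumsum(ibs0[i])
    lo <- findInterval(pos - radius_bp - 0.5, pos) + 1L
    hi <- findInterval(pos + radius_bp + 0.5, pos)
    cs_prev <- numeric(length(lo))
    cs_prev[lo > 1] <- cs[lo[lo > 1] - 1L]
    cnt0 <- cs[hi] - cs_prev
    ntot <- hi - lo + 1L
    if (!include_self) {
      cnt0 <- cnt0 - ibs0[i]
      ntot <- ntot - 1L
    }
    w[i] <- ifelse(ntot > 0, cnt0 / ntot, 0)
  }
  w
}

#' Call pairwise IBD segments
#'
#' Scans each chromosome for maximal runs of consecutive sites whose local
#' discordance `w` (see [neighborhood_w()]) does not exceed `w_threshold`,
#' and reports runs with at least `min_variants` sites spanning at least
#' `min_cm` centimorgans as IBD segments. Sites must already be filtered
#' ([filter_sites()]) and annotated with genetic positions
#' ([interpolate_cm()]; if `cm` is entirely missing a uniform 1 cM/Mb map
#' is assumed, with a message).
#'
#' @param sites Filtered sites sorted by (chrom, pos).
#' @param w_threshold Maximum local IBS = 0 fraction inside a segment
#'   (default 0.005, i.e. 0.5%).
#' @param min_variants Minimum number of sites in a run (default 100).
#' @param min_cm Minimum genetic span in cM (default 1).
#' @param radius_bp Window radius for [neighborhood_w()].
#' @return A data frame of class `ibd_segments`: `chrom`, `start_pos`,
#'   `end_pos` (bp of first/last site), `start_cm`, `end_cm`, `length_cm`,
#'   `n_variants`, `max_w`; zero rows if nothing qualifies. Segments are
#'   non-overlapping and sorted.
#' @export
call_ibd_segments <- function(sites, w_threshold = 0.005, min_variants = 100,
                              min_cm = 1.0, radius_bp = 1e6) {
  if (nrow(sites) == 0) return(.empty_segments())
  if (all(is.na(sites$cm))) {
    message("no genetic positions; assuming uniform 1 cM/Mb")
    sites$cm <- sites$pos / 1e6
  }
  if (any(is.na(sites$cm))) stop("sites have missing cm values")
  w <- neighborhood_w(sites, radius_bp = radius_bp)
  segs <- NULL
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    r <- rle(w[i] <= w_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- i[starts[k]:ends[k]]
      span <- sites$cm[run[length(run)]] - sites$cm[run[1]]
      if (length(run) >= min_variants && span >= min_cm) {
        segs <- rbind(segs, data.frame(
          chrom = ch,
          start_pos = sites$pos[run[1]], end_pos = sites$pos[run[length(run)]],
          start_cm = sites$cm[run[1]], end_cm = sites$cm[run[length(run)]],
          length_cm = span, n_variants = length(run), max_w = max(w[run]),
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(segs)) return(.empty_segments())
  segs <- segs[order(segs$chrom, segs$start_pos), , drop = FALSE]
  rownames(segs) <- NULL
  class(segs) <- c("ibd_segments", "data.frame")
  segs
}

.empty_segments <- function() {
  segs <- data.frame(chrom = character(0), start_pos = numeric(0),
                     end_pos = numeric(0), start_cm = numeric(0),
                     end_cm = numeric(0), length_cm = numeric(0),
                     n_variants = integer(0), max_w = numeric(0),
                     stringsAsFactors = FALSE)
  class(segs) <- c("ibd_segments", "data.frame")
  segs
}

#' @export
print.ibd_segments <- function(x, ...) {
  cat(sprintf("%d IBD segment(s)\n", nrow(x)))
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write IBD segments as a BED-like TSV
#'
#' Physical coordinates are converted to 0-based half-open (BED convention)
#' at the boundary; genetic length, variant count and the maximum window
#' statistic are carried as extra columns.
#'
#' @param segs An `ibd_segments` data frame.
#' @param path Output path.
#' @export
write_segments_bed <- function(segs, path) {
  out <- data.frame(chrom = segs$chrom, start = segs$start_pos - 1,
                    end = segs$end_pos, length_cm = segs$length_cm,
                    n_variants = segs$n_variants, max_w = segs$max_w)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a genetic map
#'
#' Tab-separated with header, columns `chrom`, `pos` (bp), `cm`
#' (cumulative genetic position). Positions must be strictly ascending and
#' cm non-decreasing within each chromosome.
#'
#' @param path File path.
#' @return A data frame of class `genetic_map`.
#' @export
read_genetic_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "cm")
  miss <- setdiff(need, names(map))
  if (length(miss) > 0)
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  genetic_map(map$chrom, map$pos, map$cm)
}

#' @rdname read_genetic_map
#' @param chrom,pos,cm Vectors defining the map points.
#' @export
genetic_map <- function(chrom, pos, cm) {
  map <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                    cm = as.numeric(cm), stringsAsFactors = FALSE)
  for (ch in unique(map$chrom)) {
    g <- map[map$chrom == ch, ]
    if (nrow(g) < 2) stop("map needs >= 2 points for chromosome ", ch)
    if (any(diff(g$pos) <= 0)) stop("map positions not ascending for ", ch)
    if (any(diff(g$cm) < 0)) stop("map cm not non-decreasing for ", ch)
  }
  class(map) <- c("genetic_map", "data.frame")
  map
}

#' Annotate sites with genetic positions
#'
#' Linear interpolation of cumulative genetic position between map points;
#' beyond the map range the boundary segment's recombination rate (cM/bp
#' slope) is extrapolated.
#'
#' @param sites A `variant_sites` data frame.
#' @param map A [genetic_map()].
#' @return `sites` with the `cm` column filled.
#' @export
interpolate_cm <- function(sites, map) {
  if (nrow(sites) == 0) return(sites)
  for (ch in unique(sites$chrom)) {
    g <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) stop("chromosome ", ch, " absent from genetic map")
    i <- which(sites$chrom == ch)
    p <- sites$pos[i]
    cm <- stats::approx(g$pos, g$cm, xout = p, rule = 2)$y
    m <- nrow(g)
    s_lo <- (g$cm[2] - g$cm[1]) / (g$pos[2] - g$pos[1])
    s_hi <- (g$cm[m] - g$cm[m - 1]) / (g$pos[m] - g$pos[m - 1])
    below <- p < g$pos[1]; above <- p > g$pos[m]
    cm[below] <- g$cm[1] - (g$pos[1] - p[below]) * s_lo
    cm[above] <- g$cm[m] + (p[above] - g$pos[m]) * s_hi
    sites$cm[i] <- cm
  }
  sites
}
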