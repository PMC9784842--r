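#' Construct a genetic map
#'
#' A genetic map relates each SNP to a chromosome, a physical position (bp,
#' 1-based) and a genetic position (cM).  Within a chromosome markers must be
#' sorted by bp, bp must be unique, and cM must be non-decreasing with bp.
#'
#' @param snp character vector of marker names (unique).
#' @param chrom chromosome labels, one per marker.
#' @param bp integer physical positions (1-based).
#' @param cM numeric genetic positions (non-negative); may be `NA` for markers
#'   awaiting interpolation via [interpolate_map()].
#' @return A `data.frame` of class `"genetic_map"` with columns
#'   `snp`, `chrom`, `bp`, `cM`, sorted by chromosome then bp.
#' @examples
#' genetic_map(c("s1", "s2"), c("1A", "1A"), c(100L, 200L), c(0, 1.5))
#' @export
genetic_map <- function(snp, chrom, bp, cM) {
  stopifnot(length(snp) == length(chrom), length(bp) == length(snp),
            length(cM) == length(snp))
  if (anyDuplicated(snp)) stop("duplicate marker names in map")
  m <- data.frame(snp = as.character(snp), chrom = as.character(chrom),
                  bp = as.integer(bp), cM = as.numeric(cM),
                  stringsAsFactors = FALSE)
  m <- m[order(m$chrom, m$bp), , drop = FALSE]
  rownames(m) <- NULL
  for (ch in unique(m$chrom)) {
    i <- m$chrom == ch
    if (anyDuplicated(m$bp[i])) stop("duplicate bp positions on chromosome ", ch)
    cc <- m$cM[i]
    cc <- cc[!is.na(cc)]
    if (length(cc) && any(diff(cc) < 0))
      stop("cM not non-decreasing with bp on chromosome ", ch)
    if (length(cc) && any(cc < 0)) stop("negative cM on chromosome ", ch)
  }
  class(m) <- c("genetic_map", "data.frame")
  m
}

#' Interpolate genetic positions from physical positions
#'
#' Unmapped markers are placed between the two closest (flanking) anchored
#' markers on the same chromosome by linear interpolation on the bp scale.
#' Queries beyond the terminal anchors are clamped to the terminal anchor's
#' cM.  The result preserves weak monotonicity of cM in bp.
#'
#' @param query data.frame with columns `chrom` and `bp` for the markers that
#'   need genetic positions.
#' @param anchored a [genetic_map()] whose `cM` values are all known.
#' @return numeric vector of interpolated cM, one per query row.
#' @examples
#' anc <- genetic_map(c("a", "b"), c("1A", "1A"), c(1e6L, 2e6L), c(10, 20))
#' interpolate_map(data.frame(chrom = "1A", bp = 1.5e6), anc)  # 15
#' @export
interpolate_map <- function(query, anchored) {
  stopifnot(is.data.frame(query), all(c("chrom", "bp") %in% names(query)))
  anc <- anchored[!is.na(anchored$cM), , drop = FALSE]
  out <- rep(NA_real_, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    a <- anc[anc$chrom == ch, , drop = FALSE]
    if (nrow(a) == 0L)
      stop("no anchored markers on chromosome ", ch, " for markers: ",
           paste(utils::head(qi, 5), collapse = ", "))
    if (nrow(a) == 1L) {
      out[qi] <- a$cM
    } else {
      # approx with rule = 2 is exactly linear-in-bp interpolation with clamping
      out[qi] <- stats::approx(a$bp, a$cM, xout = query$bp[qi], rule = 2,
                               ties = "ordered")$y
    }
  }
  out
}
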