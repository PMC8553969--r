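#' Founder codes of an 8-parent MAGIC population
#'
#' Two-letter codes for the eight founder cultivars (four *japonica*: AK, BE,
#' TC, MI; four *indica*: SU, TK, HO, RU). Haplotype labels throughout the
#' package are integers `1:8` indexing this vector.
#'
#' @return Character vector of length 8.
#' @export
magic_founders <- function() {
  c("AK", "BE", "TC", "MI", "SU", "TK", "HO", "RU")
}

#' Construct a SNP panel
#'
#' A SNP panel is the genomic scaffold of the haplotype scan: one row per SNP
#' with a chromosome id and a 1-based physical position in base pairs.
#' Rows must be sorted by (chromosome, position) with positions unique within
#' each chromosome.
#'
#' @param snp_id character vector of unique SNP labels.
#' @param chrom integer chromosome ids.
#' @param pos_bp integer positions, 1-based bp, strictly increasing within
#'   chromosome.
#' @return A `data.frame` of class `snp_panel` with columns
#'   `snp_id`, `chrom`, `pos_bp`.
#' @export
snp_panel <- function(snp_id, chrom, pos_bp) {
  stopifnot(length(snp_id) == length(chrom), length(chrom) == length(pos_bp))
  if (length(snp_id) == 0L) stop("empty SNP panel")
  if (anyDuplicated(snp_id)) {
    stop("duplicate snp_id: ", snp_id[duplicated(snp_id)][1L])
  }
  chrom <- as.integer(chrom)
  pos_bp <- as.double(pos_bp)
  p <- data.frame(snp_id = as.character(snp_id), chrom = chrom,
                  pos_bp = pos_bp, stringsAsFactors = FALSE)
  validate_snp_panel(p)
  class(p) <- c("snp_panel", "data.frame")
  p
}

validate_snp_panel <- function(p) {
  if (is.unsorted(p$chrom)) stop("panel not sorted by chromosome")
  for (ch in unique(p$chrom)) {
    pos <- p$pos_bp[p$chrom == ch]
    if (any(pos < 1)) stop("position < 1 on chromosome ", ch)
    bad <- which(diff(pos) <= 0)
    if (length(bad)) {
      stop("panel positions not strictly increasing on chromosome ", ch,
           " at SNP ", p$snp_id[p$chrom == ch][bad[1L] + 1L])
    }
  }
  invisible(p)
}

#' Simulate a SNP panel
#'
#' Draws SNP positions uniformly on each chromosome (then sorts), emulating a
#' genotyping-by-sequencing panel at a configurable scale.
#'
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param n_chrom number of chromosomes.
#' @param chrom_len_bp chromosome length in bp (recycled across chromosomes).
#' @param seed integer seed.
#' @return A `snp_panel`.
#' @export
simulate_snp_panel <- function(n_snps = 1000L, n_chrom = 5L,
                               chrom_len_bp = 30e6, seed = 1L) {
  set.seed(seed)
  chrom_len_bp <- rep_len(chrom_len_bp, n_chrom)
  per <- diff(round(seq(0, n_snps, length.out = n_chrom + 1L)))
  rows <- lapply(seq_len(n_chrom), function(ch) {
    pos <- sort(sample.int(chrom_len_bp[ch], per[ch]))
    data.frame(chrom = ch, pos_bp = pos)
  })
  d <- do.call(rbind, rows)
  snp_panel(sprintf("S%d_%d", d$chrom, d$pos_bp), d$chrom, d$pos_bp)
}

#' Construct a haplotype assignment matrix
#'
#' Lines x SNPs integer matrix of founder-of-origin labels in `1:8`
#' (`NA` = missing). Row names are line ids, column names SNP ids matching a
#' panel.
#'
#' @param m integer matrix.
#' @param founders founder code vector (default [magic_founders()]).
#' @return The matrix with class `hap_matrix` and a `founders` attribute.
#' @export
hap_matrix <- function(m, founders = magic_founders()) {
  stopifnot(is.matrix(m))
  vals <- m[!is.na(m)]
  if (length(vals) && (any(vals < 1L) || any(vals > length(founders)))) {
    stop("haplotype labels must be in 1..", length(founders))
  }
  storage.mode(m) <- "integer"
  attr(m, "founders") <- founders
  class(m) <- c("hap_matrix", class(m))
  m
}

#' DAT observation grids for the two field seasons
#'
#' The default time-course sampling: six days-after-transplanting (DAT)
#' timepoints per year, paired columnwise across years
#' (40/39, 56/54, 69/68, 83/83, 97/97, 111/113), two pairs per developmental
#' stage (tillering, heading, maturation).
#'
#' @return A data.frame with columns `dat_y1`, `dat_y2`, `stage`
#'   (years labelled "2019" and "2018" by convention: y1 = 2019).
#' @export
dat_pairing <- function() {
  data.frame(
    dat_y1 = c(40L, 56L, 69L, 83L, 97L, 111L),
    dat_y2 = c(39L, 54L, 68L, 83L, 97L, 113L),
    stage = rep(c("tillering", "heading", "maturation"), each = 2L),
    stringsAsFactors = FALSE
  )
}

#' Map timepoint indices to developmental stages
#'
#' With `n` timepoints per year, the grid is split into three equal thirds:
#' tillering, heading, maturation (the default 6-point grid gives two
#' timepoints per stage).
#'
#' @param n number of timepoints.
#' @return Character vector of length `n`.
#' @export
stage_of_index <- function(n) {
  c("tillering", "heading", "maturation")[ceiling(3 * seq_len(n) / n)]
}
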