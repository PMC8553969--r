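#' Simulate founder-mosaic genomes of a MAGIC population
#'
#' Generates a lines x SNPs matrix of founder-of-origin labels. Each line's
#' genome is a Markovian mosaic along every chromosome: recombination
#' breakpoints arrive as a Poisson process along physical distance at rate
#' `recomb_rate` per bp, and at each breakpoint the founder label is resampled
#' from `founder_freq` (so `founder_freq` is the stationary label
#' distribution). This reproduces the block structure that downstream stages
#' consume without simulating the 8-way funnel pedigree explicitly.
#'
#' @param n_lines number of lines (>= 1).
#' @param panel a [snp_panel()].
#' @param recomb_rate expected breakpoints per bp. The default 3e-7
#'   per bp (~3.3 Mb mean founder-block length) reflects a rice genetic map of
#'   ~4 cM/Mb accumulated over ~7 effective meioses of funnel crossing and
#'   selfing. `0` gives single-founder chromosomes.
#' @param founder_freq founder label probabilities (length 8, summing to 1).
#' @param missing_rate per-entry probability of a missing label (default 0).
#' @param seed integer seed (required: the simulator is a stated world).
#' @return A [hap_matrix()] with rownames `L001..` and colnames = panel SNP ids.
#' @export
simulate_magic_population <- function(n_lines, panel, recomb_rate = 3e-7,
                                      founder_freq = rep(1 / 8, 8),
                                      missing_rate = 0, seed) {
  stopifnot(n_lines >= 1L, !missing(seed))
  if (!inherits(panel, "snp_panel") || nrow(panel) == 0L) {
    stop("empty or invalid SNP panel")
  }
  stopifnot(abs(sum(founder_freq) - 1) < 1e-8, recomb_rate >= 0)
  set.seed(seed)
  n_snp <- nrow(panel)
  nf <- length(founder_freq)
  m <- matrix(NA_integer_, n_lines, n_snp,
              dimnames = list(sprintf("L%03d", seq_len(n_lines)), panel$snp_id))
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    gaps <- diff(panel$pos_bp[idx])
    # P(at least one breakpoint in a gap); label resampled independently of
    # the current state, so repeated events collapse to a single resample
    p_switch <- if (recomb_rate > 0) 1 - exp(-recomb_rate * gaps) else
      rep(0, length(gaps))
    for (i in seq_len(n_lines)) {
      lab <- integer(length(idx))
      lab[1L] <- sample.int(nf, 1L, prob = founder_freq)
      if (length(gaps)) {
        ev <- stats::runif(length(gaps)) < p_switch
        new_lab <- sample.int(nf, sum(ev), replace = TRUE, prob = founder_freq)
        j <- 1L
        for (k in seq_along(gaps)) {
          if (ev[k]) {
            lab[k + 1L] <- new_lab[j]
            j <- j + 1L
          } else lab[k + 1L] <- lab[k]
        }
      }
      m[i, idx] <- lab
    }
  }
  if (missing_rate > 0) {
    drop <- stats::runif(length(m)) < missing_rate
    m[drop] <- NA_integer_
  }
  hap_matrix(m)
}
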