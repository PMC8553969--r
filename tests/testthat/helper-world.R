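# small fixture builders shared across test files; everything is generated
# in code, no stored data

tiny_panel <- function(n = 40L, n_chrom = 2L, len = 10e6, seed = 11L) {
  simulate_snp_panel(n, n_chrom, len, seed = seed)
}

# a scan_result-shaped frame with prescribed p-values, for selection-rule
# tests that do not need a real scan
fake_scan <- function(p, panel = NULL) {
  n <- length(p)
  if (is.null(panel)) {
    panel <- snp_panel(sprintf("S%02d", seq_len(n)), rep(1L, n),
                       seq_len(n) * 1e5)
  }
  structure(data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                       pos_bp = panel$pos_bp, H = NA_real_, df = 7L, k = 8L,
                       n = 165L, p = p, p_bonf = pmin(p * n, 1),
                       stringsAsFactors = FALSE),
            class = c("scan_result", "data.frame"))
}

# founder-block segment lengths (in SNPs) of one hap_matrix: each segment's
# label is an independent draw from the founder distribution
hap_segments <- function(haps, panel) {
  labs <- integer(0); lens <- integer(0)
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    for (i in seq_len(nrow(haps))) {
      r <- rle(haps[i, idx])
      labs <- c(labs, r$values)
      lens <- c(lens, r$lengths)
    }
  }
  list(labels = labs, lengths = lens)
}
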