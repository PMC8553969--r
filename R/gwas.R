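#' Kruskal-Wallis rank-sum test over haplotype classes
#'
#' Tie-corrected Kruskal-Wallis H with an upper-tail chi-square p-value on
#' k - 1 degrees of freedom. Lines with missing values or labels are dropped,
#' then classes with fewer than `min_class_size` lines are excluded before
#' ranking (the small-class rule guards against 1-line classes dominating the
#' ranks). With all surviving values identical the statistic is defined as
#' H = 0, p = 1.
#'
#' H = \[ 12/(N(N+1)) * sum_i R_i^2/n_i - 3(N+1) \] / \[ 1 - sum(t^3 - t)/(N^3 - N) \]
#' with R_i the rank sum of class i and t the tie-group sizes.
#'
#' @param values numeric trait values per line.
#' @param groups integer/factor haplotype label per line.
#' @param min_class_size smallest class size tested (default 4).
#' @return one-row data.frame `H, df, p, k, n`; all-`NA` statistics when
#'   fewer than 2 classes survive.
#' @export
kruskal_wallis <- function(values, groups, min_class_size = 4L) {
  stopifnot(length(values) == length(groups))
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]
  g <- as.integer(factor(groups[keep]))
  if (length(v)) {
    sizes <- tabulate(g)
    ok_class <- which(sizes >= min_class_size)
    keep2 <- g %in% ok_class
    v <- v[keep2]
    g <- as.integer(factor(g[keep2]))
  }
  k <- length(unique(g))
  n <- length(v)
  if (k < 2L) {
    return(data.frame(H = NA_real_, df = NA_integer_, p = NA_real_,
                      k = k, n = n))
  }
  r <- rank(v)
  R <- rowsum(r, g)[, 1L]
  ni <- tabulate(g)
  H_raw <- 12 / (n * (n + 1)) * sum(R^2 / ni) - 3 * (n + 1)
  ties <- table(v)
  C <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (C <= 0) {                      # all values identical
    return(data.frame(H = 0, df = k - 1L, p = 1, k = k, n = n))
  }
  H <- H_raw / C
  data.frame(H = H, df = k - 1L,
             p = stats::pchisq(H, k - 1L, lower.tail = FALSE),
             k = k, n = n)
}

#' Per-SNP haplotype scan of one trait slice
#'
#' Applies [kruskal_wallis()] independently at every SNP of the panel, using
#' each line's founder-of-origin label at that SNP as the grouping. Lines
#' with a missing label are dropped per SNP, not listwise. Raw p-values are
#' reported without multiple-testing adjustment (selection happens on raw
#' p-values across two years); a Bonferroni-adjusted column is emitted for
#' information only.
#'
#' @param values named numeric vector of one trait slice (names = line ids),
#'   e.g. from [trait_slice()].
#' @param haps [hap_matrix()].
#' @param panel [snp_panel()] matching the haplotype matrix columns.
#' @param min_class_size see [kruskal_wallis()].
#' @return data.frame of class `scan_result`: `snp_id, chrom, pos_bp, H, df,
#'   k, n, p, p_bonf` (one row per SNP; untestable SNPs carry `NA`).
#' @export
haplotype_scan <- function(values, haps, panel, min_class_size = 4L) {
  common <- intersect(names(values), rownames(haps))
  if (length(common) == 0L) stop("no overlapping line ids between traits and haplotypes")
  if (!all(panel$snp_id %in% colnames(haps))) {
    stop("panel SNPs missing from haplotype matrix")
  }
  v0 <- values[common]
  hm <- haps[common, panel$snp_id, drop = FALSE]
  ok <- !is.na(v0)
  v0 <- v0[ok]
  hm <- hm[ok, , drop = FALSE]
  n_full <- length(v0)
  r_full <- rank(v0)
  ties <- table(v0)
  C_full <- 1 - sum(ties^3 - ties) / (n_full^3 - n_full)

  n_snp <- nrow(panel)
  H <- df <- p <- rep(NA_real_, n_snp)
  k <- nn <- rep(NA_integer_, n_snp)
  for (j in seq_len(n_snp)) {
    g <- hm[, j]
    sizes <- tabulate(g, 8L)
    full <- !anyNA(g) && all(sizes == 0L | sizes >= min_class_size)
    if (full) {
      # fast path: no dropped lines, reuse the precomputed ranks
      kk <- sum(sizes > 0L)
      if (kk < 2L) next
      R <- rowsum(r_full, g)[, 1L]
      ni <- sizes[sizes > 0L]
      H_raw <- 12 / (n_full * (n_full + 1)) * sum(R^2 / ni) - 3 * (n_full + 1)
      if (C_full <= 0) {
        H[j] <- 0; df[j] <- kk - 1L; p[j] <- 1
      } else {
        H[j] <- H_raw / C_full
        df[j] <- kk - 1L
        p[j] <- stats::pchisq(H[j], kk - 1L, lower.tail = FALSE)
      }
      k[j] <- kk; nn[j] <- n_full
    } else {
      res <- kruskal_wallis(v0, g, min_class_size)
      H[j] <- res$H; df[j] <- res$df; p[j] <- res$p
      k[j] <- res$k; nn[j] <- res$n
    }
  }
  out <- data.frame(snp_id = panel$snp_id, chrom = panel$chrom,
                    pos_bp = panel$pos_bp, H = H, df = df, k = k, n = nn,
                    p = p, p_bonf = pmin(p * n_snp, 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Two-year SNP selection rule
#'
#' A SNP is selected when its scan p-value is below `p_cut` in *both* years
#' and the product of the two p-values is below `product_cut`
#' (defaults 1e-2 and 1e-5). SNPs untestable in either year are never
#' selected.
#'
#' @param scan_y1,scan_y2 [haplotype_scan()] results on the same panel
#'   (stage-matched timepoints of the two years).
#' @param p_cut,product_cut thresholds.
#' @return Character vector of selected SNP ids.
#' @export
select_snps <- function(scan_y1, scan_y2, p_cut = 1e-2, product_cut = 1e-5) {
  if (!identical(scan_y1$snp_id, scan_y2$snp_id)) {
    stop("scans are on different panels")
  }
  p1 <- scan_y1$p; p2 <- scan_y2$p
  sel <- !is.na(p1) & !is.na(p2) & p1 < p_cut & p2 < p_cut &
    p1 * p2 < product_cut
  scan_y1$snp_id[sel]
}

#' Call QTLs from per-timepoint SNP selections
#'
#' Takes, for every stage-matched timepoint pair, the set of selected SNPs
#' and the two scans it was derived from. Per chromosome, the union of SNPs
#' selected at any timepoint is sorted by position and partitioned into runs
#' in which consecutive selected SNPs are at most `merge_gap_bp` apart
#' (default 2 Mb); each run becomes one QTL. The representative SNP is the
#' run member with the smallest two-year p-value product over all timepoints
#' (ties broken by lower position); the interval spans the run's outermost
#' SNPs (a single-SNP run gets a degenerate interval). Detection flags mark
#' the timepoint pairs at which any run member was selected, and stage
#' labels are derived from the flags.
#'
#' @param selections named list (one element per timepoint pair, e.g.
#'   `"83_83"`) of selected SNP id vectors.
#' @param scans_y1,scans_y2 named lists of the matching [haplotype_scan()]
#'   results (same names as `selections`).
#' @param panel the [snp_panel()].
#' @param merge_gap_bp maximum within-QTL gap (default 2e6).
#' @param trait trait tag used in QTL names (`qCH...`).
#' @return data.frame of class `qtl_table`: `name, chrom, start_bp, end_bp,
#'   rep_snp, rep_pos, min_p_product`, one logical `det_<pair>` column per
#'   timepoint pair, and `stages`. Empty selections give a 0-row table.
#' @export
call_qtls <- function(selections, scans_y1, scans_y2, panel,
                      merge_gap_bp = 2e6, trait = "CH") {
  stopifnot(is.list(selections), !is.null(names(selections)))
  pairs <- names(selections)
  stopifnot(all(pairs %in% names(scans_y1)), all(pairs %in% names(scans_y2)))
  all_sel <- sort(unique(unlist(selections, use.names = FALSE)))
  det_cols <- paste0("det_", pairs)
  empty <- data.frame(name = character(), chrom = integer(),
                      start_bp = double(), end_bp = double(),
                      rep_snp = character(), rep_pos = double(),
                      min_p_product = double(), stringsAsFactors = FALSE)
  for (dc in det_cols) empty[[dc]] <- logical()
  empty$stages <- character()
  if (length(all_sel) == 0L) {
    class(empty) <- c("qtl_table", "data.frame")
    return(empty)
  }
  # min over timepoints of p1*p2, per selected SNP
  idx <- match(all_sel, panel$snp_id)
  if (anyNA(idx)) stop("selected SNP not in panel: ", all_sel[is.na(idx)][1L])
  pprod <- rep(Inf, length(all_sel))
  for (pr in pairs) {
    s1 <- scans_y1[[pr]]; s2 <- scans_y2[[pr]]
    pp <- s1$p[match(all_sel, s1$snp_id)] * s2$p[match(all_sel, s2$snp_id)]
    pprod <- pmin(pprod, pp, na.rm = TRUE)
  }
  d <- data.frame(snp_id = all_sel, chrom = panel$chrom[idx],
                  pos_bp = panel$pos_bp[idx], pprod = pprod,
                  stringsAsFactors = FALSE)
  d <- d[order(d$chrom, d$pos_bp), ]

  out <- list()
  for (ch in unique(d$chrom)) {
    dc <- d[d$chrom == ch, ]
    run <- cumsum(c(1, diff(dc$pos_bp) > merge_gap_bp))
    for (rn in unique(run)) {
      dr <- dc[run == rn, ]
      best <- order(dr$pprod, dr$pos_bp)[1L]
      row <- data.frame(name = NA_character_, chrom = ch,
                        start_bp = min(dr$pos_bp), end_bp = max(dr$pos_bp),
                        rep_snp = dr$snp_id[best], rep_pos = dr$pos_bp[best],
                        min_p_product = dr$pprod[best],
                        stringsAsFactors = FALSE)
      for (pr in pairs) {
        row[[paste0("det_", pr)]] <- any(dr$snp_id %in% selections[[pr]])
      }
      out[[length(out) + 1L]] <- row
    }
  }
  q <- do.call(rbind, out)
  q <- q[order(q$chrom, q$start_bp), ]
  # names: q<trait><chrom>, with -<ordinal> only when a chromosome hosts >= 2
  nm <- character(nrow(q))
  for (ch in unique(q$chrom)) {
    w <- which(q$chrom == ch)
    nm[w] <- if (length(w) == 1L) paste0("q", trait, ch) else
      paste0("q", trait, ch, "-", seq_along(w))
  }
  q$name <- nm
  # stage labels from flags; chronological pair order (parsed from the
  # "dat1_dat2" keys when possible) split in thirds, so the result does not
  # depend on the order selections were supplied in
  d1 <- suppressWarnings(as.numeric(sub("_.*$", "", pairs)))
  ord <- if (anyNA(d1)) seq_along(pairs) else order(d1)
  st <- character(length(pairs))
  st[ord] <- stage_of_index(length(pairs))
  q$stages <- vapply(seq_len(nrow(q)), function(i) {
    f <- unlist(q[i, det_cols])
    paste(unique(st[ord][f[ord]]), collapse = "+")
  }, character(1L))
  rownames(q) <- NULL
  class(q) <- c("qtl_table", "data.frame")
  q
}
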