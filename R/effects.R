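#' Haplotype effects at a QTL
#'
#' The haplotype effect is the mean trait value of the lines carrying a given
#' founder haplotype at the QTL's representative SNP, together with its ratio
#' to the population mean. The population mean is taken over *all* lines with
#' a value and a label — including lines belonging to classes too small to
#' report. Classes with fewer than `min_n` lines are excluded from the
#' output.
#'
#' @param values named trait slice (names = line ids).
#' @param groups named haplotype labels at the representative SNP
#'   (integer 1-8), typically `haps[, rep_snp]`.
#' @param min_n smallest reported class (default 4).
#' @param founders founder code vector used to label classes.
#' @return data.frame `haplotype, n, mean, ratio` (ratio = class mean /
#'   population mean); zero rows with a warning when no class reaches
#'   `min_n`.
#' @export
haplotype_effect <- function(values, groups, min_n = 4L,
                             founders = magic_founders()) {
  common <- intersect(names(values), names(groups))
  v <- values[common]
  g <- groups[common]
  keep <- !is.na(v) & !is.na(g)
  v <- v[keep]; g <- g[keep]
  pop_mean <- mean(v)
  cls <- sort(unique(g))
  n_i <- vapply(cls, function(cl) sum(g == cl), integer(1L))
  mean_i <- vapply(cls, function(cl) mean(v[g == cl]), double(1L))
  ok <- n_i >= min_n
  if (!any(ok)) {
    warning("no haplotype class reaches n >= ", min_n)
  }
  data.frame(haplotype = founders[cls[ok]], n = n_i[ok], mean = mean_i[ok],
             ratio = mean_i[ok] / pop_mean, stringsAsFactors = FALSE)
}

#' Quadratic fit of a haplotype-effect time course
#'
#' Ordinary least squares of class means on DAT and DAT^2; with exactly three
#' timepoints the parabola interpolates. The leading coefficient `c2`
#' measures the sharpness of the time course: haplotypes whose effect is
#' stable across stages fit flatter curves (smaller |c2|).
#'
#' @param dat DAT values (>= 3 non-missing points required).
#' @param means class means at those timepoints.
#' @return Named vector `c(c2, c1, c0)` for mean(t) = c2 t^2 + c1 t + c0,
#'   or all-`NA` with fewer than 3 points.
#' @export
fit_quadratic <- function(dat, means) {
  ok <- !is.na(dat) & !is.na(means)
  if (sum(ok) < 3L) {
    return(c(c2 = NA_real_, c1 = NA_real_, c0 = NA_real_))
  }
  t <- dat[ok]; y <- means[ok]
  co <- stats::coef(stats::lm(y ~ I(t^2) + t))
  c(c2 = unname(co["I(t^2)"]), c1 = unname(co["t"]),
    c0 = unname(co["(Intercept)"]))
}

#' Full haplotype-effect profile for a QTL table
#'
#' For every called QTL, year and timepoint, computes the per-class
#' [haplotype_effect()] on a trait; per (QTL, haplotype, year) the
#' time-course of class means is additionally summarised by a
#' [fit_quadratic()].
#'
#' @param traits long trait table.
#' @param haps [hap_matrix()].
#' @param qtls a `qtl_table` from [call_qtls()].
#' @param trait trait name (default `"CH"`).
#' @param timepoints named list of DAT vectors per year (default from
#'   [dat_pairing()]).
#' @param min_n see [haplotype_effect()].
#' @return list with `profile` (`qtl, haplotype, year, dat, n, mean, ratio`)
#'   and `quadratic` (`qtl, haplotype, year, c2, c1, c0`).
#' @export
effect_profile <- function(traits, haps, qtls, trait = "CH",
                           timepoints = NULL, min_n = 4L) {
  if (is.null(timepoints)) {
    pr <- dat_pairing()
    timepoints <- list("2019" = pr$dat_y1, "2018" = pr$dat_y2)
  }
  prof <- list(); quad <- list()
  for (i in seq_len(nrow(qtls))) {
    snp <- qtls$rep_snp[i]
    g <- stats::setNames(haps[, snp], rownames(haps))
    for (year in names(timepoints)) {
      for (t in timepoints[[year]]) {
        v <- trait_slice(traits, trait, year, t)
        he <- haplotype_effect(v, g, min_n)
        if (nrow(he) == 0L) next
        prof[[length(prof) + 1L]] <- data.frame(
          qtl = qtls$name[i], haplotype = he$haplotype, year = year,
          dat = t, n = he$n, mean = he$mean, ratio = he$ratio,
          stringsAsFactors = FALSE)
      }
    }
  }
  profile <- do.call(rbind, prof)
  if (!is.null(profile)) {
    key <- unique(profile[c("qtl", "haplotype", "year")])
    for (j in seq_len(nrow(key))) {
      s <- profile[profile$qtl == key$qtl[j] &
                     profile$haplotype == key$haplotype[j] &
                     profile$year == key$year[j], ]
      q <- fit_quadratic(s$dat, s$mean)
      quad[[length(quad) + 1L]] <- data.frame(
        qtl = key$qtl[j], haplotype = key$haplotype[j], year = key$year[j],
        c2 = q["c2"], c1 = q["c1"], c0 = q["c0"],
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(profile = profile, quadratic = do.call(rbind, quad))
}

#' Correlation between two haplotype-effect vectors
#'
#' Pearson correlation over the haplotype classes shared by two effect
#' profiles (class means by default; ratios give the identical r by scale
#' invariance). Two-sided p from the t distribution on n - 2 df, annotated
#' at p < 0.05 (*) and p < 0.01 (**).
#'
#' @param a,b named numeric vectors (names = haplotype codes) or
#'   [haplotype_effect()] frames.
#' @param use `"mean"` or `"ratio"` column when frames are given.
#' @return one-row data.frame `r, p, n, tier`; `NA` when fewer than 3 shared
#'   classes.
#' @export
effect_correlation <- function(a, b, use = c("mean", "ratio")) {
  use <- match.arg(use)
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x[[use]], x$haplotype) else x
  }
  a <- as_vec(a); b <- as_vec(b)
  shared <- intersect(names(a), names(b))
  shared <- shared[!is.na(a[shared]) & !is.na(b[shared])]
  if (length(shared) < 3L) {
    return(data.frame(r = NA_real_, p = NA_real_, n = length(shared),
                      tier = NA_character_, stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(a[shared], b[shared], method = "pearson")
  tier <- if (ct$p.value < 0.01) "**" else if (ct$p.value < 0.05) "*" else ""
  data.frame(r = unname(ct$estimate), p = ct$p.value, n = length(shared),
             tier = tier, stringsAsFactors = FALSE)
}

#' Assemble the QTL x (year, DAT, haplotype) effect matrix
#'
#' @param profile the `profile` frame from [effect_profile()].
#' @return Numeric matrix, rows = QTLs, columns = `year.dat.haplotype`
#'   entries; missing combinations are `NA`.
#' @export
effect_matrix <- function(profile) {
  col <- interaction(profile$year, profile$dat, profile$haplotype, drop = TRUE)
  qtls <- unique(profile$qtl)
  m <- matrix(NA_real_, length(qtls), nlevels(col),
              dimnames = list(qtls, levels(col)))
  m[cbind(match(profile$qtl, qtls), as.integer(col))] <- profile$mean
  m
}

#' Hierarchical clustering of QTLs on effect correlations
#'
#' Agglomerative clustering (average linkage) with distance 1 - r, where r
#' is the Pearson correlation of two QTLs' haplotype-effect vectors over
#' their shared non-missing entries. QTLs whose time courses track each
#' other (e.g. constant-effect loci) merge low in the tree.
#'
#' @param m effect matrix from [effect_matrix()] (>= 2 rows).
#' @return An [stats::hclust] object.
#' @export
cluster_qtls <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 QTLs to cluster")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(ok) < 3L) {
        stop("fewer than 3 shared entries between ", rownames(m)[i],
             " and ", rownames(m)[j])
      }
      r <- stats::cor(m[i, ok], m[j, ok])
      d[i, j] <- d[j, i] <- 1 - r
    }
  }
  stats::hclust(stats::as.dist(d), method = "average")
}

# letter display for pairwise comparisons: classes ordered by decreasing
# mean; every maximal interval of mutually non-significant classes gets one
# letter, possibly overlapping (standard compact letter display on ordered
# means)
assign_letters <- function(means, sig) {
  ord <- order(-means)
  k <- length(means)
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[ord[i:(j + 1L)], ord[i:(j + 1L)]])) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  # keep only intervals not contained in an earlier (longer) one
  keep <- vapply(seq_len(k), function(i) {
    !any(vapply(seq_len(i - 1L), function(h) {
      intervals[[h]][1L] <= intervals[[i]][1L] &&
        intervals[[h]][2L] >= intervals[[i]][2L]
    }, logical(1L)))
  }, logical(1L))
  groups <- intervals[keep]
  lett <- rep("", k)
  for (gi in seq_along(groups)) {
    idx <- ord[groups[[gi]][1L]:groups[[gi]][2L]]
    lett[idx] <- paste0(lett[idx], letters[gi])
  }
  lett
}

#' Allele-class grouping test at a QTL
#'
#' Collapses founder haplotypes into functional allele classes via a mapping
#' (e.g. four *Sd1* alleles in eight founders collapsing to three classes),
#' then tests class differentiation: a Kruskal-Wallis omnibus across classes
#' plus unadjusted pairwise Wilcoxon rank-sum tests with letter grouping at
#' alpha = 0.05.
#'
#' @param values named trait slice.
#' @param groups named haplotype labels at the QTL.
#' @param class_map named character vector mapping founder codes to class
#'   labels; every included founder must be mapped.
#' @param min_n smallest class tested (default 4).
#' @param alpha pairwise significance level for lettering.
#' @return list with `classes` (`class, n, mean, letter`), `omnibus`
#'   (Kruskal-Wallis row), `pairwise` (`class_a, class_b, p`).
#' @export
allele_class_test <- function(values, groups, class_map, min_n = 4L,
                              alpha = 0.05) {
  common <- intersect(names(values), names(groups))
  v <- values[common]
  f <- magic_founders()[groups[common]]
  keep <- !is.na(v) & !is.na(f)
  v <- v[keep]; f <- f[keep]
  unmapped <- setdiff(unique(f), names(class_map))
  if (length(unmapped)) stop("founder not mapped to an allele class: ",
                             unmapped[1L])
  cl <- class_map[f]
  sizes <- table(cl)
  keepc <- names(sizes)[sizes >= min_n]
  sel <- cl %in% keepc
  v <- v[sel]; cl <- cl[sel]
  if (length(unique(cl)) < 2L) {
    return(list(classes = NULL, omnibus = NULL, pairwise = NULL))
  }
  omni <- kruskal_wallis(v, factor(cl), min_class_size = min_n)
  cls <- sort(unique(cl))
  mean_i <- vapply(cls, function(x) mean(v[cl == x]), double(1L))
  n_i <- vapply(cls, function(x) sum(cl == x), integer(1L))
  pw <- list()
  sig <- matrix(FALSE, length(cls), length(cls))
  for (i in seq_along(cls)[-length(cls)]) {
    for (j in (i + 1L):length(cls)) {
      p <- suppressWarnings(
        stats::wilcox.test(v[cl == cls[i]], v[cl == cls[j]])$p.value)
      pw[[length(pw) + 1L]] <- data.frame(class_a = cls[i], class_b = cls[j],
                                          p = p, stringsAsFactors = FALSE)
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }
  lett <- assign_letters(mean_i, sig)
  list(classes = data.frame(class = cls, n = n_i, mean = mean_i,
                            letter = lett, stringsAsFactors = FALSE,
                            row.names = NULL),
       omnibus = omni, pairwise = do.call(rbind, pw))
}

#' Contrast extreme haplotype groups on yield-allocation traits
#'
#' Pools lines by membership of a "top" vs "bottom" haplotype set at a QTL
#' (e.g. the canopy-raising vs canopy-lowering haplotypes) and compares the
#' groups on each requested trait with a Welch t-test, reporting group means
#' with standard errors, the top/bottom ratio of means, and significance
#' tiers at p < 0.01 (**), < 0.05 (*), < 0.1 (+).
#'
#' @param trait_values named list of trait slices (named numeric vectors),
#'   e.g. `list(CH = ..., PW = ..., SLW = ..., PW_SLW = ...)`.
#' @param groups named haplotype labels at the QTL (integer codes).
#' @param top_set,bottom_set founder codes defining the two groups.
#' @return data.frame `trait, n_top, n_bottom, mean_top, se_top, mean_bottom,
#'   se_bottom, ratio, p, tier` (p is `NA` when a group has < 2 lines).
#' @export
contrast_extremes <- function(trait_values, groups, top_set, bottom_set) {
  if (length(top_set) == 0L || length(bottom_set) == 0L) {
    stop("both haplotype sets must be non-empty")
  }
  f <- magic_founders()[groups]
  names(f) <- names(groups)
  rows <- lapply(names(trait_values), function(tr) {
    v <- trait_values[[tr]]
    common <- intersect(names(v), names(f))
    vt <- v[common][f[common] %in% top_set]
    vb <- v[common][f[common] %in% bottom_set]
    vt <- vt[!is.na(vt)]; vb <- vb[!is.na(vb)]
    se <- function(x) stats::sd(x) / sqrt(length(x))
    p <- if (length(vt) >= 2L && length(vb) >= 2L) {
      stats::t.test(vt, vb)$p.value
    } else NA_real_
    tier <- if (is.na(p)) NA_character_
    else if (p < 0.01) "**" else if (p < 0.05) "*" else if (p < 0.1) "+"
    else ""
    data.frame(trait = tr, n_top = length(vt), n_bottom = length(vb),
               mean_top = mean(vt), se_top = se(vt),
               mean_bottom = mean(vb), se_bottom = se(vb),
               ratio = mean(vt) / mean(vb), p = p, tier = tier,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
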