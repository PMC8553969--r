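test_that("Kruskal-Wallis statistic matches the hand-checked instance and edge rules", {
  r <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 2, 2, 2),
                      min_class_size = 1)
  expect_equal(round(r$H, 3), 3.857)
  expect_equal(r$df, 1L)

  # identical value multisets in two classes
  r <- kruskal_wallis(c(5, 7, 9, 5, 7, 9), rep(1:2, each = 3),
                      min_class_size = 1)
  expect_equal(r$H, 0, tolerance = 1e-12)

  # all values identical: defined as H = 0, p = 1
  r <- kruskal_wallis(rep(2, 10), rep(1:2, 5), min_class_size = 1)
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)

  # the n < 4 rule drops the size-3 class before testing
  v <- c(rnorm(4), rnorm(4) + 1, rnorm(3) + 9)
  g <- rep(1:3, c(4, 4, 3))
  r <- kruskal_wallis(v, g, min_class_size = 4)
  expect_equal(r$df, 1L)
  expect_equal(r$n, 8L)

  # fewer than 2 surviving classes -> flagged missing
  r <- kruskal_wallis(rnorm(5), c(1, 1, 1, 1, 2), min_class_size = 4)
  expect_true(is.na(r$H))
})

test_that("Kruskal-Wallis agrees with stats::kruskal.test including ties", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    g <- sample(1:4, n, replace = TRUE)
    if (length(unique(g)) < 2) next
    v <- sample(1:8, n, replace = TRUE)  # heavy ties
    if (length(unique(v)) < 2) next
    mine <- kruskal_wallis(v, g, min_class_size = 1)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("H is monotone in the shift between two classes", {
  set.seed(52)
  v0 <- rnorm(20)
  g <- rep(1:2, each = 10)
  H <- vapply(seq(0, 5, by = 0.25), function(s) {
    kruskal_wallis(v0 + s * (g == 2), g, min_class_size = 1)$H
  }, double(1))
  expect_true(all(diff(H) >= -1e-12))
})

test_that("scan finds a planted QTL and a permutation destroys it", {
  panel <- tiny_panel(60, 2, 20e6, seed = 53)
  haps <- simulate_magic_population(165, panel, seed = 54)
  spec <- qtl_effect_spec(panel$snp_id[30], c(RU = 10), stages = "heading")
  tr <- simulate_traits(haps, list(spec), noise_sd = 5, seed = 55)
  v <- trait_slice(tr, "CH", "2019", 83)
  s <- haplotype_scan(v, haps, panel)
  expect_equal(nrow(s), nrow(panel))
  expect_lt(s$p[30], 1e-4)

  set.seed(56)
  vp <- setNames(sample(v), names(v))
  sp <- haplotype_scan(vp, haps, panel)
  expect_gt(sp$p[30], 1e-4)

  names(v) <- paste0("X", names(v))
  expect_error(haplotype_scan(v, haps, panel), "overlap")
})

test_that("scan handles missing labels per SNP, not listwise", {
  panel <- tiny_panel(20, 1, 5e6, seed = 57)
  haps <- simulate_magic_population(100, panel, missing_rate = 0.15,
                                    seed = 58)
  tr <- simulate_traits(haps, noise_sd = 5, seed = 59)
  s <- haplotype_scan(trait_slice(tr, "CH", "2019", 83), haps, panel)
  # lines tested varies by SNP and exceeds the listwise-complete count
  n_listwise <- sum(stats::complete.cases(haps))
  expect_true(any(s$n > n_listwise))
})

test_that("two-year selection rule applies both cuts and the product cut", {
  s1 <- fake_scan(c(5e-3, 5e-3, 1e-6, 0.5, NA))
  s2 <- fake_scan(c(1e-3, 5e-3, 2e-2, 1e-8, 1e-8))
  sel <- select_snps(s1, s2)
  # p1*p2: 5e-6 in, 2.5e-5 out, year-2 fails cut, year-1 fails cut, NA out
  expect_identical(sel, s1$snp_id[1])

  s3 <- fake_scan(rep(0.5, 4))
  expect_error(select_snps(s1, s3), "panels")
})

test_that("QTL calling merges runs by the 2-Mb rule", {
  panel <- snp_panel(sprintf("S%d", 1:5), rep(1L, 5),
                     c(1.0e6, 1.5e6, 2.2e6, 4.0e6, 9.0e6))
  mkscan <- function(p) fake_scan(p, panel)
  # SNPs at 1.0/1.5/2.2 Mb -> one QTL (gaps 0.5, 0.7 Mb)
  s1 <- mkscan(c(1e-4, 1e-5, 1e-3, 1, 1))
  s2 <- mkscan(c(1e-3, 1e-4, 1e-3, 1, 1))
  q <- call_qtls(list(a = panel$snp_id[1:3]), list(a = s1), list(a = s2),
                 panel)
  expect_equal(nrow(q), 1L)
  expect_equal(q$start_bp, 1.0e6)
  expect_equal(q$end_bp, 2.2e6)
  expect_equal(q$rep_snp, "S2")      # lowest p1*p2

  # 1.0 and 4.0 Mb -> two QTLs (gap 3 Mb > 2 Mb); single-SNP runs get
  # degenerate intervals
  q <- call_qtls(list(a = c("S1", "S4")), list(a = s1), list(a = s2), panel)
  expect_equal(nrow(q), 2L)
  expect_equal(q$start_bp, q$end_bp)
  expect_equal(q$name, c("qCH1-1", "qCH1-2"))

  # empty selection is a valid empty table
  q <- call_qtls(list(a = character()), list(a = s1), list(a = s2), panel)
  expect_equal(nrow(q), 0L)
})

test_that("QTL calling is invariant to the order of timepoint selections", {
  panel <- tiny_panel(50, 2, 20e6, seed = 61)
  haps <- simulate_magic_population(165, panel, seed = 62)
  spec <- qtl_effect_spec(panel$snp_id[12], c(RU = 12))
  tr <- simulate_traits(haps, list(spec), noise_sd = 5, seed = 63)
  pr <- dat_pairing()
  s1 <- list(); s2 <- list(); sel <- list()
  for (i in 1:6) {
    key <- paste0(pr$dat_y1[i], "_", pr$dat_y2[i])
    s1[[key]] <- haplotype_scan(trait_slice(tr, "CH", "2019", pr$dat_y1[i]),
                                haps, panel)
    s2[[key]] <- haplotype_scan(trait_slice(tr, "CH", "2018", pr$dat_y2[i]),
                                haps, panel)
    sel[[key]] <- select_snps(s1[[key]], s2[[key]])
  }
  qa <- call_qtls(sel, s1, s2, panel)
  ord <- rev(names(sel))
  qb <- call_qtls(sel[ord], s1[ord], s2[ord], panel)
  expect_equal(qa$rep_snp, qb$rep_snp)
  expect_equal(qa$start_bp, qb$start_bp)
  expect_equal(qa[paste0("det_", names(sel))], qb[paste0("det_", names(sel))])
})
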