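test_that("haplotype effects: means, ratios and the n<4 rule", {
  # 8 lines at 100 cm (class 1), 8 at 120 cm (class 2)
  v <- setNames(rep(c(100, 120), each = 8), sprintf("L%02d", 1:16))
  g <- setNames(rep(c(1L, 2L), each = 8), names(v))
  he <- haplotype_effect(v, g)
  expect_equal(he$mean, c(100, 120))
  expect_equal(round(he$ratio, 3), c(0.909, 1.091))

  # constant trait: every ratio 1
  vc <- setNames(rep(7, 16), names(v))
  expect_equal(haplotype_effect(vc, g)$ratio, c(1, 1))

  # a 3-line class is absent from the output, but its lines still count in
  # the population mean
  g3 <- g; g3[14:16] <- 3L
  he <- haplotype_effect(v, g3)
  expect_false(any(he$haplotype == magic_founders()[3]))
  expect_equal(he$ratio, he$mean / mean(v))

  expect_warning(haplotype_effect(v[1:3], g[1:3]), "n >= 4")
})

test_that("weighted class means reproduce the mean over included lines exactly", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    v <- setNames(rnorm(n, 100, 15), sprintf("L%03d", 1:n))
    g <- setNames(sample(1:8, n, replace = TRUE), names(v))
    he <- haplotype_effect(v, g, min_n = 4)
    if (nrow(he) == 0) next
    incl <- g %in% match(he$haplotype, magic_founders())
    expect_equal(sum(he$n * he$mean) / sum(he$n), mean(v[incl]),
                 tolerance = 1e-12)
  }
})

test_that("quadratic fits interpolate and flag degenerate input", {
  t <- c(40, 56, 69, 83, 97, 111)
  co <- fit_quadratic(t, -0.01 * t^2 + 2 * t)
  expect_equal(unname(co), c(-0.01, 2, 0), tolerance = 1e-9)

  co <- fit_quadratic(t, rep(5, 6))
  expect_equal(unname(co[c("c2", "c1")]), c(0, 0), tolerance = 1e-12)

  expect_true(all(is.na(fit_quadratic(c(1, 2), c(1, 2)))))

  # exact interpolation at 3 points
  co <- fit_quadratic(c(1, 2, 3), c(2, 5, 10))
  expect_equal(unname(co["c2"] * 4 + co["c1"] * 2 + co["c0"]), 5,
               tolerance = 1e-9)
})

test_that("a flat haplotype fits a flatter parabola than a collapsing one", {
  t <- c(40, 56, 69, 83, 97, 111)
  set.seed(72)
  flat <- 110 + rnorm(6, 0, 1)
  collapse <- c(110, 112, 113, 110, 90, 70) + rnorm(6, 0, 1)
  expect_lt(abs(fit_quadratic(t, flat)["c2"]),
            abs(fit_quadratic(t, collapse)["c2"]))
})

test_that("effect correlations behave at the anchors", {
  a <- setNames(c(100, 105, 110, 120, 95), magic_founders()[1:5])
  expect_equal(effect_correlation(a, a)$r, 1, tolerance = 1e-12)
  b <- mean(a) - (a - mean(a))
  expect_equal(effect_correlation(a, b)$r, -1, tolerance = 1e-12)
  expect_true(is.na(effect_correlation(a[1:2], a[1:2])$r))
  # ratio scaling leaves r unchanged
  expect_equal(effect_correlation(a, 2 * a)$r, 1, tolerance = 1e-12)
})

test_that("QTL clustering merges duplicates at zero and is order invariant", {
  base <- c(100, 104, 99, 110, 105, 95, 102, 101)
  m <- rbind(q1 = base, q2 = base, q3 = rev(base) * 1.5)
  colnames(m) <- paste0("c", 1:8)
  hc <- cluster_qtls(m)
  expect_equal(min(hc$height), 0, tolerance = 1e-12)
  first <- hc$merge[1, ]
  expect_setequal(hc$labels[-first], c("q1", "q2"))

  perm <- m[c(3, 1, 2), ]
  hc2 <- cluster_qtls(perm)
  expect_equal(sort(hc$height), sort(hc2$height), tolerance = 1e-12)

  m_bad <- m
  m_bad[2, 3:8] <- NA
  expect_error(cluster_qtls(m_bad), "q2")
})

test_that("allele-class mapping collapses founders and letters separate planted shifts", {
  set.seed(73)
  n <- 165
  g <- setNames(sample(1:8, n, replace = TRUE), sprintf("L%03d", 1:n))
  # alleles: A = {AK,BE}, B = {TC,MI,SU}, C = {TK,HO}, D = {RU}; C and D
  # collapse into one functional class
  map <- c(AK = "c", BE = "c", TC = "b", MI = "b", SU = "b",
           TK = "a", HO = "a", RU = "a")
  shift <- c(a = 16, b = 8, c = 0)
  v <- setNames(rnorm(n, 100, 5) + shift[map[magic_founders()[g]]],
                names(g))
  res <- allele_class_test(v, g, map)
  expect_equal(res$classes$class, c("a", "b", "c"))
  expect_equal(length(unique(res$classes$letter)), 3L)
  expect_lt(res$omnibus$p, 1e-6)

  # unmapped founder errors
  expect_error(allele_class_test(v, g, map[-1]), "not mapped")
})

test_that("extreme-haplotype contrasts are symmetric and null-safe", {
  set.seed(74)
  n <- 80
  g <- setNames(rep(1:8, each = 10), sprintf("L%03d", 1:n))
  v <- setNames(rnorm(n, 50, 5), names(g))
  tv <- list(PW = v)
  a <- contrast_extremes(tv, g, top_set = c("AK", "BE"),
                         bottom_set = c("HO", "RU"))
  b <- contrast_extremes(tv, g, top_set = c("HO", "RU"),
                         bottom_set = c("AK", "BE"))
  expect_equal(a$ratio, 1 / b$ratio, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # identical groups: ratio 1, p = 1
  same <- contrast_extremes(tv, g, top_set = "AK", bottom_set = "AK")
  expect_equal(same$ratio, 1)
  expect_gt(same$p, 0.99)

  expect_error(contrast_extremes(tv, g, character(), "AK"), "non-empty")
})

test_that("effect_profile assembles per-QTL, per-year time courses", {
  panel <- tiny_panel(30, 1, 10e6, seed = 75)
  haps <- simulate_magic_population(120, panel, seed = 76)
  spec <- qtl_effect_spec(panel$snp_id[15], c(RU = 10))
  tr <- simulate_traits(haps, list(spec), noise_sd = 5, seed = 77)
  qtls <- data.frame(name = "qCH1", chrom = 1, rep_snp = panel$snp_id[15],
                     stringsAsFactors = FALSE)
  eff <- effect_profile(tr, haps, qtls)
  expect_true(all(eff$profile$n >= 4))
  expect_setequal(unique(eff$profile$year), c("2019", "2018"))
  expect_equal(nrow(eff$quadratic),
               nrow(unique(eff$profile[c("haplotype", "year")])))
  # the RU class mean at a heading DAT sits ~10 cm over the others
  p83 <- eff$profile[eff$profile$year == "2019" & eff$profile$dat == 83, ]
  expect_gt(p83$mean[p83$haplotype == "RU"] -
              mean(p83$mean[p83$haplotype != "RU"]), 6)
})
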