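test_that("mosaic simulator honours its limits and is deterministic", {
  panel <- tiny_panel()
  one <- simulate_magic_population(1, panel, recomb_rate = 0, seed = 1)
  expect_length(unique(as.vector(one[, panel$chrom == 1])), 1L)
  # rate 0 still allows different founders on different chromosomes
  expect_true(all(!is.na(one)))

  a <- simulate_magic_population(20, panel, seed = 42)
  b <- simulate_magic_population(20, panel, seed = 42)
  expect_identical(a, b)
  c <- simulate_magic_population(20, panel, seed = 43)
  expect_false(identical(a, c))

  expect_error(simulate_magic_population(5, data.frame(), seed = 1),
               "panel")
})

test_that("founder frequencies converge to the configured distribution", {
  panel <- simulate_snp_panel(500, 5, 30e6, seed = 3)
  haps <- simulate_magic_population(165, panel, seed = 4)
  seg <- hap_segments(haps, panel)
  w <- seg$lengths / sum(seg$lengths)
  # genome-wide label frequency is a length-weighted mean of iid segment
  # labels; its standard error uses the effective weight sum
  se <- sqrt(1 / 8 * 7 / 8 * sum(w^2))
  for (f in 1:8) {
    freq <- sum(w[seg$labels == f])
    expect_lt(abs(freq - 1 / 8), 3 * se)
  }
})

test_that("missing-label simulation hits the configured rate", {
  panel <- tiny_panel()
  haps <- simulate_magic_population(100, panel, missing_rate = 0.1,
                                    seed = 9)
  expect_gt(mean(is.na(haps)), 0.07)
  expect_lt(mean(is.na(haps)), 0.13)
})

test_that("trait simulator reproduces the planted architecture exactly at zero noise", {
  panel <- tiny_panel()
  haps <- simulate_magic_population(60, panel, seed = 5)
  null_tr <- simulate_traits(haps, noise_sd = 0,
                             endpoint_noise_sd = c(CL = 0, PL = 0, PN = 0,
                                                   PW = 0, SLW = 0, SDW = 0),
                             seed = 6)
  ch83 <- trait_slice(null_tr, "CH", "2019", 83)
  expect_equal(unname(ch83), rep(ch_baseline(83), 60))

  spec <- qtl_effect_spec(panel$snp_id[10], c(RU = 10), stages = "heading")
  tr <- simulate_traits(haps, list(spec), noise_sd = 0,
                        endpoint_noise_sd = c(CL = 0, PL = 0, PN = 0,
                                              PW = 0, SLW = 0, SDW = 0),
                        seed = 6)
  g <- haps[, panel$snp_id[10]]
  ch83 <- trait_slice(tr, "CH", "2019", 83)   # heading DAT
  ch40 <- trait_slice(tr, "CH", "2019", 40)   # tillering DAT
  expect_equal(mean(ch83[g == 8]) - mean(ch83[g != 8]), 10)
  expect_equal(mean(ch40[g == 8]) - mean(ch40[g != 8]), 0)
})

test_that("planted heading effect shows in class means at realistic noise", {
  panel <- tiny_panel()
  haps <- simulate_magic_population(165, panel, seed = 7)
  spec <- qtl_effect_spec(panel$snp_id[10], c(RU = 10), stages = "heading")
  tr <- simulate_traits(haps, list(spec), noise_sd = 5, seed = 8)
  g <- haps[, panel$snp_id[10]]
  ch83 <- trait_slice(tr, "CH", "2019", 83)
  ch40 <- trait_slice(tr, "CH", "2019", 40)
  d_heading <- mean(ch83[g == 8]) - mean(ch83[g != 8])
  d_tillering <- mean(ch40[g == 8]) - mean(ch40[g != 8])
  expect_gt(d_heading, 6)
  expect_lt(abs(d_tillering), 4)
})

test_that("trait table invariants hold", {
  panel <- tiny_panel()
  haps <- simulate_magic_population(30, panel, seed = 10)
  tr <- simulate_traits(haps, noise_sd = 5, seed = 11)
  for (year in c("2019", "2018")) {
    tw <- trait_slice(tr, "TW", year)
    pw <- trait_slice(tr, "PW", year)
    slw <- trait_slice(tr, "SLW", year)
    expect_equal(tw, pw + slw)
    pn <- trait_slice(tr, "PN", year)
    expect_true(all(pn >= 0 & pn == round(pn)))
  }
  vf <- tr$value[tr$trait == "VF"]
  expect_true(all(vf >= 0 & vf <= 100))
  expect_error(
    simulate_traits(haps, list(qtl_effect_spec("nope", c(RU = 1))),
                    seed = 1),
    "not in panel")
})

test_that("scene renderer matches requested VF, CH and determinism", {
  layout <- data.frame(plot_id = c("A", "B", "C"),
                       x0 = c(0, 210, 420), y0 = 0,
                       x1 = c(200, 410, 620), y1 = 200)
  vals <- data.frame(plot_id = c("A", "B", "C"), ch_m = c(0.5, 0.8, 0.3),
                     vf_pct = c(0, 100, 50), minus_a_star = 35)
  sc <- render_scene(vals, layout, seed = 21)
  m_a <- sc$truth_mask[1:200, 1:200]
  m_b <- sc$truth_mask[1:200, 211:410]
  m_c <- sc$truth_mask[1:200, 421:620]
  expect_equal(sum(m_a), 0L)
  expect_true(all(m_b))
  expect_lt(abs(100 * mean(m_c) - 50), 2)
  # full-canopy plot elevated exactly by CH over flat baseline
  expect_equal(unique(as.vector(round(sc$dsm[1:200, 211:410] -
                                        sc$baseline_dsm[1:200, 211:410],
                                      10))), 0.8)
  sc2 <- render_scene(vals, layout, seed = 21)
  expect_identical(sc$rgb, sc2$rgb)
  expect_identical(sc$dsm, sc2$dsm)

  vals$vf_pct[1] <- 101
  expect_error(render_scene(vals, layout, seed = 1), "VF")
})
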