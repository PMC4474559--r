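test_that("range difference and ratio use only the two extremes", {
  expect_equal(range_difference(c(60.7, 80.1)), 19.4)
  expect_equal(range_difference(c(65, 65, 65)), 0)
  expect_equal(range_difference(c(50, 60, 70)), 20)

  expect_equal(range_ratio(c(65, 65)), 1)
  # frozen from an independent one-line division: 80.1 / 60.7
  expect_equal(range_ratio(c(60.7, 80.1)), 1.31960461285008, tolerance = 1e-12)
  expect_equal(range_ratio(c(50, 60, 70) * 3.7), range_ratio(c(50, 60, 70)),
               tolerance = 1e-12)
  expect_error(range_ratio(c(-1, 60)), "positive")
  expect_error(range_difference(numeric(0)), "empty")
})

test_that("mean difference from best supports both denominator conventions", {
  expect_equal(mean_difference_from_best(c(70, 68, 64)), 8 / 3,
               tolerance = 1e-12)
  expect_equal(mean_difference_from_best(c(70, 68, 64), mode = "n-1"), 4)
  expect_equal(mean_difference_from_best(c(65, 65)), 0)
  expect_equal(mean_difference_from_best(62.1), 0)  # degenerate slice
})

test_that("index of disparity is MD as a percentage of the reference", {
  # frozen: 100 * (8/3) / 70, cross-checked against the loop oracle
  expect_equal(index_of_disparity(c(70, 68, 64)), 3.80952380952381,
               tolerance = 1e-12)
  expect_equal(index_of_disparity(c(70, 68, 64)), o_id(c(70, 68, 64)),
               tolerance = 1e-14)
  expect_equal(index_of_disparity(c(65, 65, 65)), 0)
  expect_equal(index_of_disparity(c(70, 68, 64) * 2.5),
               index_of_disparity(c(70, 68, 64)), tolerance = 1e-12)
})

test_that("between-group variance matches hand and expansion oracles", {
  expect_equal(between_group_variance(c(60, 70), c(1, 1)), 25)
  expect_equal(between_group_variance(c(65, 65, 65), c(3, 1, 9)), 0)
  # hand arithmetic: mu = 62.5, 0.75*6.25 + 0.25*56.25 = 18.75
  expect_equal(between_group_variance(c(60, 70), c(3, 1)), 18.75)
  expect_equal(o_bgv_expand(c(60, 70), c(3, 1)), 18.75)
  expect_error(between_group_variance(c(60, 70), 1), "length")
  expect_error(between_group_variance(c(60, 70), c(0, 0)), "positive total")
})

test_that("Theil, MLD and the symmetric index follow the entropy formulas", {
  eq <- symmetric_theil(c(65, 65, 65), c(1, 5, 2))
  expect_equal(eq$theil, 0, tolerance = 1e-15)
  expect_equal(eq$mld, 0, tolerance = 1e-15)
  expect_equal(eq$sti, 0, tolerance = 1e-12)

  # frozen from an independent high-precision summation (equal shares,
  # mu = 65): T = sum p r log r, MLD = sum p log(1/r)
  st <- symmetric_theil(c(60, 70), c(1, 1), scale = 1)
  expect_equal(st$theil, 0.00296150454114112, tolerance = 1e-12)
  expect_equal(st$mld, 0.00296736775990725, tolerance = 1e-12)
  expect_equal(st$sti, 0.00296443615052419, tolerance = 1e-12)

  # the reporting multiplier scales only the STI
  st1000 <- symmetric_theil(c(60, 70), c(1, 1), scale = 1000)
  expect_equal(st1000$sti, 1000 * st$sti, tolerance = 1e-12)
  expect_equal(st1000$theil, st$theil)

  expect_error(symmetric_theil(c(-60, 70), c(1, 1)), "positive")
})

test_that("BGV approaches 2 mu^2 times the unscaled STI as dispersion shrinks", {
  set.seed(99)
  base <- runif(6, 60, 70)
  pop <- rlnorm(6, 12, 1)
  mu0 <- sum(pop * base) / sum(pop)
  rel_err <- sapply(c(1, 0.1, 0.01, 0.001), function(eps) {
    le <- mu0 + eps * (base - mu0)
    bgv <- between_group_variance(le, pop)
    sti <- symmetric_theil(le, pop, scale = 1)$sti
    mu <- sum(pop * le) / sum(pop)
    abs(bgv - 2 * mu^2 * sti) / bgv
  })
  expect_true(all(diff(rel_err) < 0))  # error shrinks with dispersion
  expect_lt(rel_err[4], 1e-4)
})

test_that("the suite computes all six metrics on one slice with reference metadata", {
  sl_le <- c(64, 70, 68)
  sl_pop <- c(5, 2, 3)
  p <- toy_panel(sl_le, sl_pop)
  suite <- disparity_suite(p, panel_region(p), "1965-1970", "both",
                           sti_scale = 1000)
  expect_equal(suite$n_countries, 3L)
  expect_equal(suite$led, o_led(sl_le), tolerance = 1e-12)
  expect_equal(suite$ler, o_ler(sl_le), tolerance = 1e-12)
  expect_equal(suite$md, o_md(sl_le), tolerance = 1e-12)
  expect_equal(suite$id_pct, o_id(sl_le), tolerance = 1e-12)
  expect_equal(suite$bgv, o_bgv(sl_le, sl_pop), tolerance = 1e-12)
  expect_equal(suite$sti, o_sti(sl_le, sl_pop, 1000), tolerance = 1e-12)
  expect_equal(suite$reference_country, "C02")
  expect_equal(suite$weighted_mean, o_weighted_mean(sl_le, sl_pop),
               tolerance = 1e-12)

  # single-country slice degenerates to the equality values
  solo <- toy_panel(62.1)
  s1 <- disparity_suite(solo, panel_region(solo), "1965-1970", "both")
  expect_equal(s1$n_countries, 1L)
  expect_equal(c(s1$led, s1$md, s1$id_pct, s1$bgv, s1$sti), rep(0, 5))
  expect_equal(s1$ler, 1)

  # ties for the reference are broken lexicographically, with a message
  tie <- toy_panel(c(70, 70, 60), ids = c("CB", "CA", "CC"))
  expect_message(st <- disparity_suite(tie, panel_region(tie),
                                       "1965-1970", "both"), "tie")
  expect_equal(st$reference_country, "CA")
})

test_that("metric scale, translation and weighting behaviour is as expected", {
  set.seed(404)
  for (i in 1:15) {
    sl <- random_slice()
    c_mult <- runif(1, 0.5, 1.4)  # keeps rescaled LE inside the panel domain
    shift <- runif(1, 1, 10)
    p0 <- toy_panel(sl$le, sl$pop)
    r <- panel_region(p0)
    s0 <- disparity_suite(p0, r, "1965-1970", "both", sti_scale = 1)
    s_scaled <- disparity_suite(toy_panel(sl$le * c_mult, sl$pop), r,
                                "1965-1970", "both", sti_scale = 1)
    # relative metrics invariant under rescaling; absolute metrics scale
    expect_equal(s_scaled$ler, s0$ler, tolerance = 1e-10)
    expect_equal(s_scaled$id_pct, s0$id_pct, tolerance = 1e-10)
    expect_equal(s_scaled$theil, s0$theil, tolerance = 1e-10)
    expect_equal(s_scaled$mld, s0$mld, tolerance = 1e-10)
    expect_equal(s_scaled$sti, s0$sti, tolerance = 1e-10)
    expect_equal(s_scaled$led, c_mult * s0$led, tolerance = 1e-10)
    expect_equal(s_scaled$md, c_mult * s0$md, tolerance = 1e-10)
    expect_equal(s_scaled$bgv, c_mult^2 * s0$bgv, tolerance = 1e-10)

    s_shift <- disparity_suite(toy_panel(sl$le + shift, sl$pop), r,
                               "1965-1970", "both", sti_scale = 1)
    # absolute metrics are translation invariant; relative ones decrease
    expect_equal(s_shift$led, s0$led, tolerance = 1e-10)
    expect_equal(s_shift$md, s0$md, tolerance = 1e-10)
    expect_equal(s_shift$bgv, s0$bgv, tolerance = 1e-10)
    if (s0$led > 0) {
      expect_lt(s_shift$ler, s0$ler)
      expect_lt(s_shift$id_pct, s0$id_pct)
      expect_lt(s_shift$sti, s0$sti)
    }

    # LED/LER/MD/ID ignore weights; BGV/STI invariant to weight rescaling
    s_w <- disparity_suite(toy_panel(sl$le, rev(sl$pop) * 17), r,
                           "1965-1970", "both", sti_scale = 1)
    expect_equal(s_w$led, s0$led)
    expect_equal(s_w$ler, s0$ler)
    expect_equal(s_w$md, s0$md)
    expect_equal(s_w$id_pct, s0$id_pct)
    s_w2 <- disparity_suite(toy_panel(sl$le, sl$pop * 17), r,
                            "1965-1970", "both", sti_scale = 1)
    expect_equal(s_w2$bgv, s0$bgv, tolerance = 1e-10)
    expect_equal(s_w2$sti, s0$sti, tolerance = 1e-10)
  }
})

test_that("percent change reproduces reported trend cells", {
  expect_equal(fmt2(percent_change(1.55, 1.33)), "-14.19")
  expect_equal(fmt2(percent_change(52.41, 5.43)), "-89.64")
  expect_equal(percent_change(3.7, 3.7), 0)
  expect_error(percent_change(0, 5), "zero baseline")
})

test_that("averaged reductions are the means of their three components", {
  avg <- average_reduction(c(ler = -13.73, led = -20.6, md = -6.02,
                             id_pct = -16.94, sti = -39.66, bgv = -15.09))
  expect_equal(avg$avg_absolute, mean(c(-20.6, -6.02, -15.09)),
               tolerance = 1e-12)
  expect_equal(avg$avg_relative, mean(c(-13.73, -16.94, -39.66)),
               tolerance = 1e-12)
  z <- average_reduction(c(ler = 0, led = 0, md = 0, id = 0, sti = 0,
                           bgv = 0))
  expect_equal(c(z$avg_absolute, z$avg_relative), c(0, 0))
  expect_error(average_reduction(c(ler = -1, led = -2)), "missing per-metric")
})

test_that("suite_change composes per-metric changes and their averages", {
  p <- generate_panel(generator_config(n_countries = 6, seed = 31))
  r <- panel_region(p)
  s1 <- disparity_suite(p, r, "1965-1970", "both")
  s2 <- disparity_suite(p, r, "2005-2010", "both")
  ch <- suite_change(s1, s2)
  for (m in c("ler", "led", "md", "id_pct", "sti", "bgv")) {
    expect_equal(ch[[m]], percent_change(s1[[m]], s2[[m]]),
                 tolerance = 1e-12)
  }
  expect_equal(ch$avg_absolute, mean(c(ch$led, ch$md, ch$bgv)),
               tolerance = 1e-12)
  expect_equal(ch$avg_relative, mean(c(ch$ler, ch$id_pct, ch$sti)),
               tolerance = 1e-12)

  # equality in both periods is an unchanged trend, not undefined
  eqp <- generate_equality_panel(4, c("1965-1970", "2005-2010"))
  re <- panel_region(eqp)
  che <- suite_change(disparity_suite(eqp, re, "1965-1970", "both"),
                      disparity_suite(eqp, re, "2005-2010", "both"))
  expect_equal(unlist(che[c("ler", "led", "md", "id_pct", "sti", "bgv")]),
               setNames(rep(0, 6), c("ler", "led", "md", "id_pct", "sti",
                                     "bgv")))
})
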