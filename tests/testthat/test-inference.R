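test_that("the placebo ensemble has one fit per unit and isolates the treated unit", {
  study <- tiny_study(seed = 17, n_donors = 6)
  ens <- run_placebos(study$panel, "T01", study$donors, "2017-06",
                      v_method = "equal")
  expect_equal(ens$n_units, 7)
  expect_equal(nrow(ens$ratios), 7)
  expect_equal(sum(ens$ratios$is_treated), 1)
  # the true treated unit never appears in a placebo's donor pool
  for (f in ens$placebo_fits) {
    expect_false("T01" %in% f$donors)
    expect_equal(length(f$donors), 5)
  }
  expect_true(all(is.finite(ens$ratios$ratio)))
  expect_true(all(ens$ratios$rmspe_pre > 0))
})

test_that("two donors force unit placebo weights", {
  study <- tiny_study(seed = 19, n_donors = 2)
  ens <- run_placebos(study$panel, "T01", study$donors, "2017-06",
                      v_method = "equal")
  for (f in ens$placebo_fits) {
    expect_equal(nrow(f$weights), 1)
    expect_equal(f$weights$weight, 1)
  }
})

test_that("ranking p-values count strictly larger ratios, ties conservative", {
  make_ens <- function(ratios, treated_idx = 1) {
    structure(list(
      ratios = tibble::tibble(
        unit = paste0("u", seq_along(ratios)),
        is_treated = seq_along(ratios) == treated_idx,
        rmspe_pre = 1, rmspe_post = ratios, ratio = ratios
      )
    ), class = "placebo_ensemble")
  }
  top <- rank_p_value(make_ens(c(9, rep(1, 25))))
  expect_equal(top$rank, 1L)
  expect_equal(top$p_value, 1 / 26)

  bottom <- rank_p_value(make_ens(c(0.1, seq(1, 2, length.out = 11))))
  expect_equal(bottom$p_value, 1)

  tied <- rank_p_value(make_ens(c(2, 2, 1, 1)))
  expect_equal(tied$rank, 1L)  # strictly larger only

  withr::with_seed(3, {
    for (r in 1:10) {
      ratios <- round(runif(12, 0.5, 3), 2)
      pv <- rank_p_value(make_ens(ratios, treated_idx = 4))
      oracle <- (1 + sum(ratios[-4] > ratios[4])) / 12
      expect_equal(pv$p_value, oracle)
      # granularity: always a multiple of 1/n
      expect_equal(pv$p_value * 12, round(pv$p_value * 12))
    }
  })
})

test_that("p-values are invariant to donor input order", {
  study <- tiny_study(seed = 23, n_donors = 6)
  ens1 <- run_placebos(study$panel, "T01", study$donors, "2017-06",
                       v_method = "equal")
  ens2 <- run_placebos(study$panel, "T01", rev(study$donors), "2017-06",
                       v_method = "equal")
  expect_equal(rank_p_value(ens1), rank_p_value(ens2))
  r1 <- dplyr::arrange(ens1$ratios, unit)
  r2 <- dplyr::arrange(ens2$ratios, unit)
  expect_equal(r1$ratio, r2$ratio, tolerance = 1e-5)
})

test_that("the optional pre-fit filter drops poorly fitting placebos", {
  ratios <- tibble::tibble(
    unit = c("t", "good", "bad"),
    is_treated = c(TRUE, FALSE, FALSE),
    rmspe_pre = c(1, 2, 10),
    rmspe_post = c(5, 2, 30),
    ratio = c(5, 1, 3)
  )
  ens <- structure(list(ratios = ratios), class = "placebo_ensemble")
  expect_equal(rank_p_value(ens)$n_units, 3)
  filtered <- rank_p_value(ens, filter_ratio = 5)
  expect_equal(filtered$n_units, 2)
})

test_that("the fit gate passes perfect fits and fails poor relative fits", {
  fake_fit <- function(rmspe_pre, pre_mean = 10) {
    structure(list(
      rmspe_pre = rmspe_pre,
      series = tibble::tibble(
        observed = rep(pre_mean, 10), period = rep("pre", 10)
      )
    ), class = "scm_fit")
  }
  perfect <- fit_gate(fake_fit(0))
  expect_true(perfect$interpretable)

  poor <- fit_gate(fake_fit(5))  # 50% of the pre-period mean rate
  expect_false(poor$interpretable)
  expect_true("tau1" %in% poor$reasons[[1]])

  # placebo-relative test
  ens <- structure(list(placebo_fits = list(
    a = list(rmspe_pre = 0.1), b = list(rmspe_pre = 0.2), c = list(rmspe_pre = 0.3)
  )), class = "placebo_ensemble")
  rel <- fit_gate(fake_fit(0.9), ens)
  expect_false(rel$interpretable)
  expect_true("tau2" %in% rel$reasons[[1]])
})

test_that("yearly effects follow their arithmetic definitions", {
  fake_fit <- function(gaps, synth) {
    n <- length(gaps)
    structure(list(series = tibble::tibble(
      month = seq(as.Date("2018-01-01"), by = "month", length.out = n),
      observed = synth + gaps, synthetic = synth, gap = gaps,
      period = rep("post", n)
    )), class = "scm_fit")
  }
  zero <- yearly_effects(fake_fit(rep(0, 24), rep(10, 24)))
  expect_equal(zero$effect, c(0, 0))
  expect_equal(zero$percent_change, c(0, 0))

  const <- yearly_effects(fake_fit(rep(-1, 12), rep(20, 12)))
  expect_equal(const$effect, -12)
  expect_equal(const$percent_change, -5)
  expect_equal(const$ci_low, -12)  # no monthly variation
  expect_equal(const$ci_high, -12)

  withr::with_seed(11, {
    gaps <- rnorm(30)
  })
  ye <- yearly_effects(fake_fit(gaps, rep(15, 30)))
  expect_equal(ye$n_months, c(12, 12, 6))  # truncated final year annotated
  expect_equal(sum(ye$effect), sum(gaps))  # additivity
  expect_equal(ye$effect[1], sum(gaps[1:12]))
  half <- qnorm(0.975) * sqrt(12) * sd(gaps[1:12])
  expect_equal(ye$ci_high[1] - ye$effect[1], half, tolerance = 1e-6)
})

test_that("placebo-quantile intervals report the placebo null band", {
  study <- tiny_study(seed = 29, n_donors = 6)
  ens <- run_placebos(study$panel, "T01", study$donors, "2017-06",
                      v_method = "equal")
  ye <- yearly_effects(ens$treated_fit, method = "placebo", ensemble = ens)
  placebo_effects <- purrr::map(ens$placebo_fits, function(f) {
    post <- f$series$gap[f$series$period == "post"]
    sum(post[1:12])
  })
  expect_equal(ye$ci_low[1],
               unname(quantile(unlist(placebo_effects), 0.025)))
})

test_that("ensemble summaries and exports work", {
  study <- tiny_study(seed = 37, n_donors = 5)
  ens <- run_placebos(study$panel, "T01", study$donors, "2017-06",
                      v_method = "equal")
  td <- tidy(ens)
  expect_equal(nrow(td), 6)
  expect_equal(td$rank, sort(td$rank))
  gl <- glance(ens)
  expect_equal(gl$n_units, 6)
  expect_s3_class(autoplot(ens), "ggplot")
  paths <- write_placebo_ensemble(ens, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
})
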