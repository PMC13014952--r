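test_that("predictor matrices match a naive loop construction", {
  study <- tiny_study(seed = 13, n_donors = 5)
  treated <- "T01"
  donors <- study$donors
  pre <- c("2015-01", "2017-05")
  spec <- predictor_spec(covariates = c("cov_1", "cov_2"), lags = "thirds")
  mats <- build_predictors(study$panel, treated, donors, pre,
                           covariates = study$covariates, spec = spec)

  # independent construction: loop over units and months
  units <- c(treated, donors)
  months <- month_seq(pre[1], pre[2])
  raw <- matrix(NA_real_, length(units), 5,
                dimnames = list(units, NULL))
  thirds <- split(months, cut(seq_along(months), 3, labels = FALSE))
  for (u in units) {
    rates <- vapply(months, function(m) {
      study$panel$rate[study$panel$state == u & study$panel$month == m]
    }, numeric(1))
    raw[u, 1:3] <- vapply(thirds, function(ms) {
      mean(rates[months %in% ms])
    }, numeric(1))
    for (ci in 1:2) {
      vals <- vapply(months, function(m) {
        y <- lubridate::year(m)
        study$covariates[[paste0("cov_", ci)]][
          study$covariates$state == u & study$covariates$year == y
        ]
      }, numeric(1))
      raw[u, 3 + ci] <- mean(vals)
    }
  }
  std <- scale(raw)
  expect_equal(unname(mats$X1), unname(std[treated, ]), tolerance = 1e-12)
  expect_equal(unname(mats$X0), unname(t(std[donors, ])), tolerance = 1e-12)
  expect_equal(length(mats$Z1), length(months))
  expect_equal(dim(mats$Z0), c(length(months), length(donors)))
})

test_that("an identical treated and donor give identical predictor columns", {
  panel <- as_state_month_panel(tibble::tibble(
    state = rep(c("A", "B", "C"), each = 6),
    month = rep(month_seq("2015-01", "2015-06"), 3),
    rate = c(1:6, 1:6, c(2, 4, 1, 7, 3, 5))
  ))
  mats <- build_predictors(panel, "A", c("B", "C"), c("2015-01", "2015-06"))
  expect_equal(unname(mats$X1), unname(mats$X0[, 1]))
})

test_that("zero-variance predictors are dropped with a warning", {
  panel <- as_state_month_panel(tibble::tibble(
    state = rep(c("A", "B", "C"), each = 6),
    month = rep(month_seq("2015-01", "2015-06"), 3),
    rate = c(1:6, 2:7, c(2, 4, 1, 7, 3, 5))
  ))
  covs <- tibble::tibble(state = c("A", "B", "C"), year = 2015, flat = 1)
  expect_warning(
    mats <- build_predictors(panel, "A", c("B", "C"), c("2015-01", "2015-06"),
                             covariates = covs,
                             spec = predictor_spec(covariates = "flat")),
    "zero-variance"
  )
  expect_false(any(grepl("flat", mats$predictors)))
})

test_that("importance optimization is forced with one predictor and exact with a twin donor", {
  study <- tiny_study(seed = 21, n_donors = 4)
  mats <- build_predictors(study$panel, "T01", study$donors,
                           c("2015-01", "2017-12"),
                           spec = predictor_spec(lags = list(month_seq("2015-01", "2017-12"))))
  expect_equal(length(mats$X1), 1)
  opt <- optimize_importance(mats)
  expect_equal(unname(opt$v), 1)

  # a donor that replicates the treated unit in X and Z gives zero MSPE
  Y <- panel_matrix(study$panel)
  twin <- study$panel
  twin$rate[twin$state == "D01"] <- Y["T01", ]
  twin <- as_state_month_panel(twin)
  mats2 <- build_predictors(twin, "T01", study$donors, c("2015-01", "2017-12"))
  opt2 <- optimize_importance(mats2, n_starts = 3)
  expect_lt(opt2$mspe, 1e-12)
  expect_equal(unname(opt2$w[1]), 1, tolerance = 1e-6)
})

test_that("optimized importances beat a coarse grid and the equal baseline", {
  withr::with_seed(55, {
    for (r in 1:3) {
      k <- 2
      J <- 3
      T0 <- 12
      X0 <- matrix(rnorm(k * J), k, J)
      X1 <- rnorm(k)
      Z0 <- matrix(rnorm(T0 * J), T0, J)
      Z1 <- drop(Z0 %*% c(0.5, 0.3, 0.2)) + rnorm(T0, sd = 0.1)
      mats <- structure(list(X1 = X1, X0 = X0, Z1 = Z1, Z0 = Z0,
                             predictors = c("p1", "p2")),
                        class = "scm_predictors")
      opt <- optimize_importance(mats, n_starts = 6, seed = r)
      expect_lte(opt$mspe, opt$mspe_equal + 1e-12)

      vgrid <- seq(0.01, 0.99, by = 0.01)
      grid_best <- min(vapply(vgrid, function(v1) {
        w <- solve_inner_weights(X1, X0, c(v1, 1 - v1))
        mean((Z1 - drop(Z0 %*% w))^2)
      }, numeric(1)))
      expect_lte(opt$mspe, grid_best + 1e-3)
    }
  })
})

test_that("the synthetic series is the weighted donor average", {
  Y <- rbind(d1 = rep(2, 5), d2 = rep(4, 5), d3 = 1:5)
  expect_equal(unname(synthetic_series(c(d3 = 1), Y["d3", , drop = FALSE])),
               1:5, ignore_attr = TRUE)
  expect_equal(unname(synthetic_series(c(d1 = 0.5, d2 = 0.5), Y[1:2, ])),
               rep(3, 5))
  withr::with_seed(6, {
    w <- runif(3)
    w <- w / sum(w)
    names(w) <- rownames(Y)
    naive <- vapply(1:5, function(t) sum(w * Y[, t]), numeric(1))
    expect_equal(unname(synthetic_series(w, Y)), naive)
  })
})

test_that("gap and RMSPE follow their definitions", {
  months <- month_seq("2015-01", "2015-06")
  same <- gap_and_rmspe(1:6, 1:6, months, "2015-04")
  expect_equal(same$gap$gap, rep(0, 6))
  expect_equal(same$rmspe_pre, 0)
  expect_equal(same$rmspe_post, 0)

  gr <- gap_and_rmspe(c(0, 0, 0, 0, 3, 4), rep(0, 6), months, "2015-05")
  expect_equal(gr$rmspe_post, sqrt(12.5))
  expect_equal(gr$rmspe_pre, 0)

  withr::with_seed(77, {
    obs <- rnorm(6)
    syn <- rnorm(6)
  })
  gr2 <- gap_and_rmspe(obs, syn, months, "2015-04")
  g <- obs - syn
  expect_equal(gr2$rmspe_pre, sqrt(mean(g[1:3]^2)))
  expect_equal(gr2$rmspe_post, sqrt(mean(g[4:6]^2)))

  expect_error(gap_and_rmspe(1:6, 1:6, months, "2015-01"), "non-empty")
})

test_that("the synthetic series stays inside the donor convex hull", {
  study <- tiny_study(seed = 31, n_donors = 6)
  fit <- scm_fit(study$panel, "T01", study$donors, "2017-06", v_method = "equal")
  Y <- panel_matrix(study$panel)[study$donors, ]
  lo <- apply(Y, 2, min)
  hi <- apply(Y, 2, max)
  expect_true(all(fit$series$synthetic >= lo - 1e-9))
  expect_true(all(fit$series$synthetic <= hi + 1e-9))
})

test_that("fits are reproducible and tidiable", {
  study <- tiny_study(seed = 8, n_donors = 5)
  f1 <- scm_fit(study$panel, "T01", study$donors, "2017-06",
                covariates = study$covariates,
                spec = predictor_spec(covariates = "cov_1"),
                n_starts = 3, seed = 99)
  f2 <- scm_fit(study$panel, "T01", study$donors, "2017-06",
                covariates = study$covariates,
                spec = predictor_spec(covariates = "cov_1"),
                n_starts = 3, seed = 99)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$importance, f2$importance)

  td <- tidy(f1)
  expect_equal(sum(td$weight), 1, tolerance = 1e-8)
  gl <- glance(f1)
  expect_equal(gl$treated, "T01")
  expect_s3_class(autoplot(f1), "ggplot")

  paths <- write_scm_fit(f1, withr::local_tempdir())
  expect_true(all(file.exists(paths)))
})
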