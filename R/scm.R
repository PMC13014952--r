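#' Optimize predictor importance weights
#'
#' Outer loop of the nested synthetic-control optimization: chooses the
#' predictor-importance vector `V` (non-negative, summing to one) so that the
#' donor weights it induces, `W(V)` from the inner solve, minimize the
#' pre-period outcome mean squared prediction error
#' `||Z1 - Z0 W(V)||^2 / T0`. The search runs over a softmax
#' parameterization of the simplex with multiple seeded starts (an
#' equal-importance start plus random restarts), so the optimized fit is
#' never worse than the equal-importance baseline and results are
#' reproducible given the seed.
#'
#' @param matrices An `scm_predictors` object from [build_predictors()].
#' @param n_starts Number of starts (first is always equal importance).
#' @param seed Integer seed for the random restarts.
#' @param maxit,reltol Control parameters for each Nelder-Mead start.
#' @return List with `v` (importance vector, named), `w` (donor weights at
#'   the optimum), `mspe` (attained pre-period MSPE), `mspe_equal` (the
#'   equal-importance baseline), and `converged`.
#' @export
optimize_importance <- function(matrices, n_starts = 10, seed = 1,
                                maxit = 500, reltol = 1e-8) {
  X1 <- matrices$X1
  X0 <- matrices$X0
  Z1 <- matrices$Z1
  Z0 <- matrices$Z0
  k <- length(X1)
  T0 <- length(Z1)

  pre_mspe <- function(w) mean((Z1 - drop(Z0 %*% w))^2)
  eval_v <- function(v) {
    w <- solve_inner_weights(X1, X0, v)
    list(v = v, w = w, mspe = pre_mspe(w))
  }

  equal <- eval_v(rep(1 / k, k))
  if (k == 1L) {
    return(list(
      v = setNames(1, matrices$predictors), w = equal$w, mspe = equal$mspe,
      mspe_equal = equal$mspe, converged = TRUE
    ))
  }

  softmax <- function(theta) {
    e <- exp(theta - max(theta))
    e / sum(e)
  }
  obj <- function(theta) eval_v(softmax(theta))$mspe

  starts <- local_seed(seed, {
    c(
      list(rep(0, k)),
      purrr::map(seq_len(max(n_starts - 1, 0)), function(i) rnorm(k, sd = 1.5))
    )
  })

  best <- equal
  converged <- FALSE
  for (theta0 in starts) {
    fit <- tryCatch(
      optim(theta0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cand <- eval_v(softmax(fit$par))
    if (fit$convergence == 0) converged <- TRUE
    if (cand$mspe < best$mspe) best <- cand
  }

  v <- setNames(best$v, matrices$predictors)
  list(
    v = v, w = best$w, mspe = best$mspe, mspe_equal = equal$mspe,
    converged = converged || best$mspe <= equal$mspe
  )
}

#' Weighted donor (synthetic) outcome series
#'
#' Extends the fitted donor weights across the full study window:
#' `yhat_t = sum_j W_j y_jt` for every month, pre and post.
#'
#' @param w Named donor weight vector.
#' @param donor_outcomes Donor-by-month outcome matrix (rows named by donor,
#'   columns by month), e.g. `panel_matrix(panel)[donors, ]`.
#' @return Numeric series named by month.
#' @export
synthetic_series <- function(w, donor_outcomes) {
  if (!is.null(names(w)) && !is.null(rownames(donor_outcomes))) {
    if (!all(names(w) %in% rownames(donor_outcomes))) {
      abort("Weight names do not match donor outcome rows.")
    }
    donor_outcomes <- donor_outcomes[names(w), , drop = FALSE]
  }
  stopifnot(length(w) == nrow(donor_outcomes))
  drop(as.numeric(w) %*% donor_outcomes)
}

#' Gap series and pre/post RMSPE
#'
#' The gap is the observed minus synthetic outcome each month; the root mean
#' square prediction error summarizes it separately over the pre-policy
#' months (fit quality) and the post-policy months (divergence). The calendar
#' month containing the effective date is the first post month.
#'
#' @param observed,synthetic Equal-length outcome series.
#' @param months Month vector aligned with the series.
#' @param treatment_month First post-policy month.
#' @return List with `gap` (tibble: month, observed, synthetic, gap, period),
#'   `rmspe_pre`, `rmspe_post`.
#' @export
gap_and_rmspe <- function(observed, synthetic, months, treatment_month) {
  stopifnot(length(observed) == length(synthetic), length(observed) == length(months))
  months <- as_month(months)
  treatment_month <- as_month(treatment_month)
  is_post <- months >= treatment_month
  if (!any(is_post) || all(is_post)) {
    abort("Treatment month must leave non-empty pre and post periods.")
  }
  gap <- observed - synthetic
  list(
    gap = tibble::tibble(
      month = months,
      observed = as.numeric(observed),
      synthetic = as.numeric(synthetic),
      gap = as.numeric(gap),
      period = ifelse(is_post, "post", "pre")
    ),
    rmspe_pre = sqrt(mean(gap[!is_post]^2)),
    rmspe_post = sqrt(mean(gap[is_post]^2))
  )
}

#' Fit a synthetic control for one treated unit
#'
#' End-to-end single-unit fit: assembles predictors over the pre-policy
#' period, chooses predictor importances (nested optimization by default, or
#' fixed equal importance), solves for the simplex-constrained donor weights,
#' and extends the weighted donor average across the full window to produce
#' the synthetic series, gaps, and pre/post RMSPE.
#'
#' @param panel A `state_month_panel` of outcome rates (or an equivalent
#'   unit-by-month rate matrix with named rows).
#' @param treated Treated unit identifier.
#' @param donors Donor identifiers (the treated unit must not appear).
#' @param treatment_month First post-policy month (the calendar month
#'   containing the effective date).
#' @param covariates Optional covariate table; see [build_predictors()].
#' @param spec A [predictor_spec()].
#' @param v_method `"nested"` (default: optimize `V` for pre-period fit) or
#'   `"equal"` (fixed equal importance).
#' @param n_starts,seed,maxit Passed to [optimize_importance()] when nested.
#' @return An `scm_fit` object: donor weights, importances, the
#'   observed/synthetic/gap series, and pre/post RMSPE. Supports [tidy()]
#'   (weights), [glance()] (fit summary), and [autoplot()] (trajectory and
#'   gap plot).
#' @examples
#' study <- generate_panel(factor_config(n_treated = 1, n_donors = 8, seed = 3))
#' fit <- scm_fit(study$panel, treated = "T01", donors = study$donors,
#'                treatment_month = "2018-01", v_method = "equal")
#' glance(fit)
#' @export
scm_fit <- function(panel, treated, donors, treatment_month,
                    covariates = NULL, spec = predictor_spec(),
                    v_method = c("nested", "equal"),
                    n_starts = 10, seed = 1, maxit = 500) {
  v_method <- match.arg(v_method)
  if (treated %in% donors) {
    abort("The treated unit cannot be in its own donor pool.")
  }
  treatment_month <- as_month(treatment_month)
  Y <- panel_matrix(panel, "rate")
  months <- as_month(as.Date(paste0(colnames(Y), "-01")))
  pre_period <- c(months[[1]], as_month(treatment_month - 1))

  mats <- build_predictors(
    panel, treated, donors, pre_period,
    covariates = covariates, spec = spec
  )

  if (v_method == "nested") {
    opt <- optimize_importance(mats, n_starts = n_starts, seed = seed, maxit = maxit)
  } else {
    k <- length(mats$X1)
    w <- solve_inner_weights(mats$X1, mats$X0, rep(1 / k, k))
    mspe <- mean((mats$Z1 - drop(mats$Z0 %*% w))^2)
    opt <- list(
      v = setNames(rep(1 / k, k), mats$predictors), w = w,
      mspe = mspe, mspe_equal = mspe, converged = TRUE
    )
  }

  yhat <- synthetic_series(opt$w, Y[donors, , drop = FALSE])
  gr <- gap_and_rmspe(Y[treated, ], yhat, months, treatment_month)

  structure(
    list(
      treated = treated,
      donors = donors,
      treatment_month = treatment_month,
      weights = tibble::tibble(donor = donors, weight = as.numeric(opt$w)),
      importance = tibble::tibble(
        predictor = names(opt$v), importance = as.numeric(opt$v)
      ),
      series = gr$gap,
      rmspe_pre = gr$rmspe_pre,
      rmspe_post = gr$rmspe_post,
      pre_mspe = opt$mspe,
      pre_mspe_equal = opt$mspe_equal,
      v_method = v_method,
      converged = opt$converged
    ),
    class = "scm_fit"
  )
}

#' @export
print.scm_fit <- function(x, ...) {
  cat(sprintf(
    "<scm_fit> %s vs %d donors | post from %s | rmspe pre %.4g, post %.4g, ratio %.3g\n",
    x$treated, length(x$donors), format_month(x$treatment_month),
    x$rmspe_pre, x$rmspe_post, rmspe_ratio(x)
  ))
  top <- dplyr::slice_max(x$weights, .data$weight, n = 5)
  cat("Top donor weights:\n")
  print(as.data.frame(top), row.names = FALSE)
  invisible(x)
}

# Post/pre RMSPE ratio; Inf when the pre-period fit is exact.
rmspe_ratio <- function(fit) {
  if (fit$rmspe_pre == 0) {
    if (fit$rmspe_post == 0) 1 else Inf
  } else {
    fit$rmspe_post / fit$rmspe_pre
  }
}

#' @rdname scm_fit
#' @param x An `scm_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.scm_fit <- function(x, ...) {
  dplyr::arrange(x$weights, dplyr::desc(.data$weight))
}

#' @rdname scm_fit
#' @exportS3Method generics::glance
glance.scm_fit <- function(x, ...) {
  tibble::tibble(
    treated = x$treated,
    n_donors = length(x$donors),
    treatment_month = format_month(x$treatment_month),
    rmspe_pre = x$rmspe_pre,
    rmspe_post = x$rmspe_post,
    rmspe_ratio = rmspe_ratio(x),
    pre_mspe = x$pre_mspe,
    v_method = x$v_method,
    converged = x$converged
  )
}

#' Export a fitted synthetic control to CSV files
#'
#' Writes the donor weights, predictor importances, and the monthly
#' observed/synthetic/gap series.
#'
#' @param fit An `scm_fit`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the treated unit id.
#' @return Named character vector of the files written, invisibly.
#' @export
write_scm_fit <- function(fit, dir, prefix = fit$treated) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    weights = file.path(dir, paste0(prefix, "_weights.csv")),
    importance = file.path(dir, paste0(prefix, "_importance.csv")),
    gaps = file.path(dir, paste0(prefix, "_gaps.csv"))
  )
  readr::write_csv(fit$weights, paths[["weights"]])
  readr::write_csv(fit$importance, paths[["importance"]])
  readr::write_csv(
    dplyr::mutate(fit$series, month = format_month(.data$month)),
    paths[["gaps"]]
  )
  invisible(paths)
}
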