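#' Robust trendline between experimental and in-well control values
#'
#' Fits `experimental ~ control` across the wells of a plate batch by
#' iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685), so that the handful of wells with strong true
#' phenotypes do not drag the trend.  The trendline absorbs systematic
#' batch differences between the experimental and control cell
#' populations (e.g. "all control cells ran faster that day"), which
#' simple division by the control value would not.
#'
#' When the experimental and control values are not usefully correlated
#' (Spearman rank correlation below 0.1, or a negative fitted slope, or an
#' undefined correlation), the fit is flagged for fallback and
#' normalization divides by the plate median instead.  In practice this is
#' the common path for angular bias, whose well-to-well variation is
#' usually smaller than its statistical noise.
#'
#' @param experimental,control paired per-well values (length >= 8).
#' @return an object of class `trendline_fit`: list with `slope`,
#'   `intercept`, `spearman`, `fallback`, `weights` (final IRLS weights,
#'   `NULL` under fallback).
#' @export
fit_trendline <- function(experimental, control) {
  ok <- is.finite(experimental) & is.finite(control)
  if (sum(ok) < 8) {
    stop("need at least 8 paired wells to fit a trendline (got ",
         sum(ok), ")")
  }
  x <- control[ok]
  y <- experimental[ok]
  rho <- suppressWarnings(cor(y, x, method = "spearman"))
  fit <- tryCatch(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 50,
              acc = 1e-8),
    error = function(e) NULL
  )
  slope <- if (is.null(fit)) NA_real_ else unname(coef(fit)[2])
  intercept <- if (is.null(fit)) NA_real_ else unname(coef(fit)[1])
  fallback <- is.null(fit) || is.na(rho) || rho < 0.1 ||
    is.na(slope) || slope < 0
  structure(
    list(slope = slope, intercept = intercept, spearman = rho,
         fallback = fallback,
         weights = if (fallback || is.null(fit)) NULL else fit$w,
         weight_function = "bisquare(c = 4.685)"),
    class = "trendline_fit"
  )
}

#' Normalize experimental values against the in-well control
#'
#' The expected value for each well is `slope * control + intercept` from
#' the robust trendline (or the plate median of the experimental values
#' when the fit is flagged for fallback).  The normalized value is
#' `experimental / expected` and the phenotype score is the normalized
#' value minus 1, so a score of 0 means "behaves like the control".
#' Wells with non-positive expected values cannot be normalized and are
#' flagged and excluded (`NA` scores).
#'
#' @param experimental per-well experimental values.
#' @param control per-well control values (needed unless `fit` is given
#'   and flagged for fallback).
#' @param fit optional precomputed [fit_trendline()] result; fitted from
#'   the data when omitted.
#' @return data frame with columns `expected`, `normalized`, `score`,
#'   `excluded`; the fit is attached as attribute `"fit"`.
#' @export
normalize_scores <- function(experimental, control = NULL, fit = NULL) {
  if (is.null(fit)) {
    stopifnot(!is.null(control))
    fit <- fit_trendline(experimental, control)
  }
  if (fit$fallback) {
    expected <- rep(median(experimental, na.rm = TRUE),
                    length(experimental))
  } else {
    stopifnot(!is.null(control))
    expected <- fit$slope * control + fit$intercept
  }
  excluded <- !is.finite(expected) | expected <= 0 |
    !is.finite(experimental)
  normalized <- ifelse(excluded, NA_real_, experimental / expected)
  out <- data.frame(expected = expected, normalized = normalized,
                    score = normalized - 1, excluded = excluded)
  attr(out, "fit") <- fit
  out
}

#' Chemokinesis score: residual stimulated speed given basal speed
#'
#' Across perturbations, stimulated-speed scores correlate strongly with
#' basal-speed scores because many genes set general motility.  A robust
#' trendline of stimulated on basal score captures that shared axis; the
#' signed residual from it — how much faster or slower a condition is
#' under stimulation than its basal motility predicts — isolates the
#' stimulus-induced speed boost (chemokinesis).  Adding a constant to all
#' stimulated scores shifts the intercept, not the residuals.
#'
#' If the basal scores are (nearly) constant the slope is taken as 0 and
#' residuals are computed against a robust intercept-only fit.
#'
#' @param basal,stimulated paired phenotype scores (per well or per
#'   condition).
#' @return numeric vector of chemokinesis scores, same length as the
#'   inputs (`NA` where either input is `NA`).
#' @export
chemokinesis_score <- function(basal, stimulated) {
  stopifnot(length(basal) == length(stimulated))
  ok <- is.finite(basal) & is.finite(stimulated)
  out <- rep(NA_real_, length(basal))
  if (sum(ok) < 2) return(out)
  x <- basal[ok]
  y <- stimulated[ok]
  if (sd(x) < 1e-12) {
    fit0 <- MASS::rlm(y ~ 1, psi = MASS::psi.bisquare, c = 4.685,
                      maxit = 50)
    out[ok] <- y - unname(coef(fit0)[1])
    return(out)
  }
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 50,
                   acc = 1e-8)
  out[ok] <- y - unname(coef(fit)[1] + coef(fit)[2] * x)
  out
}

#' Fit the two-Gaussian replicate-error model
#'
#' Models the measurement error of a phenotype score as a zero-mean
#' two-component Gaussian scale mixture with weights `w = (w1, w2)` and
#' standard deviations `sigma = (sigma1, sigma2)`, `sigma1 <= sigma2`.
#' Because the error distribution is never observed directly, the model is
#' fit to the *differences* between replicate measurements of the same
#' condition: if X and Y are two iid draws from the mixture, X - Y is
#' itself a zero-mean mixture with components `N(0, sigma_i^2 + sigma_j^2)`
#' and weights `w_i * w_j`, and this closed-form convolution is maximized
#' over the observed differences by numerical maximum likelihood
#' (Nelder-Mead then BFGS polish from a deterministic grid of
#' moment-anchored starts; weights live on a logistic scale and s.d.s on a
#' log scale).
#'
#' @param scores per-well phenotype scores.
#' @param condition condition label per score; all unordered within-
#'   condition pairs contribute one difference each (3 replicates give 3
#'   differences).
#' @param diffs alternatively, a precomputed vector of replicate
#'   differences (overrides `scores`/`condition`).
#' @return an object of class `error_model`: list with `w`, `sigma`,
#'   `loglik`, `n_diffs`, `converged`.
#' @seealso [null_interval()], [null_p_value()]
#' @export
fit_error_model <- function(scores = NULL, condition = NULL, diffs = NULL) {
  if (is.null(diffs)) {
    stopifnot(!is.null(scores), !is.null(condition),
              length(scores) == length(condition))
    diffs <- replicate_differences(scores, condition)
  }
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 10) {
    stop("too few replicate differences (", length(diffs),
         ") to fit the error model")
  }
  if (length(diffs) < 100) {
    warning("only ", length(diffs), " replicate differences; ",
            "error-model parameters will be imprecise")
  }
  nll <- function(par) {
    w1 <- stats::plogis(par[1])
    s1 <- exp(par[2])
    s2 <- exp(par[3])
    d <- w1^2 * dnorm(diffs, 0, sqrt(2) * s1) +
      2 * w1 * (1 - w1) * dnorm(diffs, 0, sqrt(s1^2 + s2^2)) +
      (1 - w1)^2 * dnorm(diffs, 0, sqrt(2) * s2)
    -sum(log(pmax(d, 1e-300)))
  }
  s_hat <- sd(diffs) / sqrt(2)  # moment anchor: Var(X - Y) = 2 Var(X)
  starts <- expand.grid(
    w1 = c(0.5, 0.8, 0.95),
    f1 = c(0.4, 0.8),
    f2 = c(1.2, 2.5)
  )
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(stats::qlogis(starts$w1[k]),
              log(s_hat * starts$f1[k]),
              log(s_hat * starts$f2[k]))
    res <- tryCatch({
      r1 <- optim(par0, nll, method = "Nelder-Mead",
                  control = list(maxit = 500))
      optim(r1$par, nll, method = "BFGS",
            control = list(maxit = 200, reltol = 1e-12))
    }, error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) {
      best <- res
    }
  }
  if (is.null(best)) {
    stop("error-model MLE failed to converge from every start")
  }
  w1 <- stats::plogis(best$par[1])
  s <- exp(best$par[2:3])
  w <- c(w1, 1 - w1)
  if (s[1] > s[2]) {  # identifiability: sigma1 <= sigma2
    s <- rev(s)
    w <- rev(w)
  }
  structure(
    list(w = w, sigma = s, loglik = -best$value,
         n_diffs = length(diffs), converged = best$convergence == 0),
    class = "error_model"
  )
}

#' All unordered within-condition replicate differences
#' @param scores per-well scores.
#' @param condition condition label per score.
#' @return numeric vector of pairwise differences.
#' @export
replicate_differences <- function(scores, condition) {
  unlist(lapply(split(scores, condition), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) return(numeric(0))
    pairs <- combn(length(v), 2)
    v[pairs[1, ]] - v[pairs[2, ]]
  }), use.names = FALSE)
}

#' Error-model variance
#' @param model an `error_model`.
#' @return the mixture variance `w1*sigma1^2 + w2*sigma2^2`.
#' @export
error_model_var <- function(model) {
  stopifnot(inherits(model, "error_model"))
  sum(model$w * model$sigma^2)
}

#' CDF of the null mean of n replicate measurements
#'
#' Under the fitted error model, the mean of n iid measurements of a
#' zero-phenotype condition is itself a zero-mean Gaussian mixture: with k
#' of the n draws coming from component 1, the mean has variance
#' `(k * sigma1^2 + (n - k) * sigma2^2) / n^2` and weight
#' `choose(n, k) * w1^k * w2^(n-k)`.  This closed-form CDF underlies both
#' the confidence intervals and the P-values.
#'
#' @param q quantiles.
#' @param model an `error_model`.
#' @param n number of replicates averaged.
#' @return `P(mean <= q)`, vectorized over `q`.
#' @export
null_mean_cdf <- function(q, model, n = 3) {
  stopifnot(inherits(model, "error_model"), n >= 1)
  k <- 0:n
  wts <- dbinom(k, n, model$w[1])
  sds <- sqrt(k * model$sigma[1]^2 + (n - k) * model$sigma[2]^2) / n
  vapply(q, function(x) sum(wts * pnorm(x, 0, sds)), numeric(1))
}

#' Null confidence interval for the mean of n replicates
#'
#' The symmetric interval within which the mean of `n` independent
#' measurements of a condition with zero true phenotype falls with
#' probability `coverage` (default 98%).  The bound is found by bisection
#' on the closed-form mixture CDF of the null mean.
#'
#' @param model an `error_model`.
#' @param n number of replicates.
#' @param coverage coverage probability in (0, 1).
#' @return an object of class `null_interval`: list with `lower`, `upper`,
#'   `coverage`, `n`.
#' @export
null_interval <- function(model, n = 3, coverage = 0.98) {
  stopifnot(inherits(model, "error_model"), coverage > 0, coverage < 1)
  target <- (1 + coverage) / 2
  hi <- 20 * max(model$sigma)
  b <- uniroot(function(x) null_mean_cdf(x, model, n) - target,
               interval = c(0, hi), tol = 1e-12)$root
  structure(list(lower = -b, upper = b, coverage = coverage, n = n),
            class = "null_interval")
}

#' Two-sided P-value for a mean phenotype score
#'
#' `p = 2 * (1 - F(|m|))` with F the closed-form CDF of the null mean of
#' `n` replicates under the fitted error model.
#'
#' @param m mean phenotype score (vectorized).
#' @param n number of replicates averaged.
#' @param model an `error_model`.
#' @return two-sided P-values in `[0, 1]`.
#' @export
null_p_value <- function(m, n, model) {
  p <- 2 * (1 - null_mean_cdf(abs(m), model, n))
  pmin(pmax(p, 0), 1)
}

#' Score a simulated or measured plate against its in-well controls
#'
#' Pivots a long per-well summary table (two rows per well: experimental
#' and control populations, as produced by [make_plate()]) into per-well
#' phenotype scores: basal speed, stimulated speed, directed movement and
#' angular bias are normalized against the in-well control by
#' [normalize_scores()] (each phenotype with its own trendline), and the
#' chemokinesis score is the robust residual of the stimulated score on
#' the basal score across wells.
#'
#' @param plate data frame from [make_plate()] (or measured equivalents
#'   with the same columns).
#' @return data frame with one row per well and columns `well`,
#'   `condition`, `replicate`, `basal`, `stim`, `directed`, `bias`,
#'   `chemokinesis` (phenotype scores).  Fits are attached as attribute
#'   `"fits"`.
#' @export
score_plate <- function(plate) {
  need <- c("well", "condition", "replicate", "population", "basal_speed",
            "stim_speed", "directed_speed", "angular_bias")
  stopifnot(all(need %in% names(plate)))
  exp_rows <- plate[plate$population == "experimental", , drop = FALSE]
  ctl_rows <- plate[plate$population == "control", , drop = FALSE]
  ctl_rows <- ctl_rows[match(exp_rows$well, ctl_rows$well), , drop = FALSE]
  pheno <- c(basal = "basal_speed", stim = "stim_speed",
             directed = "directed_speed", bias = "angular_bias")
  out <- data.frame(well = exp_rows$well, condition = exp_rows$condition,
                    replicate = exp_rows$replicate)
  fits <- list()
  for (nm in names(pheno)) {
    ns <- normalize_scores(exp_rows[[pheno[nm]]], ctl_rows[[pheno[nm]]])
    out[[nm]] <- ns$score
    fits[[nm]] <- attr(ns, "fit")
  }
  out$chemokinesis <- chemokinesis_score(out$basal, out$stim)
  attr(out, "fits") <- fits
  out
}

#' Summarize a screen: condition means, intervals, and P-values
#'
#' For each phenotype score, fits the replicate-error model over the whole
#' plate (or plate set), averages replicate scores per condition, and
#' reports the null interval membership and two-sided P-value of each
#' condition mean.
#'
#' @param scores per-well score table from [score_plate()] (several
#'   plates may be row-bound).
#' @param phenotypes score columns to summarize.
#' @param coverage interval coverage.
#' @return list with `table` (data frame `condition, phenotype,
#'   mean_score, n_reps, p_value, in_ci`) and `models` (named list of
#'   `error_model`s) and `intervals`.
#' @export
summarize_screen <- function(scores,
                             phenotypes = c("basal", "stim", "directed",
                                            "bias", "chemokinesis"),
                             coverage = 0.98) {
  models <- list()
  intervals <- list()
  rows <- list()
  for (ph in phenotypes) {
    model <- fit_error_model(scores[[ph]], scores$condition)
    models[[ph]] <- model
    by_cond <- split(scores[[ph]], scores$condition)
    means <- vapply(by_cond, function(v) mean(v[is.finite(v)]), numeric(1))
    ns <- vapply(by_cond, function(v) sum(is.finite(v)), integer(1))
    # one interval per replicate count present in the data
    ci_by_n <- lapply(sort(unique(ns[ns > 0])), function(n) {
      null_interval(model, n = n, coverage = coverage)
    })
    names(ci_by_n) <- sort(unique(ns[ns > 0]))
    intervals[[ph]] <- ci_by_n
    pv <- mapply(function(m, n) {
      if (n == 0 || !is.finite(m)) NA_real_ else null_p_value(m, n, model)
    }, means, ns)
    inside <- mapply(function(m, n) {
      if (n == 0 || !is.finite(m)) return(NA)
      ci <- ci_by_n[[as.character(n)]]
      m >= ci$lower & m <= ci$upper
    }, means, ns)
    rows[[ph]] <- data.frame(condition = names(by_cond), phenotype = ph,
                             mean_score = unname(means),
                             n_reps = unname(ns),
                             p_value = unname(pv), in_ci = unname(inside))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, models = models, intervals = intervals)
}
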