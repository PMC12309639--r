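# Condition model: binomial GAM of hard-coral cover against log-TSS with a
# thin-plate regression spline and site-level random intercepts, fitted with
# mgcv. Posterior coefficient draws (empirical-Bayes multivariate normal
# around the penalized fit) turn the curve into a per-cell probability that
# cover exceeds the good-condition threshold.

#' Fit the hard-coral condition model
#'
#' Fits `cbind(hits, misses) ~ s(log_tss, bs = "tp", k) + s(site, bs = "re")`
#' with a binomial likelihood. The site smooth is the standard
#' random-intercept-as-ridge-penalty construction, so its smoothing parameter
#' estimates the site variance component. Smoothness is selected by REML by
#' default (configurable).
#'
#' @param surveys a `survey_table` (transect- or site-level rows) with
#'   columns `site_id`, `n_points`, `n_hard_coral`, `log_tss`.
#' @param k basis dimension of the log-TSS smooth (default 10).
#' @param method mgcv smoothing-selection criterion (default `"REML"`).
#' @param sp optional fixed smoothing parameters (length 2: smooth, site).
#' @return a `condition_model`: the mgcv fit plus extracted summaries
#'   (`site_effect_sd`, `smoothing_param`, `deviance_explained`,
#'   `coef_covariance`).
#' @export
fit_condition_model <- function(surveys, k = 10, method = "REML", sp = NULL) {
  df <- as.data.frame(surveys)
  need <- c("site_id", "n_points", "n_hard_coral", "log_tss")
  if (!all(need %in% names(df)))
    stop("surveys must have columns ", paste(need, collapse = ", "))
  if (length(unique(df$site_id)) < 2) stop("need at least two sites")
  if (diff(range(df$log_tss)) <= 0)
    stop("covariate log_tss is constant; the smooth is not identifiable")
  if (any(df$n_hard_coral < 0 | df$n_hard_coral > df$n_points))
    stop("counts must satisfy 0 <= n_hard_coral <= n_points")
  df$site <- factor(df$site_id)
  df$miss <- df$n_points - df$n_hard_coral
  k <- min(k, length(unique(df$log_tss)) - 1)
  fit <- mgcv::gam(cbind(n_hard_coral, miss) ~ s(log_tss, bs = "tp", k = k) +
                     s(site, bs = "re"),
                   family = stats::binomial(), method = method, sp = sp,
                   data = df)
  quiet <- utils::capture.output(vc <- mgcv::gam.vcomp(fit, rescale = FALSE))
  site_sd <- tryCatch(unname(vc[grep("site", rownames(vc)), "std.dev"]),
                      error = function(e) NA_real_)
  if (length(site_sd) != 1) site_sd <- NA_real_
  structure(list(
    fit = fit,
    coefficients = stats::coef(fit),
    coef_covariance = stats::vcov(fit),   # Bayesian posterior covariance Vp
    smoothing_param = fit$sp,
    site_effect_sd = site_sd,
    deviance_explained = summary(fit)$dev.expl,
    data = df
  ), class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat("<condition_model> binomial GAM, logit(cover) = f(log_tss) + site\n")
  cat(sprintf("  deviance explained: %.1f%%; site SD: %.3f logits\n",
              100 * x$deviance_explained, x$site_effect_sd))
  cat(sprintf("  smoothing parameters: %s\n",
              paste(signif(x$smoothing_param, 4), collapse = ", ")))
  invisible(x)
}

#' Overdispersion check
#'
#' Pearson chi-squared over residual degrees of freedom. For grouped binomial
#' data a ratio near 1 indicates the binomial variance assumption holds;
#' values above the band flag extra-binomial variation (e.g. beta-binomial
#' clustering within transects) that the site effect cannot absorb.
#'
#' @param model a `condition_model`.
#' @param band acceptable ratio band (default `c(0.7, 1.4)`).
#' @return list with `ratio`, `pearson_chisq`, `df_residual`, `verdict`
#'   (`"ok"` / `"overdispersed"` / `"underdispersed"`).
#' @export
check_overdispersion <- function(model, band = c(0.7, 1.4)) {
  r <- stats::residuals(model$fit, type = "pearson")
  dfres <- stats::df.residual(model$fit)
  ratio <- sum(r^2) / dfres
  verdict <- if (ratio > band[2]) "overdispersed"
  else if (ratio < band[1]) "underdispersed" else "ok"
  list(ratio = ratio, pearson_chisq = sum(r^2), df_residual = dfres,
       verdict = verdict, band = band)
}

#' Empirical semivariogram of model residuals
#'
#' `gamma(h) = (1 / (2 |N(h)|)) * sum over pairs in the lag bin of the
#' squared residual difference`, with deviance residuals aggregated to one
#' value per site (mean) and pair distances between site coordinates. A flat
#' semivariogram indicates no residual spatial autocorrelation.
#'
#' @param model a `condition_model`.
#' @param lag_bins number of equal-width distance bins (default 10).
#' @return data.frame with `lag` (bin midpoint), `gamma`, `n_pairs`.
#' @export
residual_semivariogram <- function(model, lag_bins = 10) {
  df <- model$data
  if (!all(c("x", "y") %in% names(df)))
    stop("surveys used to fit the model need x and y coordinates")
  r_all <- stats::residuals(model$fit, type = "deviance")
  sites <- unique(df[, c("site_id", "x", "y")])
  if (nrow(sites) < 2) stop("need at least two sites for a semivariogram")
  r <- tapply(r_all, df$site_id, mean)[as.character(sites$site_id)]
  dmat <- as.matrix(dist(sites[, c("x", "y")]))
  pr <- which(upper.tri(dmat), arr.ind = TRUE)
  d <- dmat[pr]
  sq <- (r[pr[, 1]] - r[pr[, 2]])^2
  breaks <- seq(0, max(d) * (1 + 1e-9), length.out = lag_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  data.frame(
    lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
    gamma = as.numeric(tapply(sq, factor(bin, levels = seq_len(lag_bins)),
                              function(v) sum(v) / (2 * length(v)))),
    n_pairs = as.integer(table(factor(bin, levels = seq_len(lag_bins))))
  )
}

# symmetric eigenvalue repair for a near-PSD covariance
.repair_psd <- function(V, tol = 1e-10) {
  V <- (V + t(V)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("coefficient covariance is not positive semi-definite")
  vals <- pmax(e$values, 0)
  list(vectors = e$vectors, values = vals)
}

#' Posterior draws of model coefficients
#'
#' Multivariate-normal draws centred at the penalized-likelihood coefficient
#' estimates with the Bayesian posterior covariance of the fit — the
#' empirical-Bayes posterior simulation that underlies the exceedance map.
#'
#' @param model a `condition_model`.
#' @param n_draws number of draws (default 1000).
#' @param seed integer RNG seed.
#' @return `n_draws` x p matrix of coefficient vectors.
#' @export
posterior_draws <- function(model, n_draws = 1000, seed = 1) {
  mu <- model$coefficients
  ev <- .repair_psd(model$coef_covariance)
  half <- ev$vectors %*% diag(sqrt(ev$values), length(ev$values))
  with_seed_(seed, {
    z <- matrix(rnorm(n_draws * length(mu)), length(mu), n_draws)
    t(half %*% z + mu)
  })
}

#' Probability-of-good-condition surface
#'
#' For every coral-bearing cell with a log-TSS value, the fraction of
#' posterior draws whose predicted cover (at the population-level site
#' effect, i.e. a site intercept of zero) exceeds `threshold`. Cells off the
#' coral mask, or with missing log-TSS, are no-data.
#'
#' @param model a `condition_model`.
#' @param draws matrix from [posterior_draws()].
#' @param log_tss `grid_layer` of log-TSS.
#' @param coral_mask logical matrix or coral-amount `grid_layer`.
#' @param threshold good-condition cover threshold (default 0.30).
#' @return a `condition_surface`: list with `prob_good` grid, `threshold`,
#'   `n_draws`.
#' @export
prob_good_condition <- function(model, draws, log_tss, coral_mask,
                                threshold = 0.30) {
  mask <- if (is_grid_layer(coral_mask)) {
    !is.na(coral_mask$values) & coral_mask$values > 0
  } else coral_mask
  cells <- which(mask)
  ok <- !is.na(log_tss$values[cells])
  if (any(!ok))
    message(sprintf("%d coral cells lack a log-TSS value; left as no-data",
                    sum(!ok)))
  cells <- cells[ok]
  pg <- matrix(NA_real_, nrow(log_tss$values), ncol(log_tss$values))
  if (length(cells)) {
    nd <- data.frame(log_tss = log_tss$values[cells],
                     site = model$data$site[1])
    Xp <- stats::predict(model$fit, newdata = nd, type = "lpmatrix",
                         exclude = "s(site)")
    eta <- Xp %*% t(draws)                     # cells x draws
    pg[cells] <- rowMeans(plogis(eta) > threshold)
  }
  structure(list(prob_good = with_values(log_tss, pg),
                 threshold = threshold, n_draws = nrow(draws)),
            class = "condition_surface")
}

#' Run the coral stage: surveys to exceedance surface
#'
#' @param surveys a `survey_table`.
#' @param tss a `tss_field`.
#' @param coral_mask coral-amount `grid_layer` or logical matrix.
#' @param k,method passed to [fit_condition_model()].
#' @param n_draws,seed passed to [posterior_draws()].
#' @param threshold good-condition cover threshold.
#' @return list: `model`, `draws`, `surface`, `overdispersion`.
#' @export
run_coral <- function(surveys, tss, coral_mask, k = 10, method = "REML",
                      n_draws = 1000, seed = 1, threshold = 0.30) {
  model <- fit_condition_model(surveys, k = k, method = method)
  draws <- posterior_draws(model, n_draws = n_draws, seed = seed)
  surface <- prob_good_condition(model, draws, tss$log_tss, coral_mask,
                                 threshold = threshold)
  list(model = model, draws = draws, surface = surface,
       overdispersion = check_overdispersion(model))
}
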