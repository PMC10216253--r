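# Hill concentration-response fitting for activation (agonist
# concentration-response) and inhibition (suppression of evoked release)
# curves. Fitting is done on the log-concentration axis with a multi-start
# Levenberg-Marquardt search to avoid local minima.

#' Concentration-response series
#'
#' Replicated normalized responses at strictly positive molar
#' concentrations; at least 4 distinct concentrations are required for a
#' Hill fit.
#'
#' @param concentration Molar concentrations, strictly positive.
#' @param response Normalized responses (unitless).
#' @param replicate Replicate identifiers (oocyte, slice, ...).
#' @return A data frame of class `dose_response_series`.
#' @export
dose_response_series <- function(concentration, response, replicate = 1L) {
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be strictly positive and finite",
         call. = FALSE)
  if (length(response) != length(concentration))
    stop("'concentration' and 'response' lengths differ", call. = FALSE)
  replicate <- rep_len(as.character(replicate), length(concentration))
  if (length(unique(concentration)) < 4L)
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  structure(data.frame(replicate = replicate,
                       concentration = as.numeric(concentration),
                       response = as.numeric(response)),
            class = c("dose_response_series", "data.frame"))
}

#' Normalize raw response maxima within each replicate
#'
#' Scales each replicate's responses to its own maximum (maximum = 1), the
#' convention used when averaging peak-current measurements across
#' oocytes or slices before Hill fitting. Idempotent on already-normalized
#' data.
#'
#' @param data Data frame with columns `replicate`, `concentration`,
#'   `response` (raw maxima, e.g. uA).
#' @return A [dose_response_series()] with per-replicate normalized
#'   responses.
#' @export
#' @examples
#' raw <- data.frame(replicate = 1, concentration = c(1e-8, 1e-7, 1e-6),
#'                   response = c(1, 2, 4))
#' normalize_responses(raw)$response  # 0.25 0.50 1.00
normalize_responses <- function(data) {
  req <- c("replicate", "concentration", "response")
  if (!all(req %in% names(data)))
    stop("need columns ", paste(req, collapse = ", "), call. = FALSE)
  out <- data[req]
  for (id in unique(out$replicate)) {
    sel <- out$replicate == id
    m <- max(out$response[sel])
    if (!is.finite(m) || m <= 0)
      stop("replicate '", id, "' has no positive maximum to normalize by",
           call. = FALSE)
    out$response[sel] <- out$response[sel] / m
  }
  # may have < 4 distinct concentrations when used standalone; defer that
  # check to fitting
  structure(out, class = c("dose_response_series", "data.frame"))
}

# Hill response function shared by fitting and prediction.
# activation: top * c^n / (c^n + ec50^n); inhibition:
# 1 - (1 - floor) * c^n / (c^n + ic50^n).
hill_value <- function(conc, ec50, n, top = 1, floor = 0,
                       direction = c("activation", "inhibition")) {
  direction <- match.arg(direction)
  f <- ifelse(conc == 0, 0,
              1 / (1 + exp(n * (log(ec50) - log(conc)))))
  if (direction == "activation") top * f else 1 - (1 - floor) * f
}

#' Fit a one-site Hill model
#'
#' Least-squares fit of the Hill equation to a concentration-response
#' series. For activation curves the bottom is fixed at 0 and the top
#' asymptote is free; for inhibition curves the baseline is fixed at 1
#' (responses are baseline-normalized) and the floor is fixed (0 by
#' default). The midpoint is parameterized on the log scale and the search
#' is multi-started from every tested concentration.
#'
#' @param series A [dose_response_series()] (or data frame with
#'   `replicate`, `concentration`, `response`).
#' @param direction `"activation"` or `"inhibition"`.
#' @param floor Fixed lower asymptote for inhibition fits.
#' @param top_fixed Optional fixed top asymptote for activation fits.
#' @return An object of class `hill_fit`: `ec50` (molar; the IC50 for
#'   inhibition fits), `hill_coefficient`, `top`, `floor`, `direction`,
#'   residual summary (`rss`, `sigma`), and the input series.
#' @seealso [predict.hill_fit()], [hill_ci()]
#' @export
#' @examples
#' doses <- 1e-7 * 3^seq(-5, 6)
#' series <- dose_response_series(doses,
#'   hill_value(doses, 1e-7, 1.5, direction = "activation"))
#' fit <- fit_hill(series, "activation")
#' fit$ec50  # recovers 1e-7
fit_hill <- function(series, direction = c("activation", "inhibition"),
                     floor = 0, top_fixed = NULL) {
  direction <- match.arg(direction)
  if (!inherits(series, "dose_response_series"))
    series <- dose_response_series(series$concentration, series$response,
                                   series$replicate)
  if (length(unique(series$concentration)) < 4L)
    stop("at least 4 distinct concentrations are required", call. = FALSE)
  df <- data.frame(lc = log(series$concentration), y = series$response)
  starts_lec <- unique(c(log(sort(unique(series$concentration))),
                         mean(range(log(series$concentration)))))

  fits <- list()
  for (lec0 in starts_lec) {
    fml <- if (direction == "activation") {
      if (is.null(top_fixed))
        y ~ top / (1 + exp(exp(ln_n) * (lec - lc)))
      else
        substitute(y ~ TOP / (1 + exp(exp(ln_n) * (lec - lc))),
                   list(TOP = top_fixed))
    } else {
      substitute(y ~ 1 - (1 - FLOOR) / (1 + exp(exp(ln_n) * (lec - lc))),
                 list(FLOOR = floor))
    }
    start <- list(lec = lec0, ln_n = 0)
    if (direction == "activation" && is.null(top_fixed))
      start$top <- max(df$y, 0.5)
    f <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(fml), data = df, start = start,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits))
    stop("Hill fit did not converge from any start", call. = FALSE)
  dev <- vapply(fits, stats::deviance, numeric(1))
  best <- fits[[which.min(dev)]]
  cf <- stats::coef(best)
  ec50 <- exp(cf[["lec"]])
  n <- exp(cf[["ln_n"]])
  top <- if (direction == "activation") {
    if (is.null(top_fixed)) cf[["top"]] else top_fixed
  } else 1
  rss <- stats::deviance(best)
  n_obs <- nrow(df)
  structure(list(ec50 = ec50, hill_coefficient = n, top = top,
                 floor = if (direction == "inhibition") floor else 0,
                 direction = direction, rss = rss,
                 sigma = sqrt(rss / max(n_obs - length(cf), 1)),
                 n_obs = n_obs, series = series, model = best),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  lbl <- if (x$direction == "activation") "EC50" else "IC50"
  cat(sprintf("Hill fit (%s): %s %.4g M, n = %.3g, top = %.3g (rss %.3g)\n",
              x$direction, lbl, x$ec50, x$hill_coefficient, x$top, x$rss))
  if (!is.null(x$ci))
    cat(sprintf("  95%% bootstrap CI for %s: [%.4g, %.4g] M\n", lbl,
                x$ci[1], x$ci[2]))
  invisible(x)
}

#' Predicted response from a Hill fit
#'
#' Model value at the given concentrations; monotone in concentration, with
#' the activation curve running from 0 to `top` and the inhibition curve
#' from 1 down to `floor`.
#'
#' @param object A `hill_fit`.
#' @param concentration Molar concentrations, >= 0.
#' @param ... Unused.
#' @return Numeric vector of predicted normalized responses.
#' @export
predict.hill_fit <- function(object, concentration, ...) {
  if (any(concentration < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  hill_value(concentration, object$ec50, object$hill_coefficient,
             top = object$top, floor = object$floor,
             direction = object$direction)
}

#' Bootstrap confidence interval for the Hill midpoint
#'
#' 95% (by default) percentile interval for the EC50/IC50 from
#' case-resampling of replicates: whole replicates are drawn with
#' replacement and the model refit to each resample (initialized at the
#' point estimate). Deterministic under a fixed seed; with zero residual
#' noise the interval collapses onto the point estimate.
#'
#' @param fit A `hill_fit`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed for the resampling RNG.
#' @param level Confidence level.
#' @return The `hill_fit` with elements `ci` (length-2 vector) and
#'   `boot_ec50` (the resample estimates) added.
#' @export
hill_ci <- function(fit, n_boot = 500, seed = 1, level = 0.95) {
  stopifnot(inherits(fit, "hill_fit"))
  series <- fit$series
  ids <- unique(series$replicate)
  if (length(ids) < 2L)
    stop("bootstrap requires at least 2 replicates", call. = FALSE)
  by_id <- split(seq_len(nrow(series)), series$replicate)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  est <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    draw <- sample(ids, length(ids), replace = TRUE)
    rows <- unlist(by_id[draw], use.names = FALSE)
    boot_series <- structure(series[rows, , drop = FALSE],
                             class = class(series))
    f <- tryCatch(
      refit_hill_at(boot_series, fit),
      error = function(e) NULL)
    if (!is.null(f)) est[b] <- f
  }
  est <- est[is.finite(est)]
  if (!length(est))
    stop("all bootstrap refits failed", call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(est, c(alpha, 1 - alpha)))
  fit$ci <- ci
  fit$boot_ec50 <- est
  fit
}

# fast single-start refit used inside the bootstrap; returns the midpoint
refit_hill_at <- function(series, fit) {
  df <- data.frame(lc = log(series$concentration), y = series$response)
  fml <- if (fit$direction == "activation") {
    y ~ top / (1 + exp(exp(ln_n) * (lec - lc)))
  } else {
    substitute(y ~ 1 - (1 - FLOOR) / (1 + exp(exp(ln_n) * (lec - lc))),
               list(FLOOR = fit$floor))
  }
  start <- list(lec = log(fit$ec50), ln_n = log(fit$hill_coefficient))
  if (fit$direction == "activation") start$top <- fit$top
  f <- minpack.lm::nlsLM(stats::as.formula(fml), data = df, start = start,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100, ftol = 1e-10, ptol = 1e-10))
  exp(stats::coef(f)[["lec"]])
}
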