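#' Four-parameter logistic dose-response function
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))`, the standard
#' log-logistic parameterization: `b` is the hill slope, `c` the lower
#' asymptote, `d` the upper asymptote and `e` the midpoint concentration
#' (relative ED50).  With `b > 0` the curve decreases with dose.
#'
#' @param x dose (positive).
#' @param b,c,d,e curve parameters.
#' @return response at `x`.
#' @export
logistic4 <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit a 3- or 4-parameter logistic model to a viability curve
#'
#' Least-squares fit of [logistic4()] to viability-versus-dose data by
#' multi-start Levenberg-Marquardt (logistic fits are multimodal, so each
#' model is started from a coarse grid over the hill slope and the midpoint
#' spanning the dose range).  The 3-parameter variant fixes the lower
#' asymptote at 0.  `model = "auto"` fits both and selects by AIC, falling
#' back to 3PL when the 4PL lower-asymptote estimate is negative or the 4PL
#' fit fails.
#'
#' @param doses strictly positive dose vector.
#' @param viabilities non-negative responses (fraction of control; may
#'   exceed 1).
#' @param model `"auto"`, `"4PL"` or `"3PL"`.
#' @return an object of class `logistic_fit`: list with `model`, `b`, `c`,
#'   `d`, `e`, `rss`, `n`, `aic`, `converged`.
#' @examples
#' d <- 10^seq(-3, 2)
#' v <- logistic4(d, b = 1, c = 0.1, d = 1, e = 0.5)
#' fit_logistic(d, v)
#' @export
fit_logistic <- function(doses, viabilities, model = c("auto", "4PL", "3PL")) {
  model <- match.arg(model)
  if (length(doses) != length(viabilities))
    pgx_stop("doses and viabilities must have equal length", "pgx_data_error")
  keep <- !is.na(doses) & !is.na(viabilities)
  doses <- doses[keep]; viabilities <- viabilities[keep]
  if (any(doses <= 0))
    pgx_stop("doses must be strictly positive", "pgx_domain_error")
  ndose <- length(unique(doses))
  need <- if (model == "3PL") 3L else 4L
  if (ndose < need)
    pgx_stop(sprintf("need >= %d distinct doses for %s fitting", need,
                     if (model == "3PL") "3PL" else "4PL"),
             "pgx_insufficient_data")

  fail <- structure(list(model = NA_character_, b = NA_real_, c = NA_real_,
                         d = NA_real_, e = NA_real_, rss = NA_real_,
                         n = length(doses), aic = NA_real_,
                         converged = FALSE),
                    class = "logistic_fit")
  # flat data: the midpoint is unidentifiable
  if (sd(viabilities) < 1e-10) return(fail)

  f4 <- fit_one_logistic(doses, viabilities, fix_lower = FALSE)
  f3 <- fit_one_logistic(doses, viabilities, fix_lower = TRUE)
  pick <- switch(model,
    "4PL" = f4,
    "3PL" = f3,
    "auto" = {
      if (is.null(f4) || f4$c < 0) f3
      else if (is.null(f3)) f4
      else if (f3$aic <= f4$aic) f3 else f4
    })
  if (is.null(pick)) return(fail)
  structure(c(pick, list(converged = TRUE)), class = "logistic_fit")
}

# single-model multi-start fit; returns NULL when no start converges
fit_one_logistic <- function(doses, viabilities, fix_lower) {
  dmax <- max(viabilities)
  dmin <- min(viabilities)
  slope_sign <- if (cor(log(doses), viabilities) <= 0) 1 else -1
  b_starts <- slope_sign * c(0.5, 1, 2)
  e_starts <- exp(seq(log(min(doses)), log(max(doses)), length.out = 3))
  n <- length(doses)
  best <- NULL
  for (b0 in b_starts) for (e0 in e_starts) {
    st <- if (fix_lower) list(b = b0, d = dmax, loge = log(e0))
          else list(b = b0, c = dmin, d = dmax, loge = log(e0))
    fml <- if (fix_lower)
      viabilities ~ logistic4(doses, b, 0, d, exp(loge))
    else
      viabilities ~ logistic4(doses, b, c, d, exp(loge))
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        fml, start = st,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- stats::coef(fit)
      npar <- length(cf)
      best <- list(model = if (fix_lower) "3PL" else "4PL",
                   b = unname(cf["b"]),
                   c = if (fix_lower) 0 else unname(cf["c"]),
                   d = unname(cf["d"]),
                   e = exp(unname(cf["loge"])),
                   rss = rss, n = n,
                   aic = n * log(max(rss, 1e-300) / n) + 2 * (npar + 1))
    }
  }
  best
}

#' @export
print.logistic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Logistic fit: did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("%s fit: b=%.4g c=%.4g d=%.4g e=%.4g (rss=%.4g, n=%d)\n",
              x$model, x$b, x$c, x$d, x$e, x$rss, x$n))
  invisible(x)
}

#' Extract the IC50 from a logistic fit
#'
#' By default the relative ED50, i.e. the midpoint parameter `e` (the dose at
#' which the response is halfway between the lower and upper asymptotes).
#' `type = "absolute"` instead returns the dose at which the fitted curve
#' crosses 50% of control (response = 0.5), which may not exist for curves
#' whose asymptotes bracket 0.5 poorly.
#'
#' @param fit a `logistic_fit`.
#' @param type `"relative"` (default) or `"absolute"`.
#' @return the IC50 in dose units, or `NA` with a warning for a
#'   non-converged fit.
#' @export
estimate_ic50 <- function(fit, type = c("relative", "absolute")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "logistic_fit"))
  if (!isTRUE(fit$converged)) {
    warning("IC50 unavailable: fit did not converge")
    return(NA_real_)
  }
  if (type == "relative") return(fit$e)
  target <- 0.5
  ratio <- (fit$d - target) / (target - fit$c)
  if (!is.finite(ratio) || ratio <= 0) {
    warning("absolute IC50 undefined: curve does not cross 50% of control")
    return(NA_real_)
  }
  fit$e * ratio^(1 / fit$b)
}

#' Fit IC50s for a table of dose-response curves
#'
#' Applies [fit_logistic()] per (sample, drug) group of a long-format curve
#' table and extracts IC50s.  Samples whose fit does not converge get
#' `converged = FALSE` and `NA` IC50 (and are excluded from downstream
#' association by missing-value propagation).
#'
#' @param curves data.frame with columns `sample_id`, `drug`, `dose`,
#'   `viability`.
#' @param model passed to [fit_logistic()].
#' @return data.frame with one row per sample x drug: `sample_id`, `drug`,
#'   `model`, `b`, `c`, `d`, `e`, `ic50`, `rss`, `converged`.
#' @export
fit_ic50_table <- function(curves, model = "auto") {
  need <- c("sample_id", "drug", "dose", "viability")
  if (!all(need %in% names(curves)))
    pgx_stop("curves must have columns sample_id, drug, dose, viability",
             "pgx_data_error")
  groups <- split(curves, list(curves$drug, curves$sample_id), drop = TRUE)
  rows <- lapply(groups, function(g) {
    fit <- tryCatch(fit_logistic(g$dose, g$viability, model = model),
                    pgx_error = function(e) NULL)
    if (is.null(fit))
      fit <- list(model = NA_character_, b = NA_real_, c = NA_real_,
                  d = NA_real_, e = NA_real_, rss = NA_real_,
                  converged = FALSE)
    data.frame(sample_id = g$sample_id[1], drug = g$drug[1],
               model = fit$model, b = fit$b, c = fit$c, d = fit$d,
               e = fit$e,
               ic50 = if (isTRUE(fit$converged)) fit$e else NA_real_,
               rss = fit$rss, converged = isTRUE(fit$converged),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$drug, out$sample_id), , drop = FALSE]
}

#' Transform IC50s into an association phenotype
#'
#' `method = "log10"` applies a log10 transform elementwise (the standard
#' skewness-removing transform for gemcitabine-type IC50 distributions);
#' `method = "vdw"` applies the van der Waerden rank-normal transform
#' `qnorm(rank / (n + 1))` with average ranks for ties, where `n` counts
#' non-missing values.  Missing values propagate.
#'
#' @param ic50s numeric vector (positive for `log10`).
#' @param method `"log10"` or `"vdw"`.
#' @return transformed numeric vector of the same length, names preserved.
#' @examples
#' transform_phenotype(c(1, 10, 100), "log10")
#' transform_phenotype(c(3, 1, 2), "vdw")
#' @export
transform_phenotype <- function(ic50s, method = c("log10", "vdw")) {
  method <- match.arg(method)
  if (method == "log10") {
    if (any(ic50s <= 0, na.rm = TRUE))
      pgx_stop("log10 transform requires positive IC50s", "pgx_domain_error")
    return(log10(ic50s))
  }
  ok <- !is.na(ic50s)
  n <- sum(ok)
  if (n < 2)
    pgx_stop("van der Waerden transform requires >= 2 non-missing values",
             "pgx_insufficient_data")
  out <- rep(NA_real_, length(ic50s))
  r <- rank(ic50s[ok], ties.method = "average")
  out[ok] <- qnorm(r / (n + 1))
  names(out) <- names(ic50s)
  out
}
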