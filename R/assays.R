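# Quantitative assay analytics: four-parameter-logistic dose-response (IC50),
# first-order protein-decay half-life from cycloheximide-chase data,
# densitometry normalization, and reporter-inhibition hit calling.

#' Construct a dose-response dataset
#'
#' @param doses numeric doses, uM; 0 is allowed (vehicle).
#' @param responses normalized activity (vehicle = 1).
#' @param replicate_ids optional integer replicate labels.
#' @return list of class `DoseResponseData`.
#' @export
dose_response_data <- function(doses, responses, replicate_ids = NULL) {
  stopifnot(length(doses) == length(responses), all(doses >= 0),
            all(is.finite(doses)), all(is.finite(responses)))
  if (length(unique(doses)) < 4)
    stop("at least 4 distinct dose levels are required for fitting")
  if (is.null(replicate_ids)) replicate_ids <- rep(1L, length(doses))
  structure(list(doses = doses, responses = responses,
                 replicate_ids = as.integer(replicate_ids)),
            class = "DoseResponseData")
}

.fourpl <- function(dose, ic50, hill, top, bottom)
  bottom + (top - bottom) / (1 + (dose / ic50)^hill)

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `y = bottom + (top - bottom) / (1 + (dose/ic50)^hill)`
#' on the linear dose scale, with the IC50 parameterized internally as
#' `log(ic50)` and multi-start initialization over a log-spaced IC50 grid.
#' Vehicle doses (0) evaluate to `top` exactly.  Non-convergence is reported
#' through `converged = FALSE`, never as an exception.
#'
#' @param data a [dose_response_data()] object.
#' @param fixed_top_bottom optional numeric length-2 `c(top, bottom)`; when
#'   given only IC50 and Hill slope are fitted (the usual choice for
#'   vehicle-normalized reporter data).
#' @return list of class `DoseResponseFit`: `ic50` (uM), `hill`, `top`,
#'   `bottom`, `se_ic50` (uM, delta method), `converged`, `rss`,
#'   `message`.
#' @export
fit_dose_response <- function(data, fixed_top_bottom = NULL) {
  stopifnot(inherits(data, "DoseResponseData"))
  d <- data$doses; y <- data$responses
  fail <- function(msg) structure(
    list(ic50 = NA_real_, hill = NA_real_, top = NA_real_, bottom = NA_real_,
         se_ic50 = NA_real_, converged = FALSE, rss = NA_real_, message = msg),
    class = "DoseResponseFit")
  if (stats::sd(y) == 0) return(fail("responses are constant"))
  fixed <- !is.null(fixed_top_bottom)
  if (fixed) stopifnot(length(fixed_top_bottom) == 2,
                       fixed_top_bottom[1] > fixed_top_bottom[2])
  model <- function(p) {
    top <- if (fixed) fixed_top_bottom[1] else p[["top"]]
    bottom <- if (fixed) fixed_top_bottom[2] else p[["bottom"]]
    bottom + (top - bottom) / (1 + (d / exp(p[["l_ic50"]]))^p[["hill"]])
  }
  pos <- d[d > 0]
  starts_l50 <- seq(log(min(pos) / 2), log(max(pos) * 2), length.out = 4)
  starts_hill <- c(0.5, 1.5, 3)
  best <- NULL
  for (l50 in starts_l50) for (h0 in starts_hill) {
    p0 <- c(l_ic50 = l50, hill = h0)
    if (!fixed) p0 <- c(p0, top = max(y), bottom = min(y))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = function(p) y - model(p),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    # a diverging log-IC50 (overflowing exp) is a degenerate solution
    if (!is.finite(exp(cf[["l_ic50"]]))) next
    rss <- fit$deviance
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail("no start converged"))
  cf <- stats::coef(best$fit)
  ic50 <- exp(cf[["l_ic50"]])
  se_l50 <- tryCatch(summary(best$fit)$coefficients["l_ic50", "Std. Error"],
                     error = function(e) NA_real_)
  structure(list(
    ic50 = ic50, hill = cf[["hill"]],
    top = if (fixed) fixed_top_bottom[1] else cf[["top"]],
    bottom = if (fixed) fixed_top_bottom[2] else cf[["bottom"]],
    se_ic50 = ic50 * se_l50,  # delta method from log-scale SE
    converged = is.finite(ic50) && ic50 > 0 && best$fit$info %in% 1:4,
    rss = best$rss, message = best$fit$message),
    class = "DoseResponseFit")
}

#' Construct a cycloheximide-chase dataset
#'
#' @param times numeric chase times, hours.
#' @param levels normalized protein levels (positive; t = 0 mean = 1).
#' @param condition condition label.
#' @param replicate_ids optional integer replicate labels.
#' @return list of class `ChaseData`.
#' @export
chase_data <- function(times, levels, condition = "control",
                       replicate_ids = NULL) {
  stopifnot(length(times) == length(levels), all(times >= 0),
            all(levels > 0))
  if (length(unique(times)) < 2)
    stop("at least 2 distinct timepoints are required")
  if (is.null(replicate_ids)) replicate_ids <- rep(1L, length(times))
  structure(list(times = times, levels = levels, condition = condition,
                 replicate_ids = as.integer(replicate_ids)),
            class = "ChaseData")
}

#' Fit a first-order protein-decay half-life
#'
#' Ordinary least squares of `log(level)` on time; the decay constant is the
#' negative slope and `half_life = log(2) / k`.  The half-life standard
#' error follows from the slope SE by the delta method.  Non-decaying data
#' (k <= 0) return an infinite half-life with `decaying = FALSE` and a
#' warning.
#'
#' @param data a [chase_data()] object.
#' @return list of class `DecayFit`: `k` (per hour), `half_life` (h),
#'   `se_half_life` (h), `r_squared`, `decaying`.
#' @export
fit_half_life <- function(data) {
  stopifnot(inherits(data, "ChaseData"))
  fit <- stats::lm(log(data$levels) ~ data$times)
  slope <- unname(stats::coef(fit)[2])
  se_slope <- summary(fit)$coefficients[2, 2]
  k <- -slope
  if (k <= 0) {
    warning("levels do not decay (k <= 0); half-life reported as infinite")
    return(structure(list(k = k, half_life = Inf, se_half_life = NA_real_,
                          r_squared = summary(fit)$r.squared,
                          decaying = FALSE),
                     class = "DecayFit"))
  }
  structure(list(k = k, half_life = log(2) / k,
                 se_half_life = log(2) / k^2 * se_slope,
                 r_squared = summary(fit)$r.squared, decaying = TRUE),
            class = "DecayFit")
}

#' Cross-check half-life by direct nonlinear exponential fit
#'
#' Fits `level = A * exp(-k t)` by nonlinear least squares; offered as an
#' independent check on the log-linear estimate.
#'
#' @param data a [chase_data()] object.
#' @return list with `k` and `half_life`.
#' @export
fit_half_life_nls <- function(data) {
  f <- minpack.lm::nlsLM(levels ~ A * exp(-k * times),
                         data = list(levels = data$levels, times = data$times),
                         start = list(A = max(data$levels), k = 0.1))
  k <- stats::coef(f)[["k"]]
  list(k = k, half_life = log(2) / k)
}

#' Normalize densitometry band intensities
#'
#' Each band is divided by its lane's loading control, then the whole lane
#' series is scaled so the reference lane equals 1.0.
#'
#' @param band_intensities numeric band optical densities.
#' @param loading_controls positive loading-control densities, same length.
#' @param reference_index index of the reference lane (defaults to 1).
#' @return numeric vector of relative optical densities.
#' @export
normalize_densitometry <- function(band_intensities, loading_controls,
                                   reference_index = 1L) {
  stopifnot(length(band_intensities) == length(loading_controls))
  if (any(loading_controls <= 0)) stop("loading controls must be positive")
  ratio <- band_intensities / loading_controls
  if (ratio[reference_index] <= 0) stop("reference lane intensity must be positive")
  ratio / ratio[reference_index]
}

#' Call hits by mean inhibition threshold
#'
#' A compound is a hit when its mean inhibition fraction is strictly greater
#' than the threshold (default 0.60, the reporter-screen criterion).
#'
#' @param inhibition data frame with columns `compound_id` and `inhibition`
#'   (fractions in [0, 1]; replicate rows allowed).
#' @param threshold strict inhibition threshold (default 0.60).
#' @return data frame with `compound_id`, `mean_inhibition`, `hit`.
#' @export
call_hits <- function(inhibition, threshold = 0.60) {
  stopifnot(all(c("compound_id", "inhibition") %in% names(inhibition)),
            all(inhibition$inhibition >= 0 & inhibition$inhibition <= 1))
  agg <- stats::aggregate(inhibition ~ compound_id, inhibition, mean)
  names(agg)[2] <- "mean_inhibition"
  agg$hit <- agg$mean_inhibition > threshold
  agg[order(-agg$mean_inhibition), ]
}
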