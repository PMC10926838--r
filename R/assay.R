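# Reduction of raw assay readouts to experiment outcomes: QC gates,
# progress-curve rates, shifted-sigmoid T50 fits, Michaelis-Menten kinetics.

#' Reaction rate from a progress curve
#'
#' Ordinary least-squares slope of fluorescence versus time.
#'
#' @param times Timepoints (minutes), at least 3.
#' @param fluorescence Readings at \code{times}.
#' @return Slope (fluorescence units per minute).
#' @export
fit_progress_rate <- function(times, fluorescence) {
  if (length(times) < 3) stop("need at least 3 timepoints")
  unname(stats::coef(stats::lm(fluorescence ~ times))[2])
}

#' Fluorescein internal-standard well mask
#'
#' Wells whose fluorescein signal is less than 20\% of the run average are
#' assumed to reflect pipetting failure and are excluded (strict less-than:
#' a well exactly at the cutoff is kept). The mask is invariant to uniform
#' rescaling of all wells.
#'
#' @param values Per-well fluorescein readings (at least 2 wells).
#' @param frac Cutoff fraction of the run mean (default 0.2).
#' @return Logical inclusion mask.
#' @examples
#' qc_fluorescein(c(100, 100, 100, 15))
#' @export
qc_fluorescein <- function(values, frac = 0.2) {
  stopifnot(length(values) >= 2)
  values >= frac * mean(values)
}

#' PCR amplification check against control reactions
#'
#' Passes when the EvaGreen signal exceeds the midpoint between the mean
#' negative and mean positive control signals (strictly).
#'
#' @param signal Sample signal.
#' @param positive_controls,negative_controls Control signals (>= 1 each).
#' @return \code{TRUE}/\code{FALSE}.
#' @export
qc_pcr <- function(signal, positive_controls, negative_controls) {
  stopifnot(length(positive_controls) >= 1, length(negative_controls) >= 1)
  mp <- mean(positive_controls); mn <- mean(negative_controls)
  if (mn >= mp)
    stop("control distributions overlap (mean negative >= mean positive)")
  signal > (mp + mn) / 2
}

#' Background hydrolase activity check
#'
#' Cell-free extracts show residual hydrolase activity; an enzyme is only
#' called active when its best rate clears the background by a fold factor.
#'
#' @param max_rate Largest observed enzyme rate.
#' @param background_rate Extract background rate (>= 0).
#' @param fold Required fold over background (default 2).
#' @return \code{TRUE}/\code{FALSE}.
#' @export
background_activity_check <- function(max_rate, background_rate, fold = 2) {
  stopifnot(background_rate >= 0)
  max_rate >= fold * background_rate
}

#' Fit a shifted sigmoid to a thermal-challenge profile
#'
#' Models residual activity after a 10-minute heat challenge as
#' \code{rate(T) = b + A / (1 + exp((T - t50) / s))} and reports the curve
#' midpoint \code{t50} — the temperature at which half of the enzyme is
#' irreversibly inactivated. Initialization: \code{t50} at the temperature of
#' half-maximal rate, \code{s} at a tenth of the assayed range, \code{A} at
#' the rate span, \code{b} at the minimum rate. Quality is flagged
#' \code{"below_background"} when the best rate fails
#' [background_activity_check()], \code{"no_sigmoid"} when the optimizer
#' does not converge or the fitted amplitude is not meaningfully positive,
#' and \code{"ok"} otherwise.
#'
#' @param temperatures Incubation temperatures (deg C), at least 4 after QC.
#' @param rates Post-challenge rates at those temperatures.
#' @param background_rate Extract background rate used by the activity gate.
#' @param fold Fold-over-background threshold.
#' @return List of class \code{thermal_profile}: \code{t50}, \code{slope},
#'   \code{amplitude}, \code{baseline}, \code{quality}, plus the input
#'   profile.
#' @examples
#' Tg <- seq(40, 70, by = 3)
#' r <- 1 + 80 / (1 + exp((Tg - 55) / 2))
#' fit_t50(Tg, r)$t50
#' @export
fit_t50 <- function(temperatures, rates, background_rate = 0, fold = 2) {
  stopifnot(length(temperatures) == length(rates))
  if (length(temperatures) < 4)
    stop("need at least 4 (temperature, rate) pairs after QC")
  out <- list(t50 = NA_real_, slope = NA_real_, amplitude = NA_real_,
              baseline = NA_real_, quality = "no_sigmoid",
              temperatures = temperatures, rates = rates)
  class(out) <- "thermal_profile"
  if (background_rate > 0 &&
      !background_activity_check(max(rates), background_rate, fold)) {
    out$quality <- "below_background"
    return(out)
  }
  span <- diff(range(rates))
  half <- min(rates) + span / 2
  init <- list(t50 = unname(temperatures[which.min(abs(rates - half))]),
               s = diff(range(temperatures)) / 10,
               A = span, b = min(rates))
  fit <- tryCatch(
    minpack.lm::nlsLM(rates ~ b + A / (1 + exp((temperatures - t50) / s)),
                      start = init,
                      lower = c(t50 = -Inf, s = 1e-3, A = 0, b = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- stats::coef(fit)
  # a flat profile converges with negligible amplitude: not a sigmoid
  if (cf[["A"]] < 4 * stats::sd(rates - stats::predict(fit)) + 1e-12 ||
      cf[["t50"]] < min(temperatures) || cf[["t50"]] > max(temperatures))
    return(out)
  out$t50 <- cf[["t50"]]; out$slope <- cf[["s"]]
  out$amplitude <- cf[["A"]]; out$baseline <- cf[["b"]]
  out$quality <- "ok"
  out
}

#' @export
print.thermal_profile <- function(x, ...) {
  if (x$quality == "ok")
    cat(sprintf("T50 = %.2f C (slope %.2f, amplitude %.1f, baseline %.1f)\n",
                x$t50, x$slope, x$amplitude, x$baseline))
  else cat("thermal profile quality:", x$quality, "\n")
  invisible(x)
}

#' Reduce a raw assay plate to a thermal profile
#'
#' The full reduction pipeline for one design's plate: per-well progress
#' rates by linear regression, exclusion of wells failing the fluorescein
#' 20\% rule, then the shifted-sigmoid T50 fit.
#'
#' @param plate Tidy data frame with columns \code{well},
#'   \code{temperature}, \code{time}, \code{fluorescence},
#'   \code{fluorescein} (as from [simulate_assay_plate()]).
#' @inheritParams fit_t50
#' @return A \code{thermal_profile}.
#' @export
reduce_plate <- function(plate, background_rate = 0, fold = 2) {
  wells <- split(plate, plate$well)
  rate <- vapply(wells, function(w)
    fit_progress_rate(w$time, w$fluorescence), numeric(1))
  temp <- vapply(wells, function(w) w$temperature[1], numeric(1))
  fluo <- vapply(wells, function(w) w$fluorescein[1], numeric(1))
  keep <- qc_fluorescein(fluo)
  fit_t50(temp[keep], rate[keep], background_rate, fold)
}

#' Fit Michaelis-Menten kinetics to initial-rate data
#'
#' Nonlinear least squares of \code{v = kcat * E * S / (Km + S)} given the
#' enzyme concentration \code{E}. Replicate concentrations are averaged
#' before fitting. A fit whose \code{Km} lands outside 100x the assayed
#' concentration range (the sub-saturation regime where \code{v} is simply
#' proportional to \code{S}) is flagged unreliable.
#'
#' @param concentrations Substrate concentrations (uM), at least 4 distinct.
#' @param rates Initial rates (signal/s or 1/s consistent with \code{E}).
#' @param enzyme Enzyme concentration in the same units as kcat*E.
#' @return List of class \code{kinetic_fit}: \code{kcat}, \code{km},
#'   \code{reliable}, \code{rates} (averaged input data).
#' @examples
#' S <- 500 / 2^(0:7)
#' v <- 5 * 0.01 * S / (100 + S)
#' fit_michaelis_menten(S, v, enzyme = 0.01)
#' @export
fit_michaelis_menten <- function(concentrations, rates, enzyme = 1) {
  stopifnot(length(concentrations) == length(rates))
  agg <- stats::aggregate(list(v = rates), list(S = concentrations), mean)
  if (nrow(agg) < 4) stop("need at least 4 distinct concentrations")
  S <- agg$S; v <- agg$v
  fit <- NULL
  for (km0 in c(stats::median(S), max(S), 10 * max(S))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v ~ kcat * enzyme * S / (km + S),
                        start = list(kcat = max(v) / enzyme, km = km0),
                        lower = c(kcat = 1e-12, km = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # v proportional to S: kcat and km are not separately identifiable
    # (saturation never approached), only kcat/km is. Report the
    # sub-saturation bound km >> max(S) with the matching kcat, flagged.
    slope <- stats::coef(stats::lm(v ~ 0 + S))[[1]]
    km <- 100 * max(S)
    return(structure(list(kcat = slope * km / enzyme, km = km,
                          reliable = FALSE, rates = agg),
                     class = "kinetic_fit"))
  }
  cf <- stats::coef(fit)
  reliable <- cf[["km"]] <= 100 * max(S) && cf[["km"]] >= min(S) / 100
  structure(list(kcat = cf[["kcat"]], km = cf[["km"]], reliable = reliable,
                 rates = agg), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: kcat = %.3g /s, Km = %.3g uM%s\n",
              x$kcat, x$km,
              if (x$reliable) "" else "  [flagged unreliable]"))
  invisible(x)
}
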