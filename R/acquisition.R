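#' Acquisition configuration
#'
#' @param method One of \code{"random"}, \code{"ucb"}, \code{"ucb_positive"},
#'   \code{"expected_ucb"}.
#' @param z Confidence multiplier on the predictive sd; the default 1.96
#'   makes \code{z * sigma} the half-width of a 95\% prediction interval.
#' @param batch_size Designs chosen per round.
#' @param p_threshold Activity-probability gate for \code{ucb_positive}.
#' @param seed Seed used by the \code{random} method.
#' @return List of class \code{acq_cfg}.
#' @export
acq_cfg <- function(method = c("expected_ucb", "ucb", "ucb_positive",
                               "random"),
                    z = 1.96, batch_size = 1L, p_threshold = 0.5,
                    seed = NULL) {
  method <- match.arg(method)
  stopifnot(z >= 0, batch_size >= 1, p_threshold > 0, p_threshold < 1)
  structure(list(method = method, z = z, batch_size = as.integer(batch_size),
                 p_threshold = p_threshold, seed = seed),
            class = "acq_cfg")
}

#' Upper confidence bound score
#'
#' \code{mu + z * sigma}: the optimistic estimate that drives
#' exploration-exploitation trade-off in Bayesian optimization.
#'
#' @param mu Posterior mean(s).
#' @param sigma Predictive sd(s).
#' @param z Confidence multiplier (default 1.96).
#' @return Numeric score(s).
#' @examples
#' score_ucb(5, 2)  # 8.92
#' @export
score_ucb <- function(mu, sigma, z = 1.96) mu + z * sigma

#' Expected upper confidence bound score
#'
#' The activity-aware acquisition heuristic: (1) the pool minimum is
#' subtracted from every thermostability prediction so the baseline is zero,
#' (2) the confidence term \code{z * sigma} is added, and (3) the result is
#' multiplied by the classifier's activity probability. A predicted-dead
#' candidate therefore scores 0 no matter how optimistic its regression
#' posterior is.
#'
#' @param mu,sigma,p_active Per-candidate predictions over the current pool
#'   (the baseline minimum is taken over exactly these \code{mu}).
#' @param z Confidence multiplier.
#' @return Numeric scores, one per candidate; always non-negative.
#' @examples
#' score_expected_ucb(c(50, 60), c(1, 1), c(1, 0))
#' @export
score_expected_ucb <- function(mu, sigma, p_active, z = 1.96) {
  stopifnot(length(mu) > 0)
  ((mu - min(mu)) + z * sigma) * p_active
}

# per-pool scores for one method; returns list(score, note)
acquisition_scores <- function(pred, cfg) {
  with(pred, switch(cfg$method,
    ucb = score_ucb(mu, sigma, cfg$z),
    expected_ucb = score_expected_ucb(mu, sigma, p_active, cfg$z),
    ucb_positive = {
      s <- score_ucb(mu, sigma, cfg$z)
      ok <- p_active > cfg$p_threshold
      if (any(ok)) ifelse(ok, s, -Inf)
      else p_active          # fallback: chase activity information
    },
    random = stop("random method has no scores")))
}

#' Select the next design to test
#'
#' Applies the configured acquisition rule over the untested candidate pool:
#' \code{random} draws uniformly; \code{ucb} takes the largest
#' \code{mu + z sigma}; \code{ucb_positive} restricts to candidates with
#' \code{p_active > p_threshold} (falling back to the largest
#' \code{p_active} when none qualifies) and takes the best UCB among them;
#' \code{expected_ucb} takes the largest [score_expected_ucb()]. Ties break
#' to the lowest design index.
#'
#' @param model A [landscape_gp()] (ignored by \code{random}).
#' @param candidates Integer indices of the untested pool.
#' @param cfg An [acq_cfg()].
#' @param pred Optional precomputed predictions for \code{candidates}
#'   (a data frame from [predict.landscape_gp()]).
#' @return A single design index.
#' @export
select_next <- function(model, candidates, cfg = acq_cfg(), pred = NULL) {
  if (length(candidates) == 0) stop("empty candidate pool")
  if (cfg$method == "random")
    return(with_seed(cfg$seed, candidates[sample.int(length(candidates), 1)]))
  if (is.null(pred)) pred <- predict(model, designs = candidates)
  s <- acquisition_scores(pred, cfg)
  candidates[which.max(s)]   # which.max takes the first (lowest-index) max
}

#' Select a batch of designs by fantasy updates
#'
#' Iteratively selects \code{cfg$batch_size} designs: after each pick the
#' regressor is conditioned on a fantasy observation equal to the pick's
#' current posterior mean ([add_fantasy()]), which deflates \code{sigma}
#' around the pick and pushes subsequent picks elsewhere. The classifier and
#' the pool-minimum baseline of the expected-UCB score are recomputed against
#' the shrinking pool each iteration; fantasies are discarded afterwards. No
#' design is selected twice.
#'
#' @inheritParams select_next
#' @return Integer vector of \code{batch_size} distinct design indices, in
#'   selection order.
#' @export
select_batch <- function(model, candidates, cfg = acq_cfg()) {
  stopifnot(cfg$batch_size <= length(candidates))
  if (cfg$method == "random")
    return(with_seed(cfg$seed,
                     candidates[sample.int(length(candidates),
                                           cfg$batch_size)]))
  chosen <- integer(0)
  pool <- candidates
  work <- model
  for (b in seq_len(cfg$batch_size)) {
    pick <- select_next(work, pool, cfg)
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
    if (b < cfg$batch_size) work <- add_fantasy(work, pick)
  }
  chosen
}
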