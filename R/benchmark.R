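# Simulation benchmark harness: repeated in-silico engineering trials
# comparing acquisition strategies, plus the landscape-perception analytics.

as_truth <- function(dataset_or_oracle) {
  if (inherits(dataset_or_oracle, "oracle_landscape"))
    return(ground_truth(dataset_or_oracle))
  d <- dataset_or_oracle
  stopifnot(all(c("design", "active", "t50") %in% names(d)))
  d
}

#' Run repeated simulated protein-engineering trials
#'
#' The in-silico benchmark: for each method and each trial, the first design
#' is chosen at random and subsequent designs are chosen by the acquisition
#' rule over the untested pool, observing noise-free ground truth. An active
#' observation updates the regressor (and classifier); an inactive
#' observation updates the classifier only — except under plain \code{ucb},
#' which carries no classifier and simply learns nothing from an inactive
#' pick. A trial ends when the best observed thermostability reaches
#' \code{fraction} of the landscape maximum, or after \code{max_evaluations}
#' (censored). Every measured design counts as one evaluation, inactive
#' picks included.
#'
#' Trials use fixed kernel hyperparameters (no per-step marginal-likelihood
#' re-optimization) so that tens of thousands of surrogate refits stay
#' cheap; each trial draws its own deterministic child seed, so results are
#' reproducible regardless of execution order.
#'
#' @param dataset_or_oracle An \code{oracle_landscape} or a data frame
#'   \code{design, active, t50} of ground truth.
#' @param X Encoding of the candidate space.
#' @param methods Character vector of acquisition methods to compare.
#' @param n_trials Trials per method.
#' @param batch_size Designs per learning cycle (batches use fantasy
#'   updates).
#' @param seed Master seed.
#' @param fraction Success threshold as a fraction of the landscape maximum.
#' @param max_evaluations Evaluation cap per trial.
#' @param z Confidence multiplier for the UCB scores.
#' @param gram Optional precomputed \code{tcrossprod(X)} (computed once here
#'   if missing).
#' @return A list of \code{trial_set} objects, one per method. Each holds
#'   per-trial best-so-far \code{trajectories} (by evaluation),
#'   \code{evaluations} to threshold (\code{NA} when censored),
#'   \code{cycles} to threshold, and the landscape \code{max_t50}.
#' @export
simulate_trials <- function(dataset_or_oracle, X,
                            methods = c("random", "ucb", "ucb_positive",
                                        "expected_ucb"),
                            n_trials = 500, batch_size = 1L, seed = 1,
                            fraction = 0.9, max_evaluations = 500L,
                            z = 1.96, gram = NULL) {
  truth <- as_truth(dataset_or_oracle)
  n <- nrow(truth)
  gram <- gram %||% tcrossprod(X)
  max_t50 <- max(truth$t50, na.rm = TRUE)
  target <- fraction * max_t50
  cap <- min(max_evaluations, n)
  mcfg <- kernel_cfg(optimize_hyperparameters = FALSE)
  out <- list()
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    trajectories <- vector("list", n_trials)
    evals <- cycles <- rep(NA_integer_, n_trials)
    for (tr in seq_len(n_trials)) {
      res <- with_seed(child_seed(seed, (mi - 1L) * n_trials + tr),
                       run_single_trial(truth, X, gram, method, batch_size,
                                        target, cap, z, mcfg))
      trajectories[[tr]] <- res$best
      evals[tr] <- res$evals
      cycles[tr] <- res$cycles
    }
    out[[method]] <- structure(
      list(method = method, n_trials = n_trials, batch_size = batch_size,
           trajectories = trajectories, evaluations = evals,
           cycles = cycles, max_t50 = max_t50, fraction = fraction,
           cap = cap),
      class = "trial_set")
  }
  out
}

# one simulated engineering trial; RNG comes seeded from the caller
run_single_trial <- function(truth, X, gram, method, batch_size, target,
                             cap, z, mcfg) {
  n <- nrow(truth)
  untested <- seq_len(n)
  obs <- data.frame(design = integer(0), status = character(0),
                    t50 = numeric(0))
  best_seq <- numeric(0)
  best <- -Inf
  evals <- 0L
  cycle <- 0L
  hit_eval <- NA_integer_
  hit_cycle <- NA_integer_

  observe <- function(d) {
    evals <<- evals + 1L
    if (truth$active[d] && !is.na(truth$t50[d])) {
      best <<- max(best, truth$t50[d])
      obs <<- rbind(obs, data.frame(design = d, status = "active",
                                    t50 = truth$t50[d]))
    } else if (method != "ucb") {
      obs <<- rbind(obs, data.frame(design = d, status = "inactive",
                                    t50 = NA_real_))
    }
    best_seq[evals] <<- if (is.finite(best)) best else NA_real_
    if (is.na(hit_eval) && best >= target) {
      hit_eval <<- evals; hit_cycle <<- cycle
    }
  }

  if (method == "random") {
    ord <- sample(untested)
    for (d in ord) {
      cycle <- ((evals) %/% batch_size) + 1L
      observe(d)
      if (!is.na(hit_eval) || evals >= cap) break
    }
    return(list(best = best_seq, evals = hit_eval, cycles = hit_cycle))
  }

  cfg <- acq_cfg(method, z = z)
  first <- untested[sample.int(n, 1)]
  cycle <- 1L
  # first cycle: random lead pick, remaining batch members by the method
  lead_batch <- first
  if (batch_size > 1L) {
    model0 <- landscape_gp(X, obs, mcfg, gram = gram,
                           fit_classifier = method != "ucb")
    model0 <- add_fantasy(model0, first)
    pool <- setdiff(untested, first)
    cfg0 <- cfg; cfg0$batch_size <- min(batch_size - 1L, length(pool))
    lead_batch <- c(first, select_batch(model0, pool, cfg0))
  }
  for (d in lead_batch) observe(d)
  untested <- setdiff(untested, lead_batch)

  while (is.na(hit_eval) && evals < cap && length(untested)) {
    cycle <- cycle + 1L
    model <- landscape_gp(X, obs, mcfg, gram = gram,
                          fit_classifier = method != "ucb")
    cfg_r <- cfg
    cfg_r$batch_size <- min(batch_size, length(untested), cap - evals)
    batch <- select_batch(model, untested, cfg_r)
    for (d in batch) observe(d)
    untested <- setdiff(untested, batch)
  }
  list(best = best_seq, evals = hit_eval, cycles = hit_cycle)
}

#' @export
print.trial_set <- function(x, ...) {
  ev <- x$evaluations
  cat(sprintf("%s: %d trials, batch %d\n", x$method, x$n_trials,
              x$batch_size))
  cat(sprintf("  evaluations to %.0f%% of max: mean %.1f, median %.0f (%d censored at %d)\n",
              100 * x$fraction, mean(pmin(ev, x$cap, na.rm = TRUE),
                                     na.rm = TRUE),
              stats::median(ev, na.rm = TRUE), sum(is.na(ev)), x$cap))
  invisible(x)
}

#' Evaluations needed to reach a fraction of the landscape maximum
#'
#' Recomputed from the stored per-trial best-so-far trajectories, so any
#' threshold can be interrogated after the fact.
#'
#' @param trials A \code{trial_set}.
#' @param fraction Fraction of the known landscape maximum.
#' @return List: \code{evaluations} (per-trial counts, \code{NA} when the
#'   trial never got there), \code{censored} (count), \code{mean}
#'   (censored trials entered at the cap — a lower bound).
#' @export
evaluations_to_fraction <- function(trials, fraction = 0.9) {
  target <- fraction * trials$max_t50
  ev <- vapply(trials$trajectories, function(b) {
    i <- which(b >= target)
    if (length(i)) i[1] else NA_integer_
  }, integer(1))
  list(evaluations = ev, censored = sum(is.na(ev)),
       mean = mean(ifelse(is.na(ev), trials$cap, ev)))
}

#' Learning cycles to threshold across batch sizes
#'
#' Re-runs the trial simulation at each batch size and reports how many
#' design-test-learn cycles (rounds, not individual evaluations) were needed
#' to reach the threshold fraction of the landscape maximum.
#'
#' @inheritParams simulate_trials
#' @param method A single acquisition method.
#' @param batch_sizes Integer vector of batch sizes to sweep.
#' @return Data frame: \code{batch_size}, \code{mean_cycles},
#'   \code{median_cycles}, \code{censored}.
#' @export
batch_sweep <- function(dataset_or_oracle, X, method = "expected_ucb",
                        batch_sizes = c(1, 3, 6), n_trials = 100, seed = 1,
                        fraction = 0.9, max_evaluations = 500L,
                        gram = NULL) {
  gram <- gram %||% tcrossprod(X)
  rows <- lapply(seq_along(batch_sizes), function(i) {
    b <- batch_sizes[i]
    ts <- simulate_trials(dataset_or_oracle, X, methods = method,
                          n_trials = n_trials, batch_size = b,
                          seed = child_seed(seed, i), fraction = fraction,
                          max_evaluations = max_evaluations,
                          gram = gram)[[method]]
    cyc <- ts$cycles
    cap_cycles <- ceiling(ts$cap / b)
    data.frame(batch_size = b,
               mean_cycles = mean(ifelse(is.na(cyc), cap_cycles, cyc)),
               median_cycles = stats::median(cyc, na.rm = TRUE),
               censored = sum(is.na(cyc)))
  })
  do.call(rbind, rows)
}

#' Pearson correlation between two models' landscape perceptions
#'
#' @param model_a,model_b Fitted [landscape_gp()] models over the same
#'   candidate space.
#' @param designs Design indices (default: the full space).
#' @return Pearson r of the posterior-mean vectors (\code{NA} when either
#'   prediction has zero variance).
#' @export
landscape_correlation <- function(model_a, model_b, designs = NULL) {
  designs <- designs %||% seq_len(nrow(model_a$X))
  mu_a <- predict(model_a, designs = designs)$mu
  mu_b <- predict(model_b, designs = designs)$mu
  if (stats::sd(mu_a) == 0 || stats::sd(mu_b) == 0) return(NA_real_)
  stats::cor(mu_a, mu_b)
}

# percentile rank: fraction of the pool strictly below, midranks for ties
percentile_rank <- function(x, i) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  (sum(x < x[i]) + (sum(x == x[i]) - 1) / 2) / (n - 1)
}

#' Percentile ranks of the designs chosen each round
#'
#' For each campaign round, ranks every chosen design within that round's
#' candidate pool on four factors — expected-UCB score, predicted
#' thermostability (\code{mu}), model uncertainty (\code{sigma}) and
#' \code{p_active} — and averages over the batch. A rank near 1 means the
#' choices were exceptional for that factor. Requires a campaign run with
#' \code{log_predictions = TRUE}.
#'
#' @param campaign A \code{campaign}.
#' @return Data frame: \code{round}, \code{expected_ucb}, \code{mu},
#'   \code{sigma}, \code{p_active}.
#' @export
choice_percentiles <- function(campaign) {
  rounds <- Filter(function(e) !is.null(e$predictions), campaign$rounds)
  if (!length(rounds))
    stop("campaign was run without log_predictions = TRUE")
  z <- campaign$cfg$z
  do.call(rbind, lapply(rounds, function(e) {
    pool <- e$eligible
    pr <- e$predictions[pool, , drop = FALSE]
    scores <- cbind(
      expected_ucb = score_expected_ucb(pr$mu, pr$sigma, pr$p_active, z),
      mu = pr$mu, sigma = pr$sigma, p_active = pr$p_active)
    at <- match(e$chosen, pool)
    rk <- vapply(seq_len(ncol(scores)), function(j)
      mean(vapply(at, function(i) percentile_rank(scores[, j], i),
                  numeric(1)), na.rm = TRUE), numeric(1))
    ranks <- stats::setNames(rk, colnames(scores))
    data.frame(round = e$round, t(ranks))
  }))
}

#' Sliding-window uncertainty profile across the landscape
#'
#' Average model uncertainty as a function of where a design sits on the
#' thermostability axis (as placed by a reference model, typically the
#' unified landscape model): mean \code{sigma} over all designs whose
#' reference T50 falls within a sliding window.
#'
#' @param model Model whose uncertainty is profiled.
#' @param reference_t50 Per-design reference T50 values (e.g.
#'   \code{predict(unified)$mu}).
#' @param window Window width in deg C (default 10).
#' @param n_centers Number of window centers across the T50 range.
#' @return Data frame \code{center}, \code{mean_sigma}, \code{n}; windows
#'   containing no designs yield \code{NA} (a gap in the curve).
#' @export
uncertainty_profile <- function(model, reference_t50, window = 10,
                                n_centers = 50) {
  sig <- predict(model)$sigma
  stopifnot(length(sig) == length(reference_t50))
  centers <- seq(min(reference_t50), max(reference_t50),
                 length.out = n_centers)
  rows <- lapply(centers, function(ct) {
    inw <- abs(reference_t50 - ct) <= window / 2
    data.frame(center = ct,
               mean_sigma = if (any(inw)) mean(sig[inw]) else NA_real_,
               n = sum(inw))
  })
  do.call(rbind, rows)
}

#' Classical MDS embedding of a sequence space
#'
#' Embeds designs in the plane by classical multidimensional scaling of the
#' pairwise Hamming distance matrix — the standard map for visualizing
#' search trajectories over a combinatorial landscape. Deterministic up to
#' reflection/rotation; duplicate designs land on identical coordinates.
#'
#' @param space A \code{sequence_space}.
#' @param k Embedding dimension (default 2).
#' @return Design-by-k coordinate matrix.
#' @export
mds_embed <- function(space, k = 2) {
  D <- hamming_matrix(space)
  xy <- stats::cmdscale(D, k = k)
  colnames(xy) <- paste0("mds", seq_len(k))
  xy
}

#' Average best-so-far curves of several trial sets
#'
#' @param trial_sets List of \code{trial_set} (from [simulate_trials()]).
#' @param n_eval Curve length; per-trial curves are padded with their final
#'   value once a trial has stopped.
#' @return Matrix: evaluations x methods.
#' @export
mean_trajectories <- function(trial_sets, n_eval = NULL) {
  n_eval <- n_eval %||% max(vapply(trial_sets, function(ts)
    max(lengths(ts$trajectories)), integer(1)))
  vapply(trial_sets, function(ts) {
    acc <- vapply(ts$trajectories, function(b) {
      if (!length(b)) b <- NA_real_
      c(b, rep(b[length(b)], n_eval))[seq_len(n_eval)]
    }, numeric(n_eval))
    rowMeans(acc, na.rm = TRUE)
  }, numeric(n_eval))
}

#' @method plot trial_set
#' @export
plot.trial_set <- function(x, ...) {
  tr <- mean_trajectories(list(x))
  graphics::plot(seq_len(nrow(tr)), tr[, 1], type = "l", lwd = 2,
                 xlab = "sequence evaluations",
                 ylab = "mean best observed T50 (deg C)",
                 main = x$method, ...)
  graphics::abline(h = x$fraction * x$max_t50, lty = 2)
  invisible(x)
}
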