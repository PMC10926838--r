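# The autonomous design-test-learn loop and its exception-handling state
# machine.

#' Initialize the per-design record table
#' @param n Number of designs.
#' @return Data frame \code{design}, \code{state}, \code{strikes},
#'   \code{attempts}, \code{t50}.
#' @keywords internal
init_records <- function(n) {
  data.frame(design = seq_len(n), state = "untested", strikes = 0L,
             attempts = 0L, t50 = NA_real_, stringsAsFactors = FALSE)
}

#' Apply one experiment outcome to the design record table
#'
#' The exception-handling state machine of the closed loop:
#' \itemize{
#'   \item \code{active}: the design is finalized active with its measured
#'     T50 and leaves the experiment queue.
#'   \item \code{failed_qc}: the attempt is logged and the design is
#'     re-queued unchanged; QC failures never count toward the inactive
#'     call.
#'   \item \code{no_activity}: the first time, the design is marked
#'     inconclusive and re-queued (a lone negative may be an expression or
#'     assembly failure); the second time it is finalized inactive and
#'     becomes a classifier training label. A design must therefore be
#'     tested twice to be assigned inactive.
#' }
#' An outcome arriving for an already-finalized design is logged with a
#' warning; its data still enter the observation table, where consolidation
#' (latest status, averaged T50) decides what the model sees.
#'
#' @param records Record table from [init_records()].
#' @param outcome One-row outcome data frame (see [measure()]).
#' @return Updated record table.
#' @export
update_records <- function(records, outcome) {
  i <- outcome$design
  records$attempts[i] <- records$attempts[i] + 1L
  st <- records$state[i]
  if (st %in% c("active", "inactive"))
    warning("outcome received for finalized design ", i,
            "; consolidated as a duplicate measurement")
  if (outcome$result == "active") {
    records$state[i] <- "active"
    records$t50[i] <- outcome$t50
  } else if (outcome$result == "failed_qc") {
    # re-queued; an inconclusive design keeps its strike state
    if (st == "untested") records$state[i] <- "failed_requeued"
  } else if (outcome$result == "no_activity") {
    records$strikes[i] <- records$strikes[i] + 1L
    if (!st %in% c("active", "inactive"))
      records$state[i] <- if (records$strikes[i] >= 2L) "inactive"
                          else "inconclusive_once"
  }
  records
}

# observation rows the surrogate may train on, derived from the record table
records_to_obs <- function(records, raw) {
  act <- raw[raw$result == "active" & !is.na(raw$t50), , drop = FALSE]
  obs <- data.frame(design = act$design,
                    status = rep("active", nrow(act)), t50 = act$t50)
  inact <- records$design[records$state == "inactive"]
  if (length(inact))
    obs <- rbind(obs, data.frame(design = inact,
                                 status = rep("inactive", length(inact)),
                                 t50 = NA_real_))
  obs
}

#' In-process executor backed by the synthetic oracle
#' @param oracle An \code{oracle_landscape}.
#' @return A function \code{(design, round) -> outcome} suitable for
#'   [run_campaign()].
#' @export
oracle_executor <- function(oracle) {
  function(design, round) measure(oracle, design, round)
}

#' File-exchange executor
#'
#' Lets a real laboratory sit behind the loop: each request is appended to
#' \code{requests.csv} in \code{dir}, then \code{results.csv} is polled for a
#' row answering it (columns \code{design}, \code{result}, \code{t50}). On
#' timeout the outcome is recorded as \code{failed_qc}, which re-queues the
#' design.
#'
#' @param dir Exchange directory.
#' @param timeout,poll Seconds to wait overall and between polls.
#' @return An executor function \code{(design, round) -> outcome}.
#' @export
file_executor <- function(dir, timeout = 60, poll = 1) {
  req <- file.path(dir, "requests.csv")
  res <- file.path(dir, "results.csv")
  function(design, round) {
    row <- data.frame(design = design, round = round)
    utils::write.table(row, req, sep = ",", row.names = FALSE,
                       col.names = !file.exists(req), append = file.exists(req))
    deadline <- Sys.time() + timeout
    repeat {
      if (file.exists(res)) {
        r <- utils::read.csv(res)
        hit <- which(r$design == design)
        if (length(hit)) {
          r <- r[hit[length(hit)], ]
          return(data.frame(design = design, result = r$result,
                            t50 = if ("t50" %in% names(r)) r$t50 else NA_real_,
                            round = round))
        }
      }
      if (Sys.time() > deadline)
        return(data.frame(design = design, result = "failed_qc",
                          t50 = NA_real_, round = round))
      Sys.sleep(poll)
    }
  }
}

#' Run an autonomous design-test-learn campaign
#'
#' One agent, end to end: measure the seed designs (round 0), then for each
#' round fit the landscape surrogate on all consolidated observations,
#' select a batch among the designs not yet finalized, submit it to the
#' executor, pass the outcomes through the exception-handling state machine,
#' log everything, and repeat. Standard-UCB agents, which carry no activity
#' classifier, never ingest inactive observations; all other methods add
#' inactives to the classifier only. All randomness is driven by
#' deterministic per-round child seeds of \code{seed}, so a campaign is
#' exactly reproducible.
#'
#' @param space A \code{sequence_space}.
#' @param executor Function \code{(design, round) -> outcome}; see
#'   [oracle_executor()] and [file_executor()].
#' @param seeds Design indices measured in round 0; default: six designs
#'   drawn reproducibly from \code{seed}.
#' @param cfg An [acq_cfg()].
#' @param rounds Number of design-test-learn rounds after seeding.
#' @param model_cfg A [kernel_cfg()].
#' @param seed Master campaign seed.
#' @param X,gram Optional precomputed [encode_space()] / Gram matrix.
#' @param log_predictions Keep per-round predictions over the full space
#'   (needed by the decision analytics; costs memory on large spaces).
#' @return Object of class \code{campaign}: \code{rounds} (list of per-round
#'   logs), \code{records}, \code{raw} (every outcome), \code{obs}
#'   (consolidated observation table), \code{model} (final surrogate),
#'   \code{best_trajectory} (best observed T50 after each round, including
#'   the seed round), plus the configurations.
#' @examples
#' sp <- toy_space(c(2, 3, 2), aa_len = 10)
#' oc <- generate_landscape(sp, oracle_params(failure_prob = 0, seed = 3))
#' cam <- run_campaign(sp, oracle_executor(oc), seeds = c(1, 2),
#'                     cfg = acq_cfg("expected_ucb", batch_size = 2),
#'                     rounds = 3, seed = 11)
#' cam$best_trajectory
#' @export
run_campaign <- function(space, executor, seeds = NULL,
                         cfg = acq_cfg("expected_ucb", batch_size = 3L),
                         rounds = 20L, model_cfg = kernel_cfg(),
                         seed = 1, X = NULL, gram = NULL,
                         log_predictions = FALSE) {
  n <- nrow(space$designs)
  X <- X %||% encode_space(space)
  records <- init_records(n)
  raw <- data.frame(design = integer(0), result = character(0),
                    t50 = numeric(0), round = integer(0))
  if (is.null(seeds))
    seeds <- with_seed(child_seed(seed, 0L), sample.int(n, min(6L, n)))

  submit <- function(designs, round) {
    for (d in designs) {
      out <- tryCatch(executor(d, round), error = function(e)
        data.frame(design = d, result = "failed_qc", t50 = NA_real_,
                   round = round))
      raw <<- rbind(raw, out)
      records <<- update_records(records, out)
    }
  }

  with_seed(child_seed(seed, 0L), submit(seeds, 0L))
  best <- max(c(-Inf, raw$t50), na.rm = TRUE)
  log <- list(list(round = 0L, chosen = seeds,
                   outcomes = raw, best_so_far = best))

  model <- NULL
  for (r in seq_len(rounds)) {
    obs <- records_to_obs(records, raw)
    if (cfg$method == "ucb")
      obs <- obs[obs$status == "active", , drop = FALSE]
    model <- landscape_gp(X, obs, model_cfg, gram = gram,
                          fit_classifier = cfg$method != "ucb")
    eligible <- records$design[!records$state %in% c("active", "inactive")]
    if (length(eligible) == 0L) break
    k <- min(cfg$batch_size, length(eligible))
    cfg_r <- cfg; cfg_r$batch_size <- k
    with_seed(child_seed(seed, r), {
      batch <- select_batch(model, eligible, cfg_r)
      submit(batch, r)
    })
    best <- max(c(best, raw$t50[raw$round == r]), na.rm = TRUE)
    entry <- list(round = r, chosen = batch, eligible = eligible,
                  outcomes = raw[raw$round == r, , drop = FALSE],
                  best_so_far = best,
                  hyperparameters = coef(model),
                  n_obs = nrow(obs))
    if (log_predictions) entry$predictions <- predict(model)
    log[[length(log) + 1]] <- entry
  }

  obs <- records_to_obs(records, raw)
  final <- landscape_gp(X, obs, model_cfg, gram = gram)
  structure(list(rounds = log, records = records, raw = raw,
                 obs = consolidate_obs(obs), model = final,
                 best_trajectory = vapply(log, `[[`, numeric(1),
                                          "best_so_far"),
                 cfg = cfg, model_cfg = model_cfg, seed = seed,
                 seeds = seeds, space_n = n),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  tested <- sum(x$records$attempts > 0)
  cat("Design-test-learn campaign (", x$cfg$method, ", batch ",
      x$cfg$batch_size, ", ", length(x$rounds) - 1L, " rounds)\n", sep = "")
  cat(sprintf("  %d designs tested (%d attempts) of %d in the space (%.1f%%)\n",
              tested, sum(x$records$attempts), x$space_n,
              100 * tested / x$space_n))
  cat(sprintf("  outcomes: %d active, %d inactive, %d inconclusive\n",
              sum(x$records$state == "active"),
              sum(x$records$state == "inactive"),
              sum(x$records$state %in% c("inconclusive_once",
                                         "failed_requeued"))))
  cat(sprintf("  best observed T50: %.1f C (design %d)\n",
              max(x$records$t50, na.rm = TRUE),
              x$records$design[which.max(x$records$t50)]))
  invisible(x)
}

#' @method plot campaign
#' @export
plot.campaign <- function(x, ...) {
  graphics::plot(seq_along(x$best_trajectory) - 1L, x$best_trajectory,
                 type = "s", lwd = 2, xlab = "round",
                 ylab = "best observed T50 (deg C)",
                 main = "Landscape ascent", ...)
  graphics::points(x$raw$round, x$raw$t50, pch = 16, col = "grey50")
  invisible(x)
}

#' Fit the unified landscape model from several campaigns
#'
#' Pools every agent's consolidated observations and fits one surrogate on
#' the union — the retrospective best estimate of the ground-truth
#' landscape, used as the reference for per-agent perception analytics.
#'
#' @param campaigns List of \code{campaign} objects (or a single one).
#' @param X Encoding of the shared candidate space; defaults to the one
#'   inside the first campaign's model.
#' @param cfg A [kernel_cfg()].
#' @param gram Optional precomputed Gram matrix.
#' @return A [landscape_gp()].
#' @export
unified_model <- function(campaigns, X = NULL, cfg = kernel_cfg(),
                          gram = NULL) {
  if (inherits(campaigns, "campaign")) campaigns <- list(campaigns)
  stopifnot(length(campaigns) >= 1)
  X <- X %||% campaigns[[1]]$model$X
  obs <- do.call(rbind, lapply(campaigns, function(cam)
    records_to_obs(cam$records, cam$raw)))
  landscape_gp(X, obs, cfg, gram = gram)
}
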