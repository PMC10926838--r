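test_that("two-strike state machine finalizes inactive only after two
           no-activity results, with QC failures not counting", {
  rec <- seqbo:::init_records(5)
  out <- function(d, res, t50 = NA_real_)
    data.frame(design = d, result = res, t50 = t50, round = 1L)

  rec <- update_records(rec, out(1, "active", 62.4))
  expect_equal(rec$state[1], "active")
  expect_equal(rec$t50[1], 62.4)

  rec <- update_records(rec, out(2, "no_activity"))
  expect_equal(rec$state[2], "inconclusive_once")
  rec <- update_records(rec, out(2, "no_activity"))
  expect_equal(rec$state[2], "inactive")

  # three QC failures leave the design eligible with 3 logged attempts
  for (i in 1:3) rec <- update_records(rec, out(3, "failed_qc"))
  expect_equal(rec$state[3], "failed_requeued")
  expect_equal(rec$attempts[3], 3L)
  expect_equal(rec$strikes[3], 0L)

  # failed_qc between the two strikes does not reset or advance them
  rec <- update_records(rec, out(4, "no_activity"))
  rec <- update_records(rec, out(4, "failed_qc"))
  expect_equal(rec$state[4], "inconclusive_once")
  rec <- update_records(rec, out(4, "no_activity"))
  expect_equal(rec$state[4], "inactive")

  # outcome for a finalized design warns and is consolidated downstream
  expect_warning(update_records(rec, out(1, "no_activity")), "finalized")
})

test_that("scripted outcome sequences drive the agent's observation table
           correctly", {
  rec <- seqbo:::init_records(3)
  raw <- rbind(
    data.frame(design = 1, result = "active", t50 = 60, round = 0),
    data.frame(design = 2, result = "no_activity", t50 = NA, round = 0),
    data.frame(design = 2, result = "no_activity", t50 = NA, round = 1),
    data.frame(design = 3, result = "failed_qc", t50 = NA, round = 1))
  for (i in seq_len(nrow(raw)))
    rec <- update_records(rec, raw[i, ])
  obs <- seqbo:::records_to_obs(rec, raw)
  expect_setequal(obs$design[obs$status == "inactive"], 2)
  expect_setequal(obs$design[obs$status == "active"], 1)
  expect_false(3 %in% obs$design)   # a QC failure is not a label
})

test_that("campaigns are reproducible, monotone, and conserve designs", {
  sp <- toy_space(c(3, 3, 2), aa_len = 12, seed = 30)
  oc <- generate_landscape(sp, oracle_params(seed = 5))
  ex <- oracle_executor(oc)
  cam <- run_campaign(sp, ex, seeds = c(1, 3), rounds = 5,
                      cfg = acq_cfg("expected_ucb", batch_size = 2),
                      seed = 42)
  # best-so-far trajectory is non-decreasing
  tr <- cam$best_trajectory
  expect_true(all(diff(tr[is.finite(tr)]) >= -1e-12))
  # replay determinism: identical seed, identical selections and outcomes
  cam2 <- run_campaign(sp, ex, seeds = c(1, 3), rounds = 5,
                       cfg = acq_cfg("expected_ucb", batch_size = 2),
                       seed = 42)
  expect_identical(lapply(cam$rounds, `[[`, "chosen"),
                   lapply(cam2$rounds, `[[`, "chosen"))
  expect_identical(cam$raw, cam2$raw)
  # conservation: every submitted design is active, inactive or still queued
  tested <- unique(cam$raw$design)
  states <- cam$records$state[tested]
  expect_true(all(states %in% c("active", "inactive", "inconclusive_once",
                                "failed_requeued")))
  # no design was submitted after being finalized
  for (d in tested) {
    rounds_d <- cam$raw$round[cam$raw$design == d]
    results_d <- cam$raw$result[cam$raw$design == d]
    fin <- which(results_d == "active" |
                   cumsum(results_d == "no_activity") >= 2)
    if (length(fin) > 0) expect_equal(fin[1], length(results_d))
  }
})

test_that("a noiseless oracle with the optimum among the seeds is solved at
           round 0", {
  sp <- toy_space(c(3, 3), aa_len = 10, seed = 32)
  oc <- generate_landscape(sp, oracle_params(noise_sd = 0,
                                             failure_prob = 0, seed = 7))
  top <- which.max(ifelse(oc$active, oc$true_t50, -Inf))
  cam <- run_campaign(sp, oracle_executor(oc), seeds = c(top, 1),
                      rounds = 2, cfg = acq_cfg("ucb"), seed = 3)
  expect_equal(cam$best_trajectory[1], max(oc$true_t50[oc$active]))
  expect_true(all(cam$best_trajectory == cam$best_trajectory[1]))
})

test_that("executor errors are recorded as QC failures and re-queued", {
  sp <- toy_space(c(2, 2), aa_len = 8, seed = 34)
  flaky <- function(design, round) stop("robot offline")
  cam <- run_campaign(sp, flaky, seeds = c(1, 2), rounds = 1,
                      cfg = acq_cfg("expected_ucb", batch_size = 1),
                      seed = 9)
  expect_true(all(cam$raw$result == "failed_qc"))
  expect_true(all(cam$records$state[unique(cam$raw$design)] ==
                    "failed_requeued"))
})

test_that("file-exchange executor reads answers and times out to failed_qc", {
  dir <- tempfile(); dir.create(dir)
  write.csv(data.frame(design = 4, result = "active", t50 = 61.2),
            file.path(dir, "results.csv"), row.names = FALSE)
  ex <- file_executor(dir, timeout = 2, poll = 0.2)
  out <- ex(4, 1)
  expect_equal(out$result, "active")
  expect_equal(out$t50, 61.2)
  out2 <- ex(5, 1)
  expect_equal(out2$result, "failed_qc")
  reqs <- read.csv(file.path(dir, "requests.csv"))
  expect_equal(reqs$design, c(4, 5))
})

test_that("unified model trains on the union of the agents' data", {
  sp <- toy_space(c(3, 3), aa_len = 10, seed = 36)
  oc <- generate_landscape(sp, oracle_params(seed = 11, failure_prob = 0))
  cams <- lapply(1:2, function(s)
    run_campaign(sp, oracle_executor(oc), seeds = c(s, s + 2), rounds = 2,
                 cfg = acq_cfg("expected_ucb", batch_size = 2), seed = s))
  uni <- unified_model(cams, cfg = kernel_cfg(optimize_hyperparameters = FALSE))
  per_agent <- lapply(cams, function(cam)
    unique(cam$raw$design[cam$raw$result == "active"]))
  expect_setequal(uni$reg$idx, unique(unlist(per_agent)))
  # single campaign: same training set as that agent's final model
  uni1 <- unified_model(cams[[1]])
  expect_setequal(uni1$reg$idx, cams[[1]]$model$reg$idx)
  # perception correlation with itself is exactly 1
  expect_equal(landscape_correlation(uni, uni), 1)
})

test_that("seeded expected-UCB campaigns reliably climb to within 90% of
           the landscape maximum", {
  a <- arena()
  target <- 0.9 * max(ground_truth(a$oracle)$t50, na.rm = TRUE)
  ex <- oracle_executor(a$oracle)
  succ <- vapply(1:15, function(s) {
    cam <- run_campaign(a$space, ex,
                        cfg = acq_cfg("expected_ucb", batch_size = 3),
                        rounds = 20, seed = s, X = a$X, gram = a$gram)
    max(c(-Inf, cam$records$t50), na.rm = TRUE) >= target
  }, logical(1))
  expect_gte(mean(succ), 0.8)
  # fewer than 5% of the space is physically tested in a campaign
  cam <- run_campaign(a$space, ex,
                      cfg = acq_cfg("expected_ucb", batch_size = 3),
                      rounds = 20, seed = 99, X = a$X, gram = a$gram)
  expect_lt(sum(cam$records$attempts > 0) / nrow(a$space$designs), 0.05)
})
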