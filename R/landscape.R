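#' Kernel configuration for the landscape surrogate
#'
#' @param sigma0 Linear-kernel offset (prior standard deviation of the
#'   intercept); default 1.
#' @param noise_level Additive white-noise variance of the regressor, in
#'   squared degrees C; default 1.
#' @param optimize_hyperparameters Re-estimate \code{sigma0}/\code{noise_level}
#'   for the regressor by maximizing the log marginal likelihood (single
#'   deterministic L-BFGS-B start from the configured values). The
#'   classifier's kernel stays at the configured \code{sigma0}.
#' @param include_noise_in_sigma If \code{TRUE} (default) predictive
#'   \code{sigma} is a prediction-interval width including the white-noise
#'   term; if \code{FALSE} it is the latent-function (confidence) width.
#' @return List of class \code{kernel_cfg}.
#' @export
kernel_cfg <- function(sigma0 = 1, noise_level = 1,
                       optimize_hyperparameters = TRUE,
                       include_noise_in_sigma = TRUE) {
  stopifnot(sigma0 >= 0, noise_level > 0)
  structure(list(sigma0 = sigma0, noise_level = noise_level,
                 optimize_hyperparameters = optimize_hyperparameters,
                 include_noise_in_sigma = include_noise_in_sigma),
            class = "kernel_cfg")
}

#' Consolidate raw sequence-function observations
#'
#' Collapses repeated measurements of one design into a single row: the
#' latest record decides the active/inactive status (so an erroneous early
#' call is outweighed by later data rather than edited away), and
#' thermostability values are averaged over all measurements that reported
#' one.
#'
#' @param obs Data frame with columns \code{design} (integer index),
#'   \code{status} (\code{"active"}/\code{"inactive"}), \code{t50} (deg C,
#'   \code{NA} unless measured). Rows are taken to be in observation order.
#' @return One-row-per-design data frame.
#' @export
consolidate_obs <- function(obs) {
  stopifnot(all(c("design", "status") %in% names(obs)))
  if (is.null(obs$t50)) obs$t50 <- NA_real_
  if (nrow(obs) == 0)
    return(data.frame(design = integer(0), status = character(0),
                      t50 = numeric(0)))
  out <- do.call(rbind, lapply(split(obs, obs$design), function(d) {
    t50s <- d$t50[!is.na(d$t50)]
    data.frame(design = d$design[1],
               status = d$status[nrow(d)],
               t50 = if (length(t50s)) mean(t50s) else NA_real_)
  }))
  out <- out[order(out$design), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the multi-output Gaussian-process landscape model
#'
#' The surrogate at the heart of the design-test-learn loop: two Gaussian
#' processes sharing one sequence encoding. A Laplace-approximation GP
#' classifier (logistic link) is trained on all consolidated observations to
#' give the probability \code{p_active} that a sequence is functional, and an
#' exact GP regressor is trained on the active observations' thermostability
#' values to give a posterior mean \code{mu} and predictive standard
#' deviation \code{sigma}. Both use the linear Hamming kernel
#' \code{k(x, x') = sigma0^2 + x . x'}; the regressor adds white noise.
#' Regression runs on the raw deg-C scale under a zero prior mean, so the
#' posterior mean of a sequence dissimilar from every observation decays
#' toward 0 — an intentionally pessimistic prior about unexplored sequence
#' space that the acquisition rules rely on.
#'
#' @param X Binary encoding of the full candidate space (designs in rows),
#'   from [encode_space()]. Observation \code{design} indices address rows of
#'   \code{X}.
#' @param obs Observation data frame (see [consolidate_obs()]); consolidated
#'   internally.
#' @param cfg A [kernel_cfg()].
#' @param gram Optional precomputed \code{tcrossprod(X)}; supplies every
#'   kernel entry by lookup, which makes repeated refits during simulations
#'   cheap.
#' @param fit_classifier Set \code{FALSE} to skip the activity classifier
#'   (used by acquisition rules that ignore it).
#' @return Object of class \code{landscape_gp}. Key fields:
#'   \code{reg} (regressor fit or \code{NULL} when no active observation
#'   carries a t50), \code{cls} (classifier fit), \code{obs} (consolidated
#'   observations), \code{cfg} (with any optimized hyperparameters in
#'   \code{sigma0_reg}/\code{noise_level}).
#' @examples
#' sp <- toy_space(c(3, 3), aa_len = 8)
#' X <- encode_space(sp)
#' obs <- data.frame(design = c(1, 5, 9), status = "active",
#'                   t50 = c(52, 55, 61))
#' m <- landscape_gp(X, obs, kernel_cfg(optimize_hyperparameters = FALSE))
#' predict(m, designs = 1:3)
#' @export
landscape_gp <- function(X, obs, cfg = kernel_cfg(), gram = NULL,
                         fit_classifier = TRUE) {
  obs <- consolidate_obs(obs)
  if (any(obs$design < 1 | obs$design > nrow(X)))
    stop("observation design index outside the candidate space")
  model <- structure(list(X = X, gram = gram, obs = obs, cfg = cfg,
                          n_fantasy = 0L),
                     class = "landscape_gp")

  kmat <- function(i, j) {      # kernel block by design index, cls sigma0
    if (!is.null(gram)) cfg$sigma0^2 + gram[i, j, drop = FALSE]
    else linear_kernel(X[i, , drop = FALSE], X[j, , drop = FALSE],
                       cfg$sigma0)
  }

  # --- classifier on all consolidated rows
  # The Laplace classifier is fitted even on single-class data: the latent
  # then dips toward the observed class near the data and reverts to the
  # prior (p = 0.5) far away, so e.g. a run of early inactives steers the
  # agent away from dead regions instead of zeroing p_active globally.
  if (fit_classifier && nrow(obs) > 0) {
    t <- as.numeric(obs$status == "active")
    K <- kmat(obs$design, obs$design)
    model$cls <- c(list(type = "laplace", idx = obs$design),
                   gp_cls_fit(K, t))
  } else {
    model$cls <- list(type = "constant", p = 0.5)
  }

  # --- regressor on active rows with a measured t50
  # regression on the raw deg-C scale with a zero prior mean: sequences far
  # from every observation revert to mu ~ 0, i.e. dissimilarity is presumed
  # deleterious. This pessimistic prior is what makes the acquisition rules
  # exploit; it is also why the expected-UCB score re-bases mu on the pool
  # minimum.
  act <- obs[obs$status == "active" & !is.na(obs$t50), , drop = FALSE]
  if (nrow(act) > 0) {
    s0 <- cfg$sigma0; nl <- cfg$noise_level
    yc <- act$t50
    if (cfg$optimize_hyperparameters && nrow(act) >= 2) {
      Gtr <- if (!is.null(gram)) gram[act$design, act$design] else
        tcrossprod(X[act$design, , drop = FALSE])
      hp <- gp_reg_optimize(Gtr, yc, s0, nl)
      s0 <- hp$sigma0; nl <- hp$noise_level
    }
    Kr <- if (!is.null(gram)) s0^2 + gram[act$design, act$design] else
      linear_kernel(X[act$design, , drop = FALSE], sigma0 = s0)
    model$reg <- c(gp_reg_fit(Kr, yc, nl),
                   list(idx = act$design, center = 0, sigma0 = s0))
    model$cfg$sigma0_reg <- s0
    model$cfg$noise_level <- nl
  } else {
    model$reg <- NULL
    model$cfg$sigma0_reg <- cfg$sigma0
  }
  model
}

# prior diagonal k(x,x) for given designs under sigma0
prior_diag <- function(model, designs, sigma0) {
  if (!is.null(model$gram)) sigma0^2 + diag(model$gram)[designs]
  else sigma0^2 + rowSums(model$X[designs, , drop = FALSE]^2)
}

#' Predict over candidate designs
#'
#' @param object A [landscape_gp()] model.
#' @param designs Integer indices into the model's candidate space
#'   (default: all designs).
#' @param include_noise Override the configuration's
#'   \code{include_noise_in_sigma}.
#' @param ... Unused.
#' @return Data frame with \code{design}, \code{mu} (posterior mean, deg C),
#'   \code{sigma} (predictive sd, deg C), \code{p_active}. When no regression
#'   data exist, \code{mu} is 0 and \code{sigma} the prior sd, and the
#'   attribute \code{regression_available} is \code{FALSE} so acquisition
#'   rules can fall back to pure exploration.
#' @export
predict.landscape_gp <- function(object, designs = NULL,
                                 include_noise = NULL, ...) {
  m <- object
  if (is.null(designs)) designs <- seq_len(nrow(m$X))
  inc <- include_noise %||% m$cfg$include_noise_in_sigma

  # regression head
  if (!is.null(m$reg)) {
    s0 <- m$reg$sigma0
    Ks <- if (!is.null(m$gram)) s0^2 + m$gram[designs, m$reg$idx, drop = FALSE]
    else linear_kernel(m$X[designs, , drop = FALSE],
                       m$X[m$reg$idx, , drop = FALSE], s0)
    pr <- gp_reg_predict(m$reg, Ks, prior_diag(m, designs, s0), inc)
    mu <- pr$mu + m$reg$center
    sigma <- pr$sigma
    reg_ok <- TRUE
  } else {
    s0 <- m$cfg$sigma0
    mu <- rep(0, length(designs))
    v <- prior_diag(m, designs, s0)
    if (inc) v <- v + m$cfg$noise_level
    sigma <- sqrt(v)
    reg_ok <- FALSE
  }

  # classification head
  if (m$cls$type == "constant") {
    p <- rep(m$cls$p, length(designs))
  } else {
    s0c <- m$cfg$sigma0
    Ks <- if (!is.null(m$gram))
      s0c^2 + m$gram[designs, m$cls$idx, drop = FALSE]
    else linear_kernel(m$X[designs, , drop = FALSE],
                       m$X[m$cls$idx, , drop = FALSE], s0c)
    p <- gp_cls_predict(m$cls, Ks, prior_diag(m, designs, s0c))
  }
  out <- data.frame(design = designs, mu = mu, sigma = sigma, p_active = p)
  attr(out, "regression_available") <- reg_ok
  out
}

#' Condition the regressor on a fantasy observation
#'
#' Implements the batch-selection trick: the regressor is re-conditioned on a
#' hypothesized measurement at \code{design}, by default equal to its current
#' posterior mean, which leaves the posterior mean field unchanged but
#' shrinks the uncertainty there so the next batch pick diversifies. The
#' classifier and hyperparameters are untouched, and no hyperparameter
#' re-optimization happens.
#'
#' @param model A \code{landscape_gp}.
#' @param design Candidate index to fantasize.
#' @param y Fantasy target; default the current posterior mean at
#'   \code{design}.
#' @return Updated \code{landscape_gp} with \code{n_fantasy} incremented.
#' @export
add_fantasy <- function(model, design, y = NULL) {
  if (is.null(model$reg)) {
    # no regression data yet: fantasy seeds the regressor at the prior mean
    y <- y %||% 0
    center <- y
    idx <- design; yc <- 0
  } else {
    y <- y %||% predict(model, designs = design,
                        include_noise = FALSE)$mu
    center <- model$reg$center
    idx <- c(model$reg$idx, design)
    yc <- c(model$reg$y, y - center)
  }
  s0 <- model$cfg$sigma0_reg %||% model$cfg$sigma0
  Kr <- if (!is.null(model$gram)) s0^2 + model$gram[idx, idx, drop = FALSE]
  else linear_kernel(model$X[idx, , drop = FALSE], sigma0 = s0)
  model$reg <- c(gp_reg_fit(Kr, yc, model$cfg$noise_level),
                 list(idx = idx, center = center, sigma0 = s0))
  model$n_fantasy <- model$n_fantasy + 1L
  model
}

#' @export
print.landscape_gp <- function(x, ...) {
  n_act <- sum(x$obs$status == "active")
  cat("Multi-output GP landscape model\n")
  cat("  observations: ", nrow(x$obs), " (", n_act, " active, ",
      nrow(x$obs) - n_act, " inactive)\n", sep = "")
  cat(sprintf("  regressor: %s  [sigma0 = %.3g, noise = %.3g]\n",
              if (is.null(x$reg)) "unavailable (no active t50 data)"
              else paste0(length(x$reg$idx), " points"),
              x$cfg$sigma0_reg %||% x$cfg$sigma0, x$cfg$noise_level))
  cat("  classifier: ",
      if (x$cls$type == "constant")
        sprintf("constant p_active = %.2f", x$cls$p)
      else sprintf("Laplace approximation, %d points", length(x$cls$idx)),
      "\n", sep = "")
  if (x$n_fantasy) cat("  fantasy observations:", x$n_fantasy, "\n")
  invisible(x)
}

#' @method summary landscape_gp
#' @export
summary.landscape_gp <- function(object, ...) {
  print(object)
  if (!is.null(object$reg)) {
    pr <- predict(object, designs = object$reg$idx)
    resid <- object$obs$t50[match(object$reg$idx, object$obs$design)] - pr$mu
    cat(sprintf("  training RMSE: %.2f C\n", sqrt(mean(resid^2))))
  }
  invisible(object)
}

#' @method coef landscape_gp
#' @export
coef.landscape_gp <- function(object, ...) {
  c(sigma0_classifier = object$cfg$sigma0,
    sigma0_regressor = object$cfg$sigma0_reg %||% object$cfg$sigma0,
    noise_level = object$cfg$noise_level)
}

#' Stratified k-fold cross-validation of the landscape model
#'
#' Folds are stratified over active/inactive status. Within each fold the
#' classifier's calls (\code{p_active > 0.5}) are tallied against the true
#' status as TN/FN/FP/TP, and the Pearson correlation between predicted and
#' true thermostability is computed over the pooled true positives.
#'
#' @param X Candidate-space encoding.
#' @param obs Observation data frame.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the fold assignment.
#' @param cfg A [kernel_cfg()].
#' @return List of class \code{cv_report}: \code{accuracy},
#'   \code{pearson_r_tp} (\code{NA} when fewer than 2 true positives),
#'   \code{confusion} (named counts), \code{n}.
#' @export
cross_validate <- function(X, obs, k = 10, seed = 1, cfg = kernel_cfg()) {
  obs <- consolidate_obs(obs)
  n <- nrow(obs)
  stopifnot(n >= k)
  fold <- with_seed(seed, {
    f <- integer(n)
    for (cl in unique(obs$status)) {
      i <- which(obs$status == cl)
      f[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    f
  })
  conf <- c(TN = 0L, FN = 0L, FP = 0L, TP = 0L)
  tp_pred <- tp_true <- numeric(0)
  for (j in seq_len(k)) {
    test <- obs[fold == j, , drop = FALSE]
    train <- obs[fold != j, , drop = FALSE]
    m <- landscape_gp(X, train, cfg)
    pr <- predict(m, designs = test$design)
    called_active <- pr$p_active > 0.5
    truly_active <- test$status == "active"
    conf["TN"] <- conf["TN"] + sum(!truly_active & !called_active)
    conf["FN"] <- conf["FN"] + sum(truly_active & !called_active)
    conf["FP"] <- conf["FP"] + sum(!truly_active & called_active)
    conf["TP"] <- conf["TP"] + sum(truly_active & called_active)
    tp <- truly_active & called_active & !is.na(test$t50)
    tp_pred <- c(tp_pred, pr$mu[tp])
    tp_true <- c(tp_true, test$t50[tp])
  }
  r <- if (length(tp_true) >= 2 && stats::sd(tp_true) > 0 &&
           stats::sd(tp_pred) > 0)
    stats::cor(tp_pred, tp_true) else NA_real_
  structure(list(accuracy = unname((conf["TN"] + conf["TP"]) / n),
                 pearson_r_tp = r, confusion = conf, n = n),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-sequence cross-validation\n", x$n))
  cat(sprintf("  classification accuracy: %.1f%%\n", 100 * x$accuracy))
  cat(sprintf("  Pearson r (true positives): %s\n",
              if (is.na(x$pearson_r_tp)) "undefined"
              else sprintf("%.2f", x$pearson_r_tp)))
  cat("  confusion:", paste(names(x$confusion), x$confusion,
                            collapse = "  "), "\n")
  invisible(x)
}
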