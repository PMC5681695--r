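#' Cross-validation comparison of the MPL, PVL and WSLS models
#'
#' Estimates each model's out-of-sample predictive accuracy by k-fold
#' cross-validation over participants (twelve folds of seven participants in
#' the original 84-participant design). For each fold the hierarchical model
#' is fitted to the remaining participants; for each held-out participant,
#' `S` posterior hyperparameter draws are selected, one agent parameter set
#' `phi` is generated from each (a fresh `k` from `q` and fresh transformed
#' parameters from the population t4 law), and the participant's whole-
#' sequence probability is the average over draws of
#' `prod_t p_{y(t)}(t | x, phi)`, computed with log-sum-exp. The score is
#' `CV = -2 * sum_i log Pr(y_i | x_i)`; lower means higher predictive
#' accuracy.
#'
#' Cohorts not divisible by `folds` get folds of size `floor(N/folds)` with
#' the remainder spread one per fold.
#'
#' @param cohort A list of [trial_data] (or a `"labelled_dataset"`).
#' @param model One of `"mpl"`, `"pvl"`, `"wsls"`.
#' @param folds Number of folds (default 12).
#' @param S Hyperparameter draws per held-out participant.
#' @param control An [mcmc_control()] used for every per-fold fit.
#' @param k_max MPL memory-length bound.
#' @return An object of class `"cv_result"`: the total `cv` score,
#'   per-participant held-out log predictive densities `lpd`, the fold
#'   assignment, and the model name. Participants whose held-out probability
#'   underflows to zero get `-Inf` lpd and are flagged.
#' @examples
#' set.seed(5)
#' coh <- gen_population_cohort(example_population(), n = 8, n_trials = 40)
#' cv <- twelve_fold_cv(coh, "pvl", folds = 2, S = 50,
#'                      control = mcmc_control(chains = 1, iter = 300,
#'                                             warmup = 150))
#' cv$cv
#' @export
twelve_fold_cv <- function(cohort, model = c("mpl", "pvl", "wsls"),
                           folds = 12L, S = 1000L,
                           control = mcmc_control(chains = 1L, iter = 2000L,
                                                  warmup = 1000L),
                           k_max = 5L) {
  model <- match.arg(model)
  cohort <- cohort_trials(cohort)
  N <- length(cohort)
  stopifnot(folds >= 2L, folds <= N)
  fold_of <- rep(seq_len(folds), length.out = N)[sample.int(N)]

  lpd <- numeric(N)
  for (f in seq_len(folds)) {
    train <- cohort[fold_of != f]
    test_idx <- which(fold_of == f)
    fit <- switch(model,
      mpl = fit_hier_mpl(train, k_max = k_max, control = control),
      pvl = fit_hier_pvl(train, control = control),
      wsls = fit_hier_wsls(train, control = control))
    phi <- draw_phi(fit, S)
    for (i in test_idx)
      lpd[i] <- heldout_lpd(cohort[[i]], model, phi)
  }
  structure(list(model = model, cv = -2 * sum(lpd), lpd = lpd,
                 fold = fold_of, S = S,
                 flagged = which(!is.finite(lpd))),
            class = "cv_result")
}

# one agent parameter set per posterior hyperparameter draw
draw_phi <- function(fit, S) {
  nd <- nrow(fit$draws$mu)
  idx <- sample.int(nd, S, replace = TRUE)
  d <- ncol(fit$draws$mu)
  Om <- diag(d)
  off <- which(upper.tri(Om))
  phi <- matrix(NA_real_, S, d)
  ks <- integer(S)
  for (s in seq_len(S)) {
    j <- idx[s]
    Om[off] <- fit$draws$omega[j, ]
    Om[lower.tri(Om)] <- t(Om)[lower.tri(Om)]
    tau <- fit$draws$tau[j, ]
    R <- chol(diag(tau) %*% Om %*% diag(tau))
    phi[s, ] <- rmvt_chol(1L, fit$draws$mu[j, ], R)
    if (!is.null(fit$draws$q))
      ks[s] <- sample.int(fit$k_max + 1L, 1L, prob = fit$draws$q[j, ]) - 1L
  }
  list(z = phi, k = ks, model = fit$model)
}

heldout_lpd <- function(td, model, phi) {
  S <- nrow(phi$z)
  ll <- numeric(S)
  for (s in seq_len(S)) {
    z <- phi$z[s, ]
    ll[s] <- switch(model,
      mpl = cpp_mpl_loglik(td$outcomes, td$choices, phi$k[s],
                           stats::plogis(z[1L]), stats::plogis(z[2L]),
                           exp(z[3L])),
      pvl = cpp_mpl_loglik(td$outcomes, td$choices, 0L,
                           stats::plogis(z[1L]), 1, exp(z[2L])),
      wsls = cpp_wsls_loglik(td$outcomes, td$choices,
                             stats::plogis(z[1L]), stats::plogis(z[2L]),
                             stats::plogis(z[3L]), stats::plogis(z[4L])))
  }
  logsumexp(ll) - log(S)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s model: CV = %.1f (%d participants, %d folds)\n",
              toupper(x$model), x$cv, length(x$lpd), max(x$fold)))
  if (length(x$flagged))
    cat("  flagged participants with zero held-out probability:",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
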