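#' MPL, PVL and learning-WSLS agent specifications
#'
#' Constructors for the three choice models used throughout the package.
#'
#' The Markov pattern learning (MPL) agent keeps an expected-utility table
#' \eqn{E_j^\eta} over all \eqn{2^k} histories \eqn{\eta} of the previous
#' `k` outcomes. On each trial it chooses option 1 with softmax probability
#' \deqn{p_1(t) = 1 / (1 + e^{-\theta [E_1^\eta(t) - E_0^\eta(t)]}),}
#' then, after observing the outcome, updates the table with two decay
#' rates: entries for the realized history are reinforced as
#' \eqn{E_j \leftarrow A\rho E_j + u_j} while entries for every other
#' history decay as \eqn{E_j \leftarrow A E_j}. `A` is forgetting (decay of
#' all knowledge), `rho` is recency (down-weighting of old reinforcement on
#' the realized history), `theta` is the exploration-exploitation weight
#' (`0` = random choice, `Inf` = greedy argmax, ties resolving to 0.5).
#'
#' The PVL model is the `k = 0`, `rho = 1` restriction of the MPL model:
#' a single pair of expected utilities decaying at rate `A` with fictive
#' (both-option) updating and the same softmax rule.
#'
#' The learning win-stay/lose-shift (WSLS) agent tracks a stay-after-win
#' probability `p_w(t)` and a shift-after-loss probability `p_l(t)`, each
#' pulled towards 1 or decayed after every trial by its own learning rate.
#'
#' @param k Integer memory length, `0 <= k <= 5` by convention (any
#'   non-negative integer is accepted).
#' @param A Forgetting rate in `[0, 1]`.
#' @param rho Recency rate in `[0, 1]`.
#' @param theta Exploration-exploitation weight `>= 0`; `Inf` selects the
#'   greedy limit.
#' @return An object of class `"mpl_agent"` (also `"pvl_agent"` for
#'   [pvl_agent()]) or `"wsls_agent"`: a parameter list usable with
#'   [simulate_mpl()], [loglik_mpl()] and friends.
#' @examples
#' a <- mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3)
#' simulate_mpl(a, gen_repeating("01", 8))$probs
#' @export
mpl_agent <- function(k = 0L, A = 1, rho = 1, theta = 1) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 0L,
            length(A) == 1L, A >= 0, A <= 1,
            length(rho) == 1L, rho >= 0, rho <= 1,
            length(theta) == 1L, theta >= 0)
  structure(list(k = k, A = A, rho = rho, theta = theta),
            class = "mpl_agent")
}

#' @rdname mpl_agent
#' @export
pvl_agent <- function(A = 1, theta = 1) {
  a <- mpl_agent(k = 0L, A = A, rho = 1, theta = theta)
  class(a) <- c("pvl_agent", "mpl_agent")
  a
}

#' @rdname mpl_agent
#' @param p_w1,p_l1 Initial stay-after-win and shift-after-loss
#'   probabilities, in `[0, 1]`.
#' @param theta_w,theta_l Win and loss learning rates, in `[0, 1]`.
#' @export
wsls_agent <- function(p_w1 = 0.5, p_l1 = 0.5, theta_w = 0, theta_l = 0) {
  v <- c(p_w1, p_l1, theta_w, theta_l)
  stopifnot(length(v) == 4L, all(v >= 0), all(v <= 1))
  structure(list(p_w1 = p_w1, p_l1 = p_l1,
                 theta_w = theta_w, theta_l = theta_l),
            class = "wsls_agent")
}

#' @export
print.mpl_agent <- function(x, ...) {
  cat(sprintf("<%s> k = %d, A = %g, rho = %g, theta = %s\n",
              if (inherits(x, "pvl_agent")) "pvl_agent" else "mpl_agent",
              x$k, x$A, x$rho,
              if (is.finite(x$theta)) format(x$theta) else "Inf (greedy)"))
  invisible(x)
}

#' @export
print.wsls_agent <- function(x, ...) {
  cat(sprintf(
    "<wsls_agent> p_w(1) = %g, p_l(1) = %g, theta_w = %g, theta_l = %g\n",
    x$p_w1, x$p_l1, x$theta_w, x$theta_l))
  invisible(x)
}

#' @export
coef.mpl_agent <- function(object, ...)
  c(k = object$k, A = object$A, rho = object$rho, theta = object$theta)

#' @export
coef.wsls_agent <- function(object, ...)
  c(p_w1 = object$p_w1, p_l1 = object$p_l1,
    theta_w = object$theta_w, theta_l = object$theta_l)

#' Utility attributed to each option after a trial
#'
#' Both options are credited every trial (fictive learning): the option that
#' matched the outcome receives utility 1, the other 0.
#'
#' @param outcome Trial outcome, 0 or 1.
#' @return Named numeric vector `c(u0, u1)` with exactly one element 1.
#' @examples
#' outcome_utility(1)
#' @export
outcome_utility <- function(outcome) {
  outcome <- check_binary(outcome, "outcome")
  stopifnot(length(outcome) == 1L)
  c(u0 = 1 - outcome, u1 = outcome)
}

# ---- MPL step-wise interface -----------------------------------------------

#' Step-wise MPL agent state
#'
#' [mpl_state()] creates the initial learned state of an MPL agent: an
#' all-zero expected-utility table with one column per history of `k`
#' outcomes and an empty recent-outcome window. [mpl_choice_prob()] and
#' [mpl_update()] advance it one trial at a time; [simulate_mpl()] is the
#' fast full-sequence equivalent.
#'
#' @param k Integer memory length of the agent.
#' @return For [mpl_state()], an object of class `"mpl_state"` with
#'   elements `E` (2 x 2^k matrix, rows = options 0/1, columns = histories
#'   in binary order, oldest outcome in the least significant bit), `window`
#'   (the last `min(t - 1, k)` outcomes) and `k`.
#' @examples
#' st <- mpl_state(k = 1)
#' ag <- mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3)
#' st <- mpl_update(st, outcome = 0, params = ag)
#' st <- mpl_update(st, outcome = 1, params = ag)
#' mpl_choice_prob(st, ag)
#' @export
mpl_state <- function(k = 0L) {
  k <- as.integer(k)
  stopifnot(k >= 0L)
  structure(list(E = matrix(0, 2L, 2L^k), window = integer(0), k = k),
            class = "mpl_state")
}

history_index <- function(window, k) {
  # 1-based column index of history eta; NA while no full history exists
  if (length(window) < k) return(NA_integer_)
  sum(window * 2L^(seq_len(k) - 1L)) + 1L
}

#' @rdname mpl_state
#' @param state An `"mpl_state"` object.
#' @param params An [mpl_agent()] parameter object with the same `k`.
#' @return For [mpl_choice_prob()], the probability of choosing option 1.
#' @export
mpl_choice_prob <- function(state, params) {
  stopifnot(inherits(state, "mpl_state"), state$k == params$k)
  idx <- history_index(state$window, state$k)
  diff <- if (is.na(idx)) 0 else state$E[2L, idx] - state$E[1L, idx]
  if (!is.finite(params$theta)) {
    if (diff > 0) 1 else if (diff < 0) 0 else 0.5
  } else {
    stats::plogis(params$theta * diff)
  }
}

#' @rdname mpl_state
#' @param outcome Observed trial outcome, 0 or 1.
#' @return For [mpl_update()], the updated `"mpl_state"`.
#' @export
mpl_update <- function(state, outcome, params) {
  stopifnot(inherits(state, "mpl_state"), state$k == params$k)
  outcome <- check_binary(outcome, "outcome")
  stopifnot(length(outcome) == 1L)
  idx <- history_index(state$window, state$k)
  u <- outcome_utility(outcome)
  state$E <- params$A * state$E
  if (!is.na(idx)) {
    # the realized history was decayed by A above; complete A*rho + u
    state$E[, idx] <- params$rho * state$E[, idx] + u
  }
  state$window <- utils::tail(c(state$window, outcome), state$k)
  state
}

# ---- full-sequence simulators and likelihoods ------------------------------

#' Simulate an agent on an outcome sequence
#'
#' Replays the model's learning rule along `outcomes`, drawing a choice on
#' every trial from the current choice probability. Updates depend only on
#' the outcome sequence for MPL/PVL agents, and on both the outcome and the
#' drawn choice for WSLS agents.
#'
#' @param params An [mpl_agent()], [pvl_agent()] or [wsls_agent()] object.
#' @param outcomes Binary outcome vector.
#' @return A list with `choices` (0/1 integer vector) and `probs` (the
#'   per-trial probability of choosing option 1, before the draw).
#' @examples
#' set.seed(1)
#' sim <- simulate_mpl(mpl_agent(k = 1, A = 1, rho = 1, theta = Inf),
#'                     gen_repeating("01", 10))
#' sim$choices
#' @export
simulate_mpl <- function(params, outcomes) {
  stopifnot(inherits(params, "mpl_agent"))
  outcomes <- check_binary(outcomes, "outcomes")
  cpp_mpl_simulate(outcomes, params$k, params$A, params$rho, params$theta,
                   stats::runif(length(outcomes)))
}

#' @rdname simulate_mpl
#' @export
simulate_pvl <- function(params, outcomes) {
  stopifnot(params$k == 0L)
  simulate_mpl(params, outcomes)
}

#' @rdname simulate_mpl
#' @export
simulate_wsls <- function(params, outcomes) {
  stopifnot(inherits(params, "wsls_agent"))
  outcomes <- check_binary(outcomes, "outcomes")
  cpp_wsls_simulate(outcomes, params$p_w1, params$p_l1, params$theta_w,
                    params$theta_l, stats::runif(length(outcomes)))
}

#' @rdname simulate_mpl
#' @param object An agent object (for the [stats::simulate()] method).
#' @param nsim Number of simulated choice sequences.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @export
simulate.mpl_agent <- function(object, nsim = 1, seed = NULL,
                               outcomes, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_mpl(object, outcomes), simplify = FALSE)
}

#' @rdname simulate_mpl
#' @export
simulate.wsls_agent <- function(object, nsim = 1, seed = NULL,
                                outcomes, ...) {
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim, simulate_wsls(object, outcomes), simplify = FALSE)
}

#' Choice probability trace of an MPL agent
#'
#' Deterministic replay of the MPL learning rule along an outcome sequence,
#' returning the per-trial probability of choosing option 1 and the final
#' expected-utility table. Because MPL updates do not depend on the agent's
#' own choices, this trace is the exact likelihood kernel for any choice
#' sequence.
#'
#' @inheritParams simulate_mpl
#' @return A list with `probs` (length-T numeric) and `E` (final 2 x 2^k
#'   expected-utility table).
#' @examples
#' mpl_probs(mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3),
#'           gen_repeating("01", 8))$probs
#' @export
mpl_probs <- function(params, outcomes) {
  stopifnot(inherits(params, "mpl_agent"))
  outcomes <- check_binary(outcomes, "outcomes")
  tr <- cpp_mpl_trace(outcomes, params$k, params$A, params$rho, params$theta)
  list(probs = tr$p1, E = tr$E)
}

#' Log-likelihood of a choice sequence under an agent
#'
#' Replays the model along the participant's outcome sequence and sums the
#' log probability of each recorded choice. A choice that the model assigns
#' probability zero (possible only in the greedy `theta = Inf` limit)
#' yields `-Inf` rather than an error.
#'
#' @param params An agent parameter object.
#' @param data A [trial_data] object with both outcomes and choices.
#' @return Scalar log-likelihood.
#' @examples
#' td <- trial_data(c(0, 1, 0, 1), c(0, 1, 1, 1))
#' loglik_mpl(mpl_agent(k = 1, A = 0.9, rho = 0.9, theta = 0.3), td)
#' @export
loglik_mpl <- function(params, data) {
  stopifnot(inherits(params, "mpl_agent"), inherits(data, "trial_data"))
  if (is.null(data$choices)) stop("data has no choices", call. = FALSE)
  cpp_mpl_loglik(data$outcomes, data$choices, params$k, params$A, params$rho,
                 params$theta)
}

#' @rdname loglik_mpl
#' @export
loglik_pvl <- function(params, data) {
  stopifnot(params$k == 0L)
  loglik_mpl(params, data)
}

#' @rdname loglik_mpl
#' @export
loglik_wsls <- function(params, data) {
  stopifnot(inherits(params, "wsls_agent"), inherits(data, "trial_data"))
  if (is.null(data$choices)) stop("data has no choices", call. = FALSE)
  cpp_wsls_loglik(data$outcomes, data$choices, params$p_w1, params$p_l1,
                  params$theta_w, params$theta_l)
}

# ---- WSLS step-wise interface ----------------------------------------------

#' Step-wise learning-WSLS state
#'
#' @param params A [wsls_agent()] object supplying the initial stay/shift
#'   probabilities.
#' @return For [wsls_state()], an object of class `"wsls_state"` holding the
#'   current `p_w`, `p_l` and the previous choice/outcome (`NULL` on the
#'   first trial, where the choice probability defaults to 0.5).
#' @examples
#' ag <- wsls_agent(p_w1 = 0.8, p_l1 = 0.6, theta_w = 0.2, theta_l = 0.2)
#' st <- wsls_state(ag)
#' st <- wsls_update(st, outcome = 1, choice = 1, params = ag)
#' wsls_choice_prob(st)  # stay after a win on option 1
#' @export
wsls_state <- function(params = wsls_agent()) {
  structure(list(p_w = params$p_w1, p_l = params$p_l1,
                 prev_choice = NULL, prev_outcome = NULL),
            class = "wsls_state")
}

#' @rdname wsls_state
#' @param state A `"wsls_state"` object.
#' @return For [wsls_choice_prob()], the probability of choosing option 1.
#' @export
wsls_choice_prob <- function(state) {
  stopifnot(inherits(state, "wsls_state"))
  if (is.null(state$prev_choice)) return(0.5)
  if (state$prev_choice == state$prev_outcome) {
    if (state$prev_choice == 1) state$p_w else 1 - state$p_w
  } else {
    if (state$prev_choice == 1) 1 - state$p_l else state$p_l
  }
}

#' @rdname wsls_state
#' @param outcome,choice The trial's outcome and the agent's choice (0/1).
#' @return For [wsls_update()], the updated `"wsls_state"`.
#' @export
wsls_update <- function(state, outcome, choice, params) {
  stopifnot(inherits(state, "wsls_state"), inherits(params, "wsls_agent"))
  outcome <- check_binary(outcome, "outcome")
  choice <- check_binary(choice, "choice")
  if (choice == outcome) {
    state$p_w <- state$p_w + params$theta_w * (1 - state$p_w)
    state$p_l <- (1 - params$theta_l) * state$p_l
  } else {
    state$p_w <- (1 - params$theta_w) * state$p_w
    state$p_l <- state$p_l + params$theta_l * (1 - state$p_l)
  }
  state$prev_choice <- choice
  state$prev_outcome <- outcome
  state
}
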