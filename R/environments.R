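#' Outcome sequence generators
#'
#' Generators for the three outcome processes used in probability learning
#' experiments: independent Bernoulli draws (the standard task, with
#' majority probability `p = 0.7`), deterministic repeating patterns, and
#' binary Markov chains of arbitrary order.
#'
#' @param p Probability that a trial outcome is 1 (the majority option).
#' @param n_trials Sequence length, `>= 1`.
#' @return An integer 0/1 vector of length `n_trials`.
#' @examples
#' set.seed(1)
#' mean(gen_bernoulli(0.7, 300))
#' gen_repeating("01", 8)
#' @export
gen_bernoulli <- function(p, n_trials) {
  stopifnot(length(p) == 1L, is.finite(p), p >= 0, p <= 1, n_trials >= 1L)
  as.integer(stats::runif(n_trials) < p)
}

#' @rdname gen_bernoulli
#' @param pattern A nonempty binary string (e.g. `"001010001100"`) or 0/1
#'   vector, repeated cyclically.
#' @export
gen_repeating <- function(pattern, n_trials) {
  pattern <- parse_pattern(pattern)
  stopifnot(n_trials >= 1L)
  rep_len(pattern, n_trials)
}

parse_pattern <- function(pattern) {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1L, nzchar(pattern))
    pattern <- as.integer(strsplit(pattern, "")[[1L]])
  }
  if (length(pattern) < 1L)
    stop("'pattern' must be nonempty", call. = FALSE)
  check_binary(pattern, "pattern")
}

#' Binary Markov chain specification
#'
#' Defines an order-`L` binary Markov chain by the probability of outcome 1
#' after each of the `2^L` histories of the previous `L` outcomes.
#'
#' @param order Chain order `L >= 0`.
#' @param transition Numeric vector of length `2^L`: `transition[i]` is
#'   P(next = 1) after the history whose binary encoding is `i - 1` (oldest
#'   outcome in the least significant bit, matching the MPL agent's history
#'   table).
#' @param initial The first `L` outcomes of the chain (default: all 0), or a
#'   function of no arguments returning them.
#' @return An object of class `"markov_spec"`.
#' @examples
#' alternating <- markov_spec(1, transition = c(1, 0))
#' gen_markov(alternating, 8)
#' @export
markov_spec <- function(order, transition, initial = NULL) {
  order <- as.integer(order)
  stopifnot(order >= 0L, length(transition) == 2L^order,
            all(transition >= 0), all(transition <= 1))
  if (is.null(initial)) initial <- integer(order)
  if (!is.function(initial)) {
    initial <- check_binary(initial, "initial")
    stopifnot(length(initial) == order)
  }
  structure(list(order = order, transition = as.numeric(transition),
                 initial = initial),
            class = "markov_spec")
}

#' @rdname markov_spec
#' @param pattern A repeating binary pattern; the returned spec encodes its
#'   grammar rules (deterministic transitions of the minimal order that
#'   suffices to generate the pattern) and starts the chain at the
#'   pattern's own prefix.
#' @export
markov_from_pattern <- function(pattern) {
  pattern <- parse_pattern(pattern)
  P <- length(pattern)
  # smallest order L at which every observed length-L history determines
  # the next element of the cyclic pattern
  for (L in 0:P) {
    nxt <- rep(NA_real_, 2L^L)
    ok <- TRUE
    for (s in seq_len(P)) {
      h <- if (L == 0L) integer(0)
           else pattern[((s - L):(s - 1) - 1) %% P + 1L]  # cyclic history
      idx <- if (L == 0L) 1L else sum(h * 2L^(seq_len(L) - 1L)) + 1L
      val <- pattern[s]
      if (is.na(nxt[idx])) nxt[idx] <- val
      else if (nxt[idx] != val) { ok <- FALSE; break }
    }
    if (ok) {
      nxt[is.na(nxt)] <- 0  # unreachable histories
      return(markov_spec(L, nxt, initial = pattern[seq_len(L)]))
    }
  }
  stop("pattern admits no deterministic Markov representation", call. = FALSE)
}

#' @rdname markov_spec
#' @param spec A `"markov_spec"` object.
#' @param n_trials Sequence length.
#' @export
gen_markov <- function(spec, n_trials) {
  stopifnot(inherits(spec, "markov_spec"), n_trials >= 1L)
  L <- spec$order
  init <- if (is.function(spec$initial)) check_binary(spec$initial(), "initial")
          else spec$initial
  stopifnot(length(init) == L)
  x <- integer(n_trials)
  n0 <- min(L, n_trials)
  if (n0 > 0L) x[seq_len(n0)] <- init[seq_len(n0)]
  if (n_trials > L) {
    u <- stats::runif(n_trials - L)
    for (t in (L + 1L):n_trials) {
      idx <- if (L == 0L) 1L
             else sum(x[(t - L):(t - 1L)] * 2L^(seq_len(L) - 1L)) + 1L
      x[t] <- as.integer(u[t - L] < spec$transition[idx])
    }
  }
  x
}
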