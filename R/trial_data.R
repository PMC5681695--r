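#' Trial-level data for one participant
#'
#' Bundles one participant's aligned outcome and choice sequences from a
#' two-alternative probability learning task. Outcomes and choices are coded
#' so that 1 is the majority option (the option rewarded with probability
#' p > 0.5); raw left/right data must be recoded before entry.
#'
#' @param outcomes Integer vector of 0/1 trial outcomes, length T >= 1.
#' @param choices Optional integer vector of 0/1 predictions, same length as
#'   `outcomes`. May be `NULL` before simulation.
#' @param id Participant identifier (scalar, coerced to character).
#'
#' @return An object of class `"trial_data"`: a list with elements
#'   `id`, `outcomes`, `choices` and `n_trials`.
#' @examples
#' td <- trial_data(c(0, 1, 1, 0, 1), c(1, 1, 0, 1, 1), id = "p1")
#' td
#' @export
trial_data <- function(outcomes, choices = NULL, id = "1") {
  outcomes <- check_binary(outcomes, "outcomes")
  if (length(outcomes) < 1L)
    stop("'outcomes' must contain at least one trial", call. = FALSE)
  if (!is.null(choices)) {
    choices <- check_binary(choices, "choices")
    if (length(choices) != length(outcomes))
      stop("'choices' and 'outcomes' must have the same length", call. = FALSE)
  }
  structure(
    list(id = as.character(id)[1L], outcomes = outcomes, choices = choices,
         n_trials = length(outcomes)),
    class = "trial_data")
}

check_binary <- function(v, what) {
  if (is.logical(v)) v <- as.integer(v)
  if (!is.numeric(v) || anyNA(v) || any(v != 0L & v != 1L))
    stop(sprintf("'%s' must be a vector of 0/1 values", what), call. = FALSE)
  as.integer(v)
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> participant %s: %d trials%s\n", x$id, x$n_trials,
              if (is.null(x$choices)) " (outcomes only)" else ""))
  cat("  outcomes:", paste(utils::head(x$outcomes, 20L), collapse = ""),
      if (x$n_trials > 20L) "..." else "", "\n")
  if (!is.null(x$choices))
    cat("  choices: ", paste(utils::head(x$choices, 20L), collapse = ""),
        if (x$n_trials > 20L) "..." else "", "\n")
  invisible(x)
}

#' Read and write trial-level CSV files
#'
#' The trial table format has four columns: `participant_id`, `trial`
#' (1-based, contiguous per participant), `outcome` and `choice` (both
#' strictly 0/1, majority-coded).
#'
#' @param path Path to a CSV file.
#' @return `read_trials()` returns a list of [trial_data] objects, one per
#'   participant, trial-sorted. `write_trials()` invisibly returns `path`.
#' @examples
#' cohort <- list(trial_data(c(0, 1, 1), c(1, 1, 0), id = "a"),
#'                trial_data(c(1, 1, 0), c(1, 0, 1), id = "b"))
#' f <- tempfile(fileext = ".csv")
#' write_trials(cohort, f)
#' identical(read_trials(f), cohort)
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial", "outcome", "choice")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("trial file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("outcome", "choice")) {
    bad <- which(!(df[[col]] %in% c(0L, 1L)))
    if (length(bad))
      stop(sprintf("non-binary '%s' value at data row %d", col, bad[1L]),
           call. = FALSE)
  }
  ids <- unique(df$participant_id)
  lapply(ids, function(pid) {
    sub <- df[df$participant_id == pid, , drop = FALSE]
    sub <- sub[order(sub$trial), , drop = FALSE]
    if (!identical(as.integer(sub$trial), seq_len(nrow(sub))))
      stop(sprintf(
        "participant %s: trial indices must be contiguous starting at 1",
        pid), call. = FALSE)
    trial_data(sub$outcome, sub$choice, id = pid)
  })
}

#' @rdname read_trials
#' @param cohort A list of [trial_data] objects (with choices present).
#' @export
write_trials <- function(cohort, path) {
  cohort <- as_cohort(cohort)
  rows <- lapply(cohort, function(td) {
    if (is.null(td$choices))
      stop("participant ", td$id, " has no choices to write", call. = FALSE)
    data.frame(participant_id = td$id, trial = seq_len(td$n_trials),
               outcome = td$outcomes, choice = td$choices,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# accept a single trial_data or a list of them
as_cohort <- function(cohort) {
  if (inherits(cohort, "trial_data")) return(list(cohort))
  if (!is.list(cohort) || !all(vapply(cohort, inherits, TRUE, "trial_data")))
    stop("expected a trial_data object or a list of them", call. = FALSE)
  cohort
}
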