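#' Construct a single-subject choice dataset
#'
#' Bundles one subject's trial design and binary accept/reject vector for one
#' task into a validated `choice_dataset` object. In the risky task each trial
#' offers a gamble (win `win_amount` with probability `win_probability`,
#' nothing otherwise) against a certain `reference_amount`; in the
#' intertemporal task each trial offers `delayed_amount` after `delay_days`
#' against an immediate `reference_amount`.
#'
#' @param task `"risky"` or `"intertemporal"`.
#' @param trials data frame of trial parameters. For `"risky"`: columns
#'   `win_probability` (in (0,1]) and `win_amount` (> 0). For
#'   `"intertemporal"`: columns `delayed_amount` (> 0) and `delay_days`
#'   (>= 0).
#' @param choices integer/numeric vector of 0/1, one per trial; 1 means the
#'   variable (risky or delayed) option was accepted, 0 the fixed option.
#' @param reference_amount the fixed option's amount in dollars (default 20,
#'   the value used in both tasks of the study design this package models).
#' @return An object of class `choice_dataset`: a list with elements `task`,
#'   `trials`, `choices`, `reference_amount`.
#' @examples
#' tr <- data.frame(win_probability = c(0.47, 0.8), win_amount = c(84, 30))
#' choice_dataset("risky", tr, c(1, 0))
#' @export
choice_dataset <- function(task, trials, choices, reference_amount = 20) {
  task <- match.arg(task, c("risky", "intertemporal"))
  trials <- as.data.frame(trials)
  needed <- if (task == "risky") c("win_probability", "win_amount") else
    c("delayed_amount", "delay_days")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trials is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (task == "risky") {
    p <- trials$win_probability
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
      stop("win_probability must lie in (0, 1]")
    if (any(!is.finite(trials$win_amount)) || any(trials$win_amount <= 0))
      stop("win_amount must be > 0")
  } else {
    if (any(!is.finite(trials$delayed_amount)) || any(trials$delayed_amount <= 0))
      stop("delayed_amount must be > 0")
    if (any(!is.finite(trials$delay_days)) || any(trials$delay_days < 0))
      stop("delay_days must be >= 0")
  }
  choices <- as.numeric(choices)
  if (length(choices) != nrow(trials))
    stop("length(choices) must equal nrow(trials)")
  if (any(!choices %in% c(0, 1)))
    stop("choices must be 0/1")
  if (!is.numeric(reference_amount) || length(reference_amount) != 1 ||
      reference_amount <= 0)
    stop("reference_amount must be a single positive number")
  structure(
    list(task = task, trials = trials, choices = choices,
         reference_amount = reference_amount),
    class = "choice_dataset"
  )
}

#' @method print choice_dataset
#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("<choice_dataset> %s task: %d trials, %.0f%% accepted, $%.2f reference\n",
              x$task, length(x$choices), 100 * mean(x$choices),
              x$reference_amount))
  invisible(x)
}

#' Read subject choice data from a delimited text file
#'
#' Expects one row per trial with columns `subject_id`, `task`, `choice`
#' (0/1), and the trial parameters: `win_probability` + `amount` for risky
#' rows, `delay_days` + `amount` for intertemporal rows.
#'
#' @param path CSV/TSV file (delimiter inferred from the extension: `.tsv`
#'   reads tab-separated, anything else comma-separated).
#' @param reference_amount fixed-option amount applied to every dataset.
#' @return Named list of lists: `result[[subject_id]][[task]]` is a
#'   [choice_dataset()].
#' @seealso [write_choices()]
#' @export
read_choices <- function(path, reference_amount = 20) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  needed <- c("subject_id", "task", "choice")
  if (!all(needed %in% names(df)))
    stop("choice file must have columns: ", paste(needed, collapse = ", "))
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df[df$subject_id == sid, , drop = FALSE]
    out[[as.character(sid)]] <- lapply(
      stats::setNames(unique(sub$task), unique(sub$task)),
      function(tk) {
        rows <- sub[sub$task == tk, , drop = FALSE]
        trials <- if (tk == "risky") {
          data.frame(win_probability = rows$win_probability,
                     win_amount = rows$amount)
        } else {
          data.frame(delayed_amount = rows$amount,
                     delay_days = rows$delay_days)
        }
        choice_dataset(tk, trials, rows$choice, reference_amount)
      })
  }
  out
}

#' Write subject choice data to a delimited text file
#'
#' Inverse of [read_choices()]: flattens a list of per-subject, per-task
#' [choice_dataset()]s into one long table.
#'
#' @param datasets named list (subject id) of named lists (task) of
#'   [choice_dataset()] objects.
#' @param path output file; `.tsv` writes tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_choices <- function(datasets, path) {
  rows <- list()
  for (sid in names(datasets)) {
    for (tk in names(datasets[[sid]])) {
      ds <- datasets[[sid]][[tk]]
      rows[[length(rows) + 1L]] <- if (tk == "risky") {
        data.frame(subject_id = sid, task = tk,
                   win_probability = ds$trials$win_probability,
                   delay_days = NA_real_,
                   amount = ds$trials$win_amount,
                   choice = ds$choices)
      } else {
        data.frame(subject_id = sid, task = tk,
                   win_probability = NA_real_,
                   delay_days = ds$trials$delay_days,
                   amount = ds$trials$delayed_amount,
                   choice = ds$choices)
      }
    }
  }
  df <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
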