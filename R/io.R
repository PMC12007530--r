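# CSV interchange for choice tables, ground truths, posterior draws and
# reports. Artifacts carry a provenance header as '#' comment lines (package
# version, seed, a config hash) and are deterministic for a given seed.

.CHOICE_COLS <- c("subject_id", "condition", "i_ero", "trial_index",
                  "ll_amount", "delay_days", "choice")

# small FNV-1a string hash (hex), for provenance headers
.config_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = ";")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

.provenance <- function(seed = NULL, extra = character()) {
  c(paste0("# offsetTD ", as.character(utils::packageVersion("offsetTD"))),
    if (!is.null(seed)) paste0("# seed=", seed),
    extra)
}

#' Write a choice table as CSV
#'
#' Long format, one row per trial, with a provenance comment header. The file
#' round-trips losslessly through [read_choice_table()].
#'
#' @param data Choice data frame with the standard columns.
#' @param path Output file.
#' @param seed Optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_choice_table <- function(data, path, seed = NULL) {
  miss <- setdiff(.CHOICE_COLS, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- data[, .CHOICE_COLS]
  d$ll_amount <- sprintf("%.2f", d$ll_amount)
  hash <- .config_hash(nrow(d), unique(d$subject_id), seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed, paste0("# config_hash=", hash)), con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a choice table from CSV
#'
#' Validates the schema strictly: the exact header, choice tokens in
#' `{SS, LL, INVALID}`, no duplicated (subject, condition, trial) rows, and
#' condition labels consistent with the `i_ero` indicator. Errors name the
#' offending row.
#'
#' @param path CSV file written by [write_choice_table()] (or matching its
#'   schema); `#` comment lines are ignored.
#' @return A validated choice data frame.
#' @export
read_choice_table <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(.CHOICE_COLS, names(d))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!d$choice %in% c("SS", "LL", "INVALID"))
  if (length(bad))
    stop(sprintf("unknown choice token '%s' in row %d", d$choice[bad[1]],
                 bad[1]), call. = FALSE)
  bad <- which(!d$i_ero %in% c(0L, 1L))
  if (length(bad))
    stop(sprintf("invalid i_ero value in row %d", bad[1]), call. = FALSE)
  expect <- ifelse(d$i_ero == 1L, "erotic", "neutral")
  bad <- which(d$condition != expect)
  if (length(bad))
    stop(sprintf("condition/i_ero mismatch in row %d", bad[1]),
         call. = FALSE)
  key <- paste(d$subject_id, d$condition, d$trial_index)
  if (anyDuplicated(key))
    stop(sprintf("duplicated (subject, condition, trial_index) in row %d",
                 which(duplicated(key))[1]), call. = FALSE)
  if (any(!is.finite(d$ll_amount)) || any(!is.finite(d$delay_days)))
    stop("non-numeric ll_amount or delay_days", call. = FALSE)
  message(sprintf("read %d trials from %d subject(s), %d INVALID",
                  nrow(d), length(unique(d$subject_id)),
                  sum(d$choice == "INVALID")))
  d
}

#' Write the ground-truth sidecar of a simulated cohort
#'
#' Long format (`subject_id`, `parameter`, `true_value`), for parameter
#' recovery checks against a fit of the simulated data.
#'
#' @param cohort A `"td_cohort"` from [simulate_cohort()].
#' @param path Output CSV.
#' @param seed Optional seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(cohort, path, seed = NULL) {
  stopifnot(inherits(cohort, "td_cohort"))
  s <- cohort$truth$subjects
  num <- names(s)[vapply(s, is.numeric, logical(1))]
  long <- do.call(rbind, lapply(num, function(p)
    data.frame(subject_id = s$subject_id, parameter = p,
               true_value = s[[p]])))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(seed), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write posterior draws as a tidy CSV
#'
#' Long format: `chain`, `iteration`, `parameter`, `value`.
#'
#' @param fit A `"td_fit"` object.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "td_fit"))
  kept <- nrow(fit$draws) / fit$chains
  long <- data.frame(
    chain = rep(fit$chain, times = ncol(fit$draws)),
    iteration = rep(rep(seq_len(kept), fit$chains), times = ncol(fit$draws)),
    parameter = rep(colnames(fit$draws), each = nrow(fit$draws)),
    value = as.vector(fit$draws))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenance(fit$seed,
                         paste0("# variant=", fit$variant)), con)
  utils::write.csv(long, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read posterior draws written by [write_draws()]
#'
#' @param path CSV file.
#' @return A list with `draws` (iterations x parameters matrix, chains
#'   stacked) and `chain` (integer index per row).
#' @export
read_draws <- function(path) {
  long <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  pars <- unique(long$parameter)
  chains <- sort(unique(long$chain))
  rows <- split(seq_len(nrow(long)), long$parameter)
  first <- long[rows[[pars[1]]], ]
  draws <- vapply(pars, function(p) long$value[rows[[p]]],
                  numeric(nrow(first)))
  list(draws = draws, chain = first$chain)
}

#' Write a convergence report as JSON
#'
#' @param fit A `"td_fit"` object with a convergence report.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_convergence_json <- function(fit, path) {
  stopifnot(inherits(fit, "td_fit"))
  cv <- fit$convergence
  if (is.null(cv)) stop("fit has no convergence report", call. = FALSE)
  jsonlite::write_json(
    list(pass = attr(cv, "pass"), threshold = fit$rhat_threshold,
         max_rhat = max(cv$rhat, na.rm = TRUE),
         parameters = cv),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
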