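# Subject exclusion for degenerate choice patterns.

#' Exclude subjects with degenerate choice patterns
#'
#' A subject whose minority-option count over the valid trials of both
#' conditions falls below `min_minority_choices` (default 2; e.g. a single SS
#' choice across both sessions) carries almost no information about the
#' trade-off the model estimates and is excluded. Exclusions are reported via
#' `message()`.
#'
#' @param data Long-format choice data frame.
#' @param min_minority_choices Minimum count of the rarer option (default 2);
#'   0 excludes nobody.
#' @return List with `kept` (the filtered data frame) and `excluded`
#'   (character vector of subject ids).
#' @export
exclude_degenerate_subjects <- function(data, min_minority_choices = 2) {
  if (min_minority_choices < 0)
    stop("`min_minority_choices` must be >= 0", call. = FALSE)
  d <- data[data$choice != "INVALID", , drop = FALSE]
  counts <- aggregate(cbind(ss = d$choice == "SS", ll = d$choice == "LL"),
                      by = list(subject_id = d$subject_id), FUN = sum)
  minority <- pmin(counts$ss, counts$ll)
  excl <- as.character(counts$subject_id[minority < min_minority_choices])
  if (length(excl) == length(unique(data$subject_id)))
    stop("all subjects excluded; lower `min_minority_choices`", call. = FALSE)
  if (length(excl))
    message("excluding ", length(excl), " subject(s) with degenerate ",
            "choice patterns: ", paste(excl, collapse = ", "))
  list(kept = data[!data$subject_id %in% excl, , drop = FALSE],
       excluded = excl)
}
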