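# Trial designs for the 128-trial delay-discounting task: a fixed 20 EUR
# smaller-sooner (SS) option against a larger-later (LL) option formed by
# crossing 16 amount multipliers with 8 delays. Two printed sets exist,
# differing slightly, one per testing day.

.TD_MULTIPLIERS <- list(
  `1` = c(1.01, 1.02, 1.05, 1.10, 1.15, 1.25, 1.35, 1.45,
          1.65, 1.85, 2.05, 2.25, 2.65, 3.05, 3.45, 3.85),
  `2` = c(1.01, 1.03, 1.08, 1.12, 1.20, 1.30, 1.40, 1.50,
          1.60, 1.80, 2.00, 2.20, 2.60, 3.00, 3.40, 3.80)
)

.TD_DELAYS <- list(
  `1` = c(1L, 3L, 5L, 8L, 14L, 30L, 60L, 122L),
  `2` = c(2L, 4L, 6L, 9L, 15L, 32L, 58L, 119L)
)

#' Build a delay-discounting trial design
#'
#' Constructs the full 16 x 8 crossing of LL-amount multipliers and delays for
#' one of the two task versions. Every (multiplier, delay) pair appears exactly
#' once, giving 128 trials. LL amounts are `ss_amount * multiplier`, rounded to
#' euro cents.
#'
#' @param set_id Design set, `1` or `2`. The two sets use slightly different
#'   multipliers and delays (e.g. maximum delay 122 vs 119 days).
#' @param ss_amount Amount of the fixed immediate smaller-sooner option, in
#'   euros. Default 20.
#' @return A data frame of class `"td_design"` with columns `trial_index`,
#'   `multiplier`, `ll_amount`, `delay_days`, and attributes `set_id` and
#'   `ss_amount`.
#' @examples
#' d <- td_design(1)
#' nrow(d)            # 128
#' range(d$ll_amount) # 20.20 .. 77.00
#' @export
td_design <- function(set_id, ss_amount = 20) {
  if (length(set_id) != 1L || !set_id %in% c(1L, 2L))
    stop("`set_id` must be 1 or 2", call. = FALSE)
  if (!is.numeric(ss_amount) || length(ss_amount) != 1L || ss_amount <= 0)
    stop("`ss_amount` must be a single positive number", call. = FALSE)
  mult <- .TD_MULTIPLIERS[[as.character(set_id)]]
  dels <- .TD_DELAYS[[as.character(set_id)]]
  g <- expand.grid(multiplier = mult, delay_days = dels,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    trial_index = seq_len(nrow(g)),
    multiplier  = g$multiplier,
    ll_amount   = round(ss_amount * g$multiplier, 2),
    delay_days  = as.integer(g$delay_days)
  )
  attr(out, "set_id") <- as.integer(set_id)
  attr(out, "ss_amount") <- ss_amount
  class(out) <- c("td_design", "data.frame")
  out
}

#' Map delays to the eight canonical delay bins
#'
#' Pools delays from both design sets into eight bins by mapping each delay to
#' the nearest Set-1 delay (ties broken toward the shorter delay, so e.g. 2
#' days -> bin 1, 4 days -> bin 3). Used when summarising LL-choice proportions
#' across delays for datasets that mix the two sets.
#'
#' @param delays Integer vector of delays in days.
#' @return Integer vector of the same length giving the bin label (a Set-1
#'   delay) for each input delay.
#' @export
delay_bins <- function(delays) {
  if (!is.numeric(delays) || any(!is.finite(delays)) || any(delays < 0))
    stop("`delays` must be finite non-negative numbers", call. = FALSE)
  ref <- .TD_DELAYS[[1L]]
  vapply(delays, function(d) {
    dist <- abs(ref - d)
    ref[which.min(dist)]  # which.min takes the first, i.e. shorter, on ties
  }, integer(1))
}
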