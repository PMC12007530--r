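# Split-chain convergence diagnostics.

# split each chain in half and compute the potential scale reduction factor
.split_rhat_one <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    n2 <- length(v) %/% 2L
    halves <- c(halves, list(v[seq_len(n2)], v[n2 + seq_len(n2)]))
  }
  n <- length(halves[[1]])
  if (n < 2L) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size from pooled autocorrelations (Geyer initial positive
# sequence, summed over chains)
.ess_one <- function(x, chain) {
  chains <- unique(chain)
  n <- min(table(chain))
  if (stats::var(x) == 0) return(NA_real_)
  acfs <- lapply(chains, function(ch) {
    v <- x[chain == ch][seq_len(n)]
    if (stats::var(v) == 0) return(rep(0, n))
    stats::acf(v, lag.max = n - 1L, plot = FALSE,
               demean = TRUE)$acf[, 1, 1]
  })
  rho <- Reduce(`+`, acfs) / length(acfs)
  tau <- 1
  t <- 1L
  while (t + 1L < length(rho)) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    t <- t + 2L
  }
  max(length(chains) * n / tau, 1)
}

#' Split-chain R-hat convergence report
#'
#' Computes the split-chain potential scale reduction factor and an effective
#' sample size for every sampled parameter. Parameters with zero variance
#' across all chains (e.g. structurally fixed shifts in a single-condition
#' fit) are reported with R-hat 1 and flagged.
#'
#' @param x A `"td_fit"` object, or a draws matrix (iterations x parameters).
#' @param chain Integer chain index per row (taken from the fit if omitted).
#' @param threshold Pass criterion: all R-hat strictly below this (default
#'   1.05).
#' @return Data frame with columns `parameter`, `rhat`, `ess`,
#'   `zero_variance`, and attribute `pass` (`TRUE` iff all R-hat <
#'   `threshold`).
#' @export
compute_rhat <- function(x, chain = NULL, threshold = 1.05) {
  if (inherits(x, "td_fit")) {
    chain <- x$chain
    x <- x$draws
  }
  if (is.null(chain) || length(unique(chain)) < 2L)
    stop("R-hat requires at least 2 chains", call. = FALSE)
  if (!is.matrix(x)) x <- as.matrix(x)
  rhat <- numeric(ncol(x))
  ess <- numeric(ncol(x))
  zv <- logical(ncol(x))
  for (p in seq_len(ncol(x))) {
    v <- x[, p]
    if (stats::var(v) == 0) {
      zv[p] <- TRUE
      rhat[p] <- 1
      ess[p] <- NA_real_
    } else {
      rhat[p] <- .split_rhat_one(v, chain)
      ess[p] <- .ess_one(v, chain)
    }
  }
  out <- data.frame(parameter = colnames(x), rhat = rhat, ess = ess,
                    zero_variance = zv)
  attr(out, "pass") <- all(out$rhat < threshold, na.rm = TRUE)
  out
}
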