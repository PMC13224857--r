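# Delta-Ct normalization, fold changes relative to a reference condition,
# and mixed-model condition tests with Benjamini-Hochberg correction.

#' Delta-Ct normalization against a housekeeping gene
#'
#' @param ct_target,ct_housekeeping Ct values in cycles, same sample.
#' @return `ct_target - ct_housekeeping`.
#' @export
delta_ct <- function(ct_target, ct_housekeeping) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_housekeeping)))
  ct_target - ct_housekeeping
}

#' Expression fold change relative to a reference condition
#'
#' Computes `2^-(dct - mean(dct_reference))`, i.e. the 2^-ddCt expression
#' ratio relative to the geometric mean of the reference condition: the
#' arithmetic mean of reference delta-Ct values in the exponent is exactly
#' the geometric mean of their `2^-dct` expression values.
#'
#' @param dct_sample Delta-Ct value(s) of the sample(s).
#' @param dct_reference Non-empty vector of reference-condition delta-Ct
#'   values.
#' @return Fold change(s), positive.
#' @export
fold_change <- function(dct_sample, dct_reference) {
  if (length(dct_reference) == 0L)
    stop("reference set must be non-empty", call. = FALSE)
  2^(-(dct_sample - mean(dct_reference)))
}

#' Compute delta-Ct values from a long Ct table
#'
#' Pairs each target measurement with the housekeeping measurement of the
#' same condition and replicate.
#'
#' @param ct_table `data.frame` with columns `condition`, `replicate`,
#'   `target`, `ct`; one housekeeping row per (condition, replicate).
#' @param housekeeping Name of the housekeeping target (default
#'   `"housekeeping"`).
#' @return `data.frame` with columns `condition`, `replicate`, `target`,
#'   `dct`.
#' @export
delta_ct_table <- function(ct_table, housekeeping = "housekeeping") {
  stopifnot(all(c("condition", "replicate", "target", "ct") %in%
                  names(ct_table)))
  hk <- ct_table[ct_table$target == housekeeping, ]
  if (nrow(hk) == 0L) stop("no housekeeping rows found", call. = FALSE)
  tg <- ct_table[ct_table$target != housekeeping, ]
  key <- function(d) paste(d$condition, d$replicate, sep = "\r")
  i <- match(key(tg), key(hk))
  if (anyNA(i))
    stop("missing housekeeping measurement for some (condition, replicate)",
         call. = FALSE)
  data.frame(condition = tg$condition, replicate = tg$replicate,
             target = tg$target, dct = delta_ct(tg$ct, hk$ct[i]),
             stringsAsFactors = FALSE)
}

#' Fold changes for every sample relative to a reference condition
#'
#' @param dct `data.frame` from [delta_ct_table()].
#' @param reference Condition label used as reference.
#' @return `data.frame` with columns `condition`, `replicate`, `target`,
#'   `dct`, `fold_change` (relative to the geometric mean of the reference
#'   condition, per target).
#' @export
fold_change_table <- function(dct, reference) {
  if (!reference %in% dct$condition)
    stop("reference condition not present", call. = FALSE)
  out <- dct
  out$fold_change <- NA_real_
  for (tg in unique(dct$target)) {
    sel <- dct$target == tg
    ref <- dct$dct[sel & dct$condition == reference]
    out$fold_change[sel] <- fold_change(dct$dct[sel], ref)
  }
  out
}

#' Mixed-model test for condition effects on delta-Ct values
#'
#' Per target, fits a linear mixed model of delta-Ct with fixed condition
#' effects and a per-replicate random intercept (absorbing systematic
#' between-replicate shifts), and compares it against the model without the
#' condition term by a likelihood-ratio test (ML fits). P-values are
#' Benjamini-Hochberg adjusted across targets. With a single replicate the
#' random intercept is dropped and an ordinary linear model is used, with a
#' warning.
#'
#' @param dct `data.frame` from [delta_ct_table()] (columns `condition`,
#'   `replicate`, `target`, `dct`); at least two conditions.
#' @return `data.frame` with one row per target: `target`, `chisq`, `df`,
#'   `p.value`, `p.adjusted`.
#' @export
condition_test <- function(dct) {
  stopifnot(all(c("condition", "replicate", "target", "dct") %in% names(dct)))
  if (length(unique(dct$condition)) < 2L)
    stop("need at least 2 conditions", call. = FALSE)
  targets <- unique(dct$target)
  res <- data.frame(target = targets, chisq = NA_real_, df = NA_integer_,
                    p.value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    d <- dct[dct$target == targets[i], ]
    k <- length(unique(d$condition))
    if (var(d$dct) < 1e-24) {  # constant response: no evidence either way
      res$chisq[i] <- 0
      res$df[i] <- k - 1L
      res$p.value[i] <- 1
      next
    }
    if (length(unique(d$replicate)) < 2L) {
      warning("single replicate: falling back to ordinary linear model")
      full <- stats::lm(dct ~ condition, data = d)
      null <- stats::lm(dct ~ 1, data = d)
    } else {
      full <- suppressWarnings(suppressMessages(
        lme4::lmer(dct ~ condition + (1 | replicate), data = d,
                   REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
      null <- suppressWarnings(suppressMessages(
        lme4::lmer(dct ~ 1 + (1 | replicate), data = d, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))))
    }
    stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
    res$chisq[i] <- stat
    res$df[i] <- k - 1L
    res$p.value[i] <- pchisq(stat, df = k - 1L, lower.tail = FALSE)
  }
  res$p.adjusted <- bh_adjust(res$p.value)
  res
}

#' Benjamini-Hochberg adjustment (step-up)
#'
#' Standard step-up procedure: sort p-values ascending, take
#' `q_(i) = min_{j >= i} p_(j) * n / j`, cap at 1, and restore the input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  if (n == 0L) return(numeric(0))
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}
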