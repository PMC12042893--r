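#' @include AllClasses.R metrics.R
NULL

#' Mann-Kendall trend test
#'
#' Classical nonparametric trend test on an ordered series:
#' \eqn{S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)}, tie-corrected variance
#' \eqn{[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} over tie groups of size
#' \eqn{t}, continuity-corrected normal deviate
#' (\eqn{(S-1)/\sqrt{var}} for \eqn{S>0}, 0 for \eqn{S=0},
#' \eqn{(S+1)/\sqrt{var}} for \eqn{S<0}), and a two-sided normal
#' p-value. The direction label is the sign of S when \eqn{p \le \alpha},
#' otherwise "none".
#'
#' @param x numeric series in time order, length >= 3, no missing values.
#' @param alpha significance level for the direction label (default 0.05).
#' @return A [TrendResult-class].
#' @examples
#' mannKendall(c(1, 3, 2, 5, 7, 8, 9, 12, 11, 15))
#' @export
mannKendall <- function(x, alpha = 0.05) {
  if (anyNA(x)) stop("series contains missing values")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  S <- 0
  for (i in seq_len(n - 1))
    S <- S + sum(sign(x[(i + 1):n] - x[i]))
  ties <- table(x)
  ties <- ties[ties > 1]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  Z <- if (S > 0) (S - 1) / sqrt(varS)
       else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  p <- if (S == 0) 1 else 2 * (1 - pnorm(abs(Z)))
  dir <- if (p <= alpha && S > 0) "increasing"
         else if (p <= alpha && S < 0) "decreasing"
         else "none"
  new("TrendResult", n = as.integer(n), S = S, varS = varS, Z = Z,
      p = p, direction = dir, alpha = alpha)
}

#' Trend table over scopes and hazard combinations
#'
#' Applies [mannKendall()] to the annual tract-day series of every flag
#' assay, region-wide and per state. Series shorter than 10 years carry a
#' small-sample caution flag: with so few years, small p-values indicate
#' only a possible trend. Series shorter than 3 years cannot be tested
#' and are reported with missing statistics.
#'
#' @param he a classified/coexposed [HazardExperiment-class].
#' @param alpha significance level (default 0.05).
#' @return data.frame: scope, scope_id, hazard, n, S, varS, Z, p,
#'   direction, small_n_caution.
#' @export
trendTable <- function(he, alpha = 0.05) {
  stopifnot(is(he, "HazardExperiment"))
  rd <- rowData(he)
  states <- sort(unique(rd$state))
  rowFor <- function(scope, id, nm, series) {
    if (length(series) < 3)  # too short to test; keep the row, flag it
      return(data.frame(scope = scope, scope_id = id, hazard = nm,
                        n = length(series), S = NA_real_,
                        varS = NA_real_, Z = NA_real_, p = NA_real_,
                        direction = "none", small_n_caution = TRUE,
                        stringsAsFactors = FALSE))
    r <- mannKendall(series, alpha)
    data.frame(scope = scope, scope_id = id, hazard = nm, n = r@n,
               S = r@S, varS = r@varS, Z = r@Z, p = round(r@p, 3),
               direction = r@direction, small_n_caution = r@n < 10,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (nm in flagNames(he)) {
    flags <- hazardFlags(he, nm)
    out[[length(out) + 1L]] <- rowFor("region", "all", nm,
                                      annualSeries(flags))
    for (s in states)
      out[[length(out) + 1L]] <- rowFor(
        "state", s, nm, annualSeries(flags[rd$state == s, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
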