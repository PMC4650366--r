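#' Find the steady level of a colony-count series
#'
#' Scans windows of three consecutive counts `(N_i, N_i+1, N_i+2)` in
#' ascending order of `i`. A window qualifies when `N_i >= 1` and either
#' criterion holds:
#' \itemize{
#'   \item large counts (`N_i > 100`): `|N_i+1 - N_i| <= 0.01 N_i` and
#'     `|N_i+2 - N_i+1| <= 0.01 N_i+1`;
#'   \item small counts (`N_i <= 100`): `|N_i+1 - N_i| <= 1` and
#'     `|N_i+2 - N_i+1| <= 1`.
#' }
#' The first qualifying window wins and `N_i+2` is the steady level
#' `N_stdy`, reported with its capture time. The criterion is selected by
#' the first count of the window; a count of exactly 100 uses the small-
#' count criterion. The 1\% comparisons are evaluated in exact integer
#' arithmetic (`100 |diff| <= N`), so no float boundary can flip a window.
#' Requiring `N_i >= 1` prevents an all-zero prefix, before any colony has
#' been recognised, from being declared steady.
#'
#' @param series a [CountSeries-class] with at least 3 points.
#' @return A [SteadyDecision-class].
#' @examples
#' findSteady(CountSeries(0:7, c(0, 10, 80, 120, 200, 201, 202, 202)))
#' @export
findSteady <- function(series) {
  stopifnot(is(series, "CountSeries"))
  cnt <- series@counts
  if (length(cnt) < 3L) stop("count series must have at least 3 points")
  for (i in seq_len(length(cnt) - 2L)) {
    c0 <- cnt[i]; c1 <- cnt[i + 1L]; c2 <- cnt[i + 2L]
    if (c0 < 1L) next
    if (c0 > 100L) {
      ok <- (100L * abs(c1 - c0) <= c0) && (100L * abs(c2 - c1) <= c1)
      crit <- "large_n"
    } else {
      ok <- (abs(c1 - c0) <= 1L) && (abs(c2 - c1) <= 1L)
      crit <- "small_n"
    }
    if (ok)
      return(new("SteadyDecision", found = TRUE, window_start_i = i,
                 n_stdy = c2, t_stdy_h = series@times_h[i + 2L],
                 criterion_used = crit))
  }
  new("SteadyDecision", found = FALSE, window_start_i = NA_integer_,
      n_stdy = NA_integer_, t_stdy_h = NA_real_,
      criterion_used = NA_character_)
}

#' Confirmed count at the end of the culture
#'
#' The count confirmed at the final capture time of the prescribed long
#' culture (e.g. 24 h for *E. coli*, 48 h for fungi) is the
#' reference-equivalent result `N_conf`.
#'
#' @param series a non-empty [CountSeries-class].
#' @return A list with `n_conf` and `t_conf_h`.
#' @export
confirmCount <- function(series) {
  stopifnot(is(series, "CountSeries"))
  n <- length(series@counts)
  if (!n) stop("empty count series")
  list(n_conf = series@counts[n], t_conf_h = series@times_h[n])
}

#' Relative difference between the rapid and the confirmed count
#'
#' `100 (N_conf - N_stdy) / N_conf`, reported to one decimal place (so the
#' cut-vegetable example, 2155 vs 2240, gives 3.8).
#'
#' @param n_stdy steady-level count.
#' @param n_conf confirmed count (> 0).
#' @return Signed percentage, rounded to one decimal.
#' @examples
#' relativeDifference(2155, 2240)  # 3.8
#' @export
relativeDifference <- function(n_stdy, n_conf) {
  if (!is.finite(n_conf) || n_conf <= 0) stop("n_conf must be > 0")
  round(100 * (n_conf - n_stdy) / n_conf, 1L)
}

#' Classify the outcome of a plate run
#'
#' Labels the count time course: `steady_unchanged` when the steady level
#' was reached and held to the end (`N_conf == N_stdy`); `late_increase`
#' when slowly appearing colonies raised the count after the steady call
#' (`N_conf > N_stdy`); `late_decrease` when the count fell (in principle,
#' fusion missed by single-frame counting); `no_steady` when no window
#' qualified.
#'
#' @param series a [CountSeries-class].
#' @param decision a [SteadyDecision-class] for the series.
#' @param confirmed result of [confirmCount()].
#' @param tracks optional [ColonyTrackSet-class]; when given, the ids of
#'   viable tracks born after `t_stdy` are reported for a `late_increase`.
#' @return A list with `scenario` and `late_track_ids`.
#' @export
classifyOutcome <- function(series, decision, confirmed, tracks = NULL) {
  stopifnot(is(decision, "SteadyDecision"))
  if (!decision@found)
    return(list(scenario = "no_steady", late_track_ids = integer()))
  late <- integer()
  if (!is.null(tracks) && is(tracks, "ColonyTrackSet")) {
    info <- tracks@info
    bt <- tracks@times_h[pmin(info$birth_frame, length(tracks@times_h))]
    late <- info$track_id[info$viability == "viable" & bt > decision@t_stdy_h]
  }
  n_conf <- confirmed$n_conf
  scenario <- if (n_conf == decision@n_stdy) "steady_unchanged"
              else if (n_conf > decision@n_stdy) "late_increase"
              else "late_decrease"
  if (scenario != "late_increase") late <- integer()
  list(scenario = scenario, late_track_ids = late)
}

#' Log-log regression of confirmed on rapid counts across plates
#'
#' Ordinary least squares of `log10(N_conf)` on `log10(N_stdy)` with the
#' Pearson correlation and its significance,
#' `t = r sqrt(df) / sqrt(1 - r^2)` against the t-distribution. The degrees
#' of freedom follow the configured convention: `n_minus_2` (the standard
#' correlation test) or `n_minus_1`; both are supported because published
#' analyses of this design differ on the convention.
#'
#' @param n_stdy,n_conf paired counts across plates (all >= 1; at least 3
#'   pairs).
#' @param df_convention `"n_minus_2"` (default) or `"n_minus_1"`.
#' @return A list with `n_pairs`, `slope`, `intercept`, `r`, `r_squared`,
#'   `df`, `t_stat`, `p_corr`.
#' @export
loglogRegression <- function(n_stdy, n_conf,
                             df_convention = c("n_minus_2", "n_minus_1")) {
  df_convention <- match.arg(df_convention)
  if (length(n_stdy) != length(n_conf)) stop("paired vectors required")
  if (length(n_stdy) < 3L) stop("at least 3 pairs required")
  if (any(n_stdy < 1) || any(n_conf < 1))
    stop("all counts must be >= 1 (log undefined at 0)")
  x <- log10(n_stdy); y <- log10(n_conf)
  if (stats::sd(x) == 0) stop("singular fit: constant N_stdy across plates")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  df <- length(x) - if (df_convention == "n_minus_2") 2L else 1L
  t_stat <- if (abs(r) >= 1) Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(n_pairs = length(x), slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]), r = r, r_squared = r^2,
       df = df, t_stat = t_stat, p_corr = p)
}

#' Paired t-test on determination times
#'
#' Two-sided paired t-test of `d = t_conf - t_stdy` across plates (df =
#' n - 1), quantifying how much earlier the rapid count is available than
#' the end-of-culture confirmation.
#'
#' @param t_stdy_list,t_conf_list paired determination times (h), length
#'   >= 2.
#' @return A list with `t_stat`, `df`, `p`, `mean_diff`.
#' @export
pairedTimeTest <- function(t_stdy_list, t_conf_list) {
  if (length(t_stdy_list) != length(t_conf_list))
    stop("paired vectors required")
  if (length(t_stdy_list) < 2L) stop("at least 2 pairs required")
  d <- t_conf_list - t_stdy_list
  if (stats::sd(d) == 0)
    stop("degenerate test: zero variance of time differences")
  ht <- stats::t.test(t_conf_list, t_stdy_list, paired = TRUE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = mean(d))
}

#' Combined equivalence statistics across plates
#'
#' @param n_stdy,n_conf paired counts.
#' @param t_stdy,t_conf paired determination times (h).
#' @param df_convention see [loglogRegression()].
#' @return An [EquivalenceStats-class].
#' @export
equivalenceStats <- function(n_stdy, n_conf, t_stdy, t_conf,
                             df_convention = c("n_minus_2", "n_minus_1")) {
  df_convention <- match.arg(df_convention)
  reg <- loglogRegression(n_stdy, n_conf, df_convention)
  tt <- pairedTimeTest(t_stdy, t_conf)
  new("EquivalenceStats", n_pairs = as.integer(reg$n_pairs), slope = reg$slope,
      intercept = reg$intercept, r = reg$r, r_squared = reg$r_squared,
      df = as.integer(reg$df), p_corr = reg$p_corr, t_stat_times = tt$t_stat,
      df_times = as.integer(tt$df), p_times = tt$p,
      df_convention = df_convention)
}
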