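#' Percentage of stags hunted successfully
#'
#' `100 * coop_stags / (hares + coop_stags + solo_stags)` — the share of
#' cooperatively captured stags among all prey removed. The denominator
#' includes failed solitary stag hunts (they are prey removals); set
#' `include_failed = FALSE` for the alternative convention. Defined as 0
#' when nothing was hunted.
#'
#' @param hares,coop_stags,solo_stags Non-negative counts (vectorised).
#' @param include_failed Count solitary stag hunts in the denominator?
#' @return Percentages in `[0, 100]`.
#' @export
stag_proportion <- function(hares, coop_stags, solo_stags,
                            include_failed = TRUE) {
  stopifnot(all(hares >= 0), all(coop_stags >= 0), all(solo_stags >= 0))
  denom <- hares + coop_stags + if (include_failed) solo_stags else 0
  ifelse(denom == 0, 0, 100 * coop_stags / denom)
}

#' Summarise the last generation of one or more runs
#'
#' For each run, the mean and standard deviation over the final
#' generation's per-episode evaluations (25 episodes per individual in the
#' embodied model) of the three prey-count categories, plus the
#' successful-stag percentage of the summed counts.
#'
#' @param runs A `stag_run` or a list of them.
#' @param condition Condition label attached to the summary; defaults to
#'   the label stored in the first run.
#' @return A tibble of class `condition_summary`, one row per run with
#'   columns `condition`, `run`, `seed`, means and standard deviations of
#'   `hares`, `coop_stags` and `solo_stags`, and `stag_pct`.
#' @export
last_generation_summary <- function(runs, condition = NULL) {
  if (inherits(runs, "stag_run")) runs <- list(runs)
  stopifnot(length(runs) >= 1, all(purrr::map_lgl(runs, inherits, "stag_run")))
  condition <- condition %||% runs[[1]]$config$condition
  out <- purrr::imap(runs, function(r, i) {
    lg <- r$last_generation
    if (is.null(lg)) stop("run ", i, " carries no last-generation table",
                          call. = FALSE)
    tibble::tibble(
      condition = condition,
      run = i,
      seed = r$seed,
      hares_mean = mean(lg$hares), hares_sd = stats::sd(lg$hares),
      coop_stags_mean = mean(lg$coop_stags),
      coop_stags_sd = stats::sd(lg$coop_stags),
      solo_stags_mean = mean(lg$solo_stags),
      solo_stags_sd = stats::sd(lg$solo_stags),
      stag_pct = stag_proportion(sum(lg$hares), sum(lg$coop_stags),
                                 sum(lg$solo_stags)))
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("condition_summary", class(out))
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum U with midranks for ties. The two-sided p-value is exact (by
#' enumeration over all rank assignments) when `n_a + n_b <= 12` and there
#' are no ties, and otherwise uses the normal approximation with tie and
#' continuity corrections. When the variance collapses entirely (all
#' observations tied) the p-value is 1.
#'
#' @param sample_a,sample_b Non-empty numeric samples. `sample_a` may also
#'   be a data frame holding both groups, with `sample_b` naming the value
#'   column and `group` the two-level grouping column.
#' @param sample_b See above.
#' @param group Grouping column name for the data-frame interface.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return A list with `U` (statistic of `sample_a`), `p_value`
#'   (two-sided) and `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b, group = NULL,
                           method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (is.data.frame(sample_a)) {
    stopifnot(is.character(sample_b), is.character(group))
    g <- factor(sample_a[[group]])
    stopifnot(nlevels(g) == 2)
    vals <- sample_a[[sample_b]]
    sample_b <- vals[g == levels(g)[2]]
    sample_a <- vals[g == levels(g)[1]]
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  if (na == 0 || nb == 0) stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)  # midranks
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  use_exact <- method == "exact" ||
    (method == "auto" && na + nb <= 12 && !ties)
  if (use_exact && ties) {
    stop("exact enumeration requires untied samples", call. = FALSE)
  }
  if (use_exact) {
    # Exact null distribution of U over all C(na+nb, na) equally likely
    # rank splits (cross-checked against a full enumeration oracle in the
    # test suite).
    lower <- stats::pwilcox(U, na, nb)
    upper <- 1 - stats::pwilcox(U - 1, na, nb)
    p <- min(1, 2 * min(lower, upper))
    return(list(U = U, p_value = p, method = "exact"))
  }
  n <- na + nb
  mu <- na * nb / 2
  tie_sizes <- table(pooled)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    return(list(U = U, p_value = 1, method = "normal"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p_value = p, method = "normal")
}

#' Mutual-circling statistic of a hunter pair
#'
#' Successful cooperators coordinate by circling around one another while
#' closing in on a stag; this statistic quantifies that orbiting as the
#' mean absolute per-step change of the bearing from one hunter to its
#' partner (wrapped to `(-pi, pi]`), symmetrised over the two hunters.
#' Parallel straight motion and stationary pairs score 0; a pair orbiting
#' a common centre at angular velocity `w` scores `w`.
#'
#' @param traj_a,traj_b Data frames (or matrices) with columns `x`, `y`
#'   giving the two hunters' positions at the same time steps, or a single
#'   trajectory tibble from [run_episode()] (`traj_a` with a `hunter`
#'   column, `traj_b` missing).
#' @return Mean absolute bearing change in radians per step.
#' @export
circling_statistic <- function(traj_a, traj_b = NULL) {
  if (is.null(traj_b)) {
    stopifnot(is.data.frame(traj_a), "hunter" %in% names(traj_a))
    traj_b <- traj_a[traj_a$hunter == 2, c("x", "y")]
    traj_a <- traj_a[traj_a$hunter == 1, c("x", "y")]
  }
  ax <- traj_a[, "x", drop = TRUE]
  ay <- traj_a[, "y", drop = TRUE]
  bx <- traj_b[, "x", drop = TRUE]
  by <- traj_b[, "y", drop = TRUE]
  if (length(ax) != length(bx)) stop("trajectory lengths differ", call. = FALSE)
  if (length(ax) < 2) stop("trajectories must have at least 2 steps",
                           call. = FALSE)
  bearing_rate <- function(dx, dy) {
    theta <- atan2(dy, dx)
    inc <- diff(theta)
    inc <- ((inc + pi) %% (2 * pi)) - pi  # wrap to (-pi, pi]
    mean(abs(inc))
  }
  (bearing_rate(bx - ax, by - ay) + bearing_rate(ax - bx, ay - by)) / 2
}

#' Compare the final-generation stag proportion of two conditions
#'
#' Runs the Mann-Whitney U test on the per-run successful-stag
#' percentages of the last generation, the comparison used between
#' experimental conditions.
#'
#' @param summary_a,summary_b [last_generation_summary()] tibbles (or
#'   lists of `stag_run`s, summarised on the fly).
#' @return A tibble with the two condition labels, sample sizes, `U` and
#'   the two-sided p-value.
#' @export
compare_conditions <- function(summary_a, summary_b) {
  if (!is.data.frame(summary_a)) summary_a <- last_generation_summary(summary_a)
  if (!is.data.frame(summary_b)) summary_b <- last_generation_summary(summary_b)
  mw <- mann_whitney_u(summary_a$stag_pct, summary_b$stag_pct)
  tibble::tibble(condition_a = summary_a$condition[1],
                 condition_b = summary_b$condition[1],
                 n_a = nrow(summary_a), n_b = nrow(summary_b),
                 U = mw$U, p_value = mw$p_value, method = mw$method)
}
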