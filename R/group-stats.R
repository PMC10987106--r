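#' Welch's unequal-variance t-test
#'
#' Two-sided t-test without the equal-variance assumption, using the
#' Welch-Satterthwaite degrees of freedom. The degenerate case (both
#' groups constant with equal means) returns `t = 0, p = 1` with a flag.
#'
#' @param a,b Numeric vectors, each with >= 2 finite observations.
#' @return Tibble with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
welch_t <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 finite observations", call. = FALSE)
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    return(tibble::tibble(t = 0, df = length(a) + length(b) - 2,
                          p = 1, mean_diff = d, degenerate = TRUE))
  }
  t_stat <- d / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  tibble::tibble(t = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df),
                 mean_diff = d, degenerate = FALSE)
}

#' Levene's test for homogeneity of variance
#'
#' One-way ANOVA on absolute deviations from each group's centre. The
#' classic test centres on the mean; `center = "median"` gives the
#' Brown-Forsythe variant. All-identical observations return
#' `W = 0, p = 1`.
#'
#' @param data Tidy data frame with one observation per row.
#' @param value,group Column names (strings or bare names via `{{ }}` are
#'   not required; strings).
#' @param center `"mean"` or `"median"`.
#' @return Tibble with `W`, `df1`, `df2`, `p`.
#' @export
levene_test <- function(data, value = "value", group = "group",
                        center = c("mean", "median")) {
  center <- match.arg(center)
  y <- data[[value]]; g <- factor(data[[group]])
  check_groups(y, g)
  cfun <- if (center == "mean") mean else stats::median
  z <- abs(y - stats::ave(y, g, FUN = cfun))
  k <- nlevels(g); n <- length(z)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ng <- tabulate(g)
  ss_between <- sum(ng * (zg - zbar)^2)
  ss_within <- sum((z - stats::ave(z, g, FUN = mean))^2)
  if (ss_within == 0 && ss_between == 0) {
    return(tibble::tibble(W = 0, df1 = k - 1, df2 = n - k, p = 1))
  }
  W <- (ss_between / (k - 1)) / (ss_within / (n - k))
  tibble::tibble(W = W, df1 = k - 1, df2 = n - k,
                 p = stats::pf(W, k - 1, n - k, lower.tail = FALSE))
}

#' Games-Howell pairwise comparisons
#'
#' Post-hoc pairwise mean comparisons for groups with unequal variances
#' and sizes: for groups i and j,
#' `t = (mean_i - mean_j) / sqrt(s2_i/n_i + s2_j/n_j)` with
#' Welch-Satterthwaite degrees of freedom, and the p-value comes from the
#' studentized-range distribution with `k` groups evaluated at
#' `q = |t| * sqrt(2)`. Appropriate after a significant Levene's test,
#' where Tukey's range test would be unsound.
#'
#' @inheritParams levene_test
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per pair: `group_a`, `group_b`,
#'   `mean_diff`, `t`, `df`, `p`, `significant`.
#' @export
games_howell <- function(data, value = "value", group = "group",
                         alpha = 0.05) {
  y <- data[[value]]; g <- factor(data[[group]])
  check_groups(y, g)
  levs <- levels(g)
  k <- length(levs)
  m <- tapply(y, g, mean)
  v <- tapply(y, g, stats::var)
  n <- tabulate(g)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(idx) {
    i <- idx[1]; j <- idx[2]
    se2 <- v[i] / n[i] + v[j] / n[j]
    d <- m[i] - m[j]
    if (se2 == 0) {
      t_stat <- 0
      df <- n[i] + n[j] - 2
      p <- if (d == 0) 1 else 0
    } else {
      t_stat <- d / sqrt(se2)
      df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
      p <- stats::ptukey(abs(t_stat) * sqrt(2), k, df, lower.tail = FALSE)
    }
    tibble::tibble(group_a = levs[i], group_b = levs[j],
                   mean_diff = unname(d), t = unname(t_stat),
                   df = unname(df), p = unname(p))
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- out$p < alpha
  out
}

check_groups <- function(y, g) {
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(tabulate(g) < 2)) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  if (any(!is.finite(y))) stop("observations must be finite", call. = FALSE)
  invisible(TRUE)
}

#' Compact letter display from pairwise results
#'
#' Greedy insert-absorb lettering: groups share a letter if and only if no
#' significant difference separates them within that letter's set. The
#' letter count is not guaranteed minimal, but the display never assigns a
#' shared letter to a significantly different pair, and every
#' non-significant pair shares at least one letter.
#'
#' @param pairwise Tibble from [games_howell()] (or any table with
#'   `group_a`, `group_b`, `significant`), covering every pair.
#' @return Tibble with `group` and `letters`.
#' @export
letter_display <- function(pairwise) {
  stopifnot(all(c("group_a", "group_b", "significant") %in% names(pairwise)))
  groups <- sort(unique(c(pairwise$group_a, pairwise$group_b)))
  k <- length(groups)
  if (nrow(pairwise) < choose(k, 2)) {
    stop("input error: pairwise results must cover all pairs", call. = FALSE)
  }
  sig <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (r in seq_len(nrow(pairwise))) {
    ga <- pairwise$group_a[r]; gb <- pairwise$group_b[r]
    sig[ga, gb] <- sig[gb, ga] <- isTRUE(pairwise$significant[r])
  }
  # each non-significant pair must share a letter: grow one compatible set
  # around every uncovered pair, then absorb redundant subsets
  sets <- list()
  covered <- function(i, j) {
    any(vapply(sets, function(s) groups[i] %in% s && groups[j] %in% s,
               logical(1)))
  }
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (sig[i, j] || covered(i, j)) next
      s <- c(groups[i], groups[j])
      for (gi in setdiff(groups, s)) {
        if (!any(sig[gi, s])) s <- c(s, gi)
      }
      sets[[length(sets) + 1]] <- s
    }
  }
  # groups different from everything get their own letter
  for (gi in groups) {
    if (!any(vapply(sets, function(s) gi %in% s, logical(1)))) {
      sets[[length(sets) + 1]] <- gi
    }
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[j] && all(sets[[i]] %in% sets[[j]]) &&
          length(sets[[i]]) < length(sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  pool <- c(LETTERS, c(outer(LETTERS, LETTERS, paste0)))
  letters_used <- pool[seq_along(sets)]
  tibble::tibble(
    group = groups,
    letters = vapply(groups, function(gi) {
      paste0(letters_used[vapply(sets, function(s) gi %in% s, logical(1))],
             collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
}

#' Risk-group comparison of session vitals
#'
#' Convenience wrapper for remote-monitoring cohort comparisons: per-subject
#' mean vitals are compared between the high- and low-risk groups with
#' Welch's t-tests (per-subject aggregation avoids pseudo-replication of
#' windows within a subject).
#'
#' @param vitals Tidy tibble with columns `subject_id`, `risk_group`, and
#'   vitals columns.
#' @param vars Character vector of vitals columns to test.
#' @return Tibble with one row per variable: Welch `t`, `df`, `p`, group
#'   means.
#' @export
compare_risk_groups <- function(vitals,
                                vars = c("hr_bpm", "hrv_sdnn_ms",
                                         "resp_rate_bpm", "spo2_pct",
                                         "temp_c")) {
  stopifnot(all(c("subject_id", "risk_group") %in% names(vitals)))
  vars <- intersect(vars, names(vitals))
  per_subject <- vitals |>
    dplyr::group_by(.data$subject_id, .data$risk_group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  purrr::map_dfr(vars, function(v) {
    hi <- per_subject[[v]][per_subject$risk_group == "high"]
    lo <- per_subject[[v]][per_subject$risk_group == "low"]
    res <- welch_t(hi, lo)
    tibble::tibble(variable = v, mean_high = mean(hi), mean_low = mean(lo),
                   t = res$t, df = res$df, p = res$p)
  })
}
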