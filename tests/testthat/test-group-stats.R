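test_that("Welch's t matches the direct formula and base R", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- welch_t(a, b)
  ref <- stats::t.test(a, b)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  # identical groups
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # degenerate zero-variance case is flagged
  deg <- welch_t(c(2, 2), c(2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  # gross separation
  far <- welch_t(rnorm(10), rnorm(10) + 1e6)
  expect_lt(far$p, 1e-12)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Welch's t holds its type-I error under the null", {
  n_sim <- 2000
  rejections <- withr::with_seed(99, {
    sum(vapply(seq_len(n_sim), function(i) {
      welch_t(rnorm(15), rnorm(25))$p < 0.05
    }, logical(1)))
  })
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rejections / n_sim - 0.05), 2 * se + 1e-12)
})

test_that("Levene's test agrees with the reference implementation", {
  skip_if_not_installed("car")
  df <- withr::with_seed(12, data.frame(
    value = c(rnorm(30, 0, 1), rnorm(25, 1, 2), rnorm(35, -1, 0.5)),
    group = rep(c("a", "b", "c"), c(30, 25, 35))
  ))
  for (ctr in c("mean", "median")) {
    ours <- levene_test(df, "value", "group", center = ctr)
    ref <- car::leveneTest(value ~ factor(group), data = df,
                           center = get(ctr))
    expect_equal(ours$W, ref[1, "F value"], tolerance = 1e-10)
    expect_equal(ours$p, ref[1, "Pr(>F)"], tolerance = 1e-10)
  }
})

test_that("Levene's test separates unequal variances and not equal ones", {
  sim <- function(sd2) withr::with_seed(7, data.frame(
    value = c(rnorm(50, 0, 1), rnorm(50, 5, sd2)),
    group = rep(c("a", "b"), each = 50)))
  # equal spread, different means: fails to reject
  expect_gt(levene_test(sim(1))$p, 0.05)
  # variances 1 vs 100
  expect_lt(levene_test(sim(10))$p, 0.01)
  # degenerate identical observations
  flat <- data.frame(value = rep(1, 10), group = rep(c("a", "b"), 5))
  res <- levene_test(flat)
  expect_equal(res$W, 0)
  expect_equal(res$p, 1)
  expect_error(levene_test(data.frame(value = c(1, 2), group = c("a", "b"))),
               ">= 2")
})

test_that("Games-Howell with two groups reduces to Welch's t", {
  df <- withr::with_seed(3, data.frame(
    value = c(rnorm(20, 0, 1), rnorm(30, 1, 3)),
    group = rep(c("a", "b"), c(20, 30))
  ))
  gh <- games_howell(df)
  w <- welch_t(df$value[df$group == "a"], df$value[df$group == "b"])
  expect_equal(nrow(gh), 1)
  expect_equal(abs(gh$t), abs(w$t), tolerance = 1e-10)
  expect_equal(gh$df, w$df, tolerance = 1e-10)
  expect_lt(abs(gh$p - w$p), 1e-6)
})

test_that("Games-Howell separates the separated pairs only", {
  df <- withr::with_seed(41, data.frame(
    value = c(rnorm(30, 0), rnorm(30, 0), rnorm(30, 5), rnorm(30, 5)),
    group = rep(c("g1", "g2", "g3", "g4"), each = 30)
  ))
  gh <- games_howell(df)
  expect_equal(nrow(gh), 6)
  sig_of <- function(a, b) gh$significant[gh$group_a == a & gh$group_b == b]
  expect_false(sig_of("g1", "g2"))
  expect_false(sig_of("g3", "g4"))
  expect_true(sig_of("g1", "g3"))
  expect_true(sig_of("g1", "g4"))
  expect_true(sig_of("g2", "g3"))
  expect_true(sig_of("g2", "g4"))
  # identical groups: p ~ 1 everywhere
  same <- data.frame(value = rep(c(1, 2, 3), 3),
                     group = rep(c("a", "b", "c"), each = 3))
  expect_true(all(games_howell(same)$p > 0.999))
})

test_that("Games-Howell p-values are invariant to relabeling and affine maps", {
  df <- withr::with_seed(15, data.frame(
    value = c(rnorm(12, 0, 1), rnorm(18, 2, 2), rnorm(25, 3, 0.5)),
    group = rep(c("a", "b", "c"), c(12, 18, 25))
  ))
  gh1 <- games_howell(df)
  relab <- df
  relab$group <- c(a = "z", b = "y", c = "x")[df$group]
  gh2 <- games_howell(relab)
  key1 <- paste(pmin(gh1$group_a, gh1$group_b), pmax(gh1$group_a, gh1$group_b))
  expect_equal(sort(gh1$p), sort(gh2$p), tolerance = 1e-12)
  aff <- df
  aff$value <- -2.5 * df$value + 100
  gh3 <- games_howell(aff)
  expect_equal(gh1$p, gh3$p, tolerance = 1e-9)
})

test_that("letter displays encode exactly the non-significant structure", {
  mk <- function(a, b, sig) tibble::tibble(group_a = a, group_b = b,
                                           significant = sig)
  # all pairs different: distinct single letters
  all_sig <- mk(c("a", "a", "a", "b", "b", "c"),
                c("b", "c", "d", "c", "d", "d"), rep(TRUE, 6))
  ld <- letter_display(all_sig)
  expect_equal(sort(nchar(ld$letters)), rep(1L, 4))
  expect_equal(length(unique(ld$letters)), 4)
  # no pair different: one shared letter
  none_sig <- all_sig; none_sig$significant <- FALSE
  expect_equal(unique(letter_display(none_sig)$letters), "A")
  # chain a~b, b~c, a!=c
  chain <- mk(c("a", "a", "b"), c("b", "c", "c"), c(FALSE, TRUE, FALSE))
  lc <- letter_display(chain)
  expect_equal(lc$letters[lc$group == "a"], "A")
  expect_equal(lc$letters[lc$group == "b"], "AB")
  expect_equal(lc$letters[lc$group == "c"], "B")
  expect_error(letter_display(chain[1:2, ]), "all pairs")
})

test_that("letter displays are consistent on random significance patterns", {
  check_pattern <- function(seed) {
    k <- withr::with_seed(seed, sample(3:6, 1))
    groups <- paste0("g", seq_len(k))
    pairs <- t(utils::combn(groups, 2))
    sig <- withr::with_seed(seed + 1000, runif(nrow(pairs)) < 0.4)
    tab <- tibble::tibble(group_a = pairs[, 1], group_b = pairs[, 2],
                          significant = sig)
    ld <- letter_display(tab)
    lv <- stats::setNames(strsplit(ld$letters, ""), ld$group)
    for (r in seq_len(nrow(tab))) {
      shared <- length(intersect(lv[[tab$group_a[r]]],
                                 lv[[tab$group_b[r]]])) > 0
      if (tab$significant[r] && shared) return(FALSE)
      if (!tab$significant[r] && !shared) return(FALSE)
    }
    TRUE
  }
  expect_true(all(vapply(1:500, check_pattern, logical(1))))
})

test_that("risk-group comparison aggregates per subject before testing", {
  vit <- withr::with_seed(8, tibble::tibble(
    subject_id = rep(paste0("s", 1:10), each = 20),
    risk_group = rep(c("high", "low"), each = 100),
    hr_bpm = c(rnorm(100, 95, 5), rnorm(100, 70, 5)),
    temp_c = rnorm(200, 36.6, 0.1)
  ))
  out <- compare_risk_groups(vit, vars = c("hr_bpm", "temp_c"))
  expect_equal(nrow(out), 2)
  hr <- out[out$variable == "hr_bpm", ]
  expect_lt(hr$p, 0.01)
  expect_gt(hr$mean_high, hr$mean_low)
  # per-subject means imply 5-per-group degrees of freedom, not 100
  expect_lt(hr$df, 10)
})
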