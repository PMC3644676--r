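# Difference scores with sign conventions, outlier removal, the
# day-by-sequence repeated-measures ANOVA and explicit recognition.

make_scores <- function(subject, rmse_rep, rmse_rand, lag_rep, lag_rand,
                        sp_rep = 1, sp_rand = 1, day = 7) {
  data.frame(subject_id = subject, day = day,
             trial_index = 1,
             segment_kind = c("repeated", "random"),
             rmse = c(rmse_rep, rmse_rand),
             lag_ms = c(lag_rep, lag_rand),
             r2 = 0.9,
             spatial_rmse = c(sp_rep, sp_rand))
}

test_that("difference scores follow the error-inversion sign convention", {
  sc <- make_scores(1, rmse_rep = 1.0, rmse_rand = 1.5,
                    lag_rep = -120, lag_rand = -200,
                    sp_rep = 0.8, sp_rand = 0.6)
  ds <- difference_scores(sc, day = 7)

  r <- ds[ds$measure == "rmse", ]
  expect_equal(r$diff, -0.5)
  expect_equal(r$weight, 0.5)

  l <- ds[ds$measure == "lag", ]
  expect_equal(l$diff, 80)
  expect_equal(l$weight, 80)

  s <- ds[ds$measure == "spatial", ]
  expect_equal(s$diff, 0.2, tolerance = 1e-12)
  expect_equal(s$weight, -0.2, tolerance = 1e-12)

  same <- difference_scores(make_scores(1, 1, 1, -50, -50), day = 7)
  expect_true(all(same$diff == 0) && all(same$weight == 0))
})

test_that("improving repeated performance yields positive weights on all measures", {
  # lower repeated error, lag nearer zero, lower repeated spatial error
  sc <- make_scores(1, rmse_rep = 0.9, rmse_rand = 1.4,
                    lag_rep = -80, lag_rand = -220,
                    sp_rep = 0.5, sp_rand = 0.9)
  ds <- difference_scores(sc)
  expect_true(all(ds$weight > 0))
})

test_that("subjects missing a sequence kind are excluded with a message", {
  sc <- rbind(make_scores(1, 1, 1.5, -100, -150),
              make_scores(2, 1, 1.5, -100, -150)[1, ])
  expect_message(ds <- difference_scores(sc), "excluded")
  expect_identical(unique(ds$subject_id), 1)
})

test_that("the bundled retention cohort reproduces its sign counts", {
  tbl <- weighted_scores_table()
  expect_identical(nrow(tbl), 10L)
  expect_identical(count_positive(tbl$overall_error), 3L)
  expect_identical(count_positive(tbl$temporal_precision), 8L)
  expect_identical(count_positive(tbl$spatial_accuracy), 1L)
})

test_that("outlier removal uses a single-pass exclusive 2 SD rule", {
  expect_length(remove_outliers(rep(4, 10)), 10)

  x <- c(rep(0, 9), 100)
  out <- remove_outliers(x)
  expect_identical(attr(out, "removed"), 10L)
  expect_length(out, 9)

  # a single spike among n-1 equal values sits at z = (n-1)/sqrt(n):
  # below 2 for n = 5 (kept), above 2 for n = 6 (removed)
  expect_length(remove_outliers(c(10, rep(-1, 4))), 5)
  expect_length(remove_outliers(c(10, rep(-1, 5))), 5)

  df <- data.frame(id = 1:10, change = x)
  expect_identical(nrow(remove_outliers(df, "change")), 9L)
  expect_error(remove_outliers(c(1, 2)), "at least 3")
})

# independent sums-of-squares oracle for the balanced two-way
# within-subject design
anova_oracle <- function(data) {
  y <- xtabs(value ~ subject + day + sequence, data = data)
  S <- dim(y)[1]; D <- dim(y)[2]; Q <- dim(y)[3]
  gm <- mean(y)
  ms <- apply(y, 1, mean); md <- apply(y, 2, mean); mq <- apply(y, 3, mean)
  msd <- apply(y, c(1, 2), mean); msq <- apply(y, c(1, 3), mean)
  mdq <- apply(y, c(2, 3), mean)
  ss_day <- S * Q * sum((md - gm)^2)
  ss_seq <- S * D * sum((mq - gm)^2)
  ss_dq <- S * sum((sweep(sweep(mdq, 1, md), 2, mq) + gm)^2)
  err_day <- Q * sum((msd - outer(ms, md, `+`) + gm)^2)
  err_seq <- D * sum((msq - outer(ms, mq, `+`) + gm)^2)
  resid <- y
  for (s in 1:S) for (d in 1:D) for (q in 1:Q)
    resid[s, d, q] <- y[s, d, q] - msd[s, d] - msq[s, q] - mdq[d, q] +
      ms[s] + md[d] + mq[q] - gm
  err_dq <- sum(resid^2)
  data.frame(
    effect = c("day", "sequence", "day:sequence"),
    F = c((ss_day / (D - 1)) / (err_day / ((S - 1) * (D - 1))),
          (ss_seq / (Q - 1)) / (err_seq / ((S - 1) * (Q - 1))),
          (ss_dq / ((D - 1) * (Q - 1))) /
            (err_dq / ((S - 1) * (D - 1) * (Q - 1)))))
}

test_that("rm_anova matches a brute-force sums-of-squares oracle", {
  set.seed(17)
  toy <- expand.grid(subject = 1:4, day = 1:3,
                     sequence = c("repeated", "random"))
  toy$value <- rnorm(nrow(toy), mean = 5 + toy$day * 0.3)
  res <- rm_anova(toy)
  orc <- anova_oracle(toy)
  expect_equal(res$F[match(orc$effect, res$effect)], orc$F,
               tolerance = 1e-8)
})

test_that("rm_anova handles degenerate inputs explicitly", {
  toy <- expand.grid(subject = 1:4, day = 1:3,
                     sequence = c("repeated", "random"))
  toy$value <- 5
  res <- rm_anova(toy)
  expect_identical(res$F, c(0, 0, 0))
  expect_identical(res$p, c(1, 1, 1))

  # pure additive day effect, no noise: day F is infinite and flagged,
  # interaction stays zero
  toy2 <- toy
  toy2$value <- as.numeric(toy2$day)
  res2 <- rm_anova(toy2)
  expect_identical(res2$F[res2$effect == "day"], Inf)
  expect_true(res2$degenerate[res2$effect == "day"])
  expect_identical(res2$F[res2$effect == "day:sequence"], 0)

  expect_error(rm_anova(toy[-1, ]), "incomplete|unbalanced")
})

test_that("rm_anova detects a large programmed interaction at n = 10", {
  n_seeds <- 200
  sig <- 0
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    d <- expand.grid(subject = 1:10, day = 1:5,
                     sequence = c("repeated", "random"))
    d$value <- 10 - 0.2 * d$day -
      ifelse(d$sequence == "repeated", 0.4 * d$day, 0) +
      rnorm(nrow(d), 0, 0.5)
    res <- rm_anova(d)
    if (res$p[res$effect == "day:sequence"] < 0.05) sig <- sig + 1
  }
  expect_gte(sig / n_seeds, 0.8)
})

test_that("explicit recognition applies the 2-of-3 / 4-of-7 criterion", {
  truth <- c(rep(TRUE, 3), rep(FALSE, 7))

  all_right <- score_recognition(truth, truth)
  expect_identical(all_right$percent_correct, 100)
  expect_true(all_right$explicit)

  # high percent correct without enough hits is not explicit
  one_hit <- score_recognition(truth, c(TRUE, FALSE, FALSE, rep(FALSE, 7)))
  expect_identical(one_hit$percent_correct, 80)
  expect_false(one_hit$explicit)

  # exactly at criterion: 2 hits and 4 correct rejections
  border <- score_recognition(truth, c(TRUE, TRUE, FALSE,
                                       rep(TRUE, 3), rep(FALSE, 4)))
  expect_identical(border$hits, 2L)
  expect_identical(border$correct_rejections, 4L)
  expect_identical(border$percent_correct, 60)
  expect_true(border$explicit)

  expect_error(score_recognition(rep(TRUE, 10), rep(TRUE, 10)), "exactly 3")
  expect_error(score_recognition(truth[1:9], rep(TRUE, 9)), "10")
})
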