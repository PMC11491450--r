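null_cube <- function(n, levels, seed, effect = 0) {
  d <- expand.grid(c(list(participant = seq_len(n)),
                     lapply(levels, function(l) factor(seq_len(l)))))
  withr::with_seed(seed, {
    d$value <- stats::rnorm(nrow(d)) +
      rep(stats::rnorm(n, sd = 1.5), length.out = nrow(d))  # subject effect
    if (effect != 0)
      d$value <- d$value + effect * (as.integer(d[[2]]) - 1)
  })
  d
}

test_that("a two-level factor reproduces the paired t test exactly", {
  d <- null_cube(10, list(task = 2), seed = 1, effect = 0.6)
  a <- rm_anova(d, "value", "participant", "task")
  x <- d$value[d$task == 1][order(d$participant[d$task == 1])]
  y <- d$value[d$task == 2][order(d$participant[d$task == 2])]
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  expect_equal(a$gg_epsilon, 1)
})

test_that("F, epsilon and p agree with an independent multivariate routine", {
  skip_if_not_installed("car")
  d <- null_cube(12, list(task = 2, stage = 3, area = 4), seed = 2,
                 effect = 0.4)
  mine <- rm_anova(d, "value", "participant", c("task", "stage", "area"))
  # rebuild the subject x cells matrix for the multivariate route
  cells <- expand.grid(task = factor(1:2), stage = factor(1:3),
                       area = factor(1:4))
  Y <- matrix(NA_real_, 12, nrow(cells))
  for (j in seq_len(nrow(cells))) {
    sel <- d$task == cells$task[j] & d$stage == cells$stage[j] &
      d$area == cells$area[j]
    Y[, j] <- d$value[sel][order(d$participant[sel])]
  }
  mod <- stats::lm(Y ~ 1)
  aa <- car::Anova(mod, idata = cells, idesign = ~ task * stage * area,
                   type = 3)
  s <- suppressWarnings(summary(aa, multivariate = FALSE))
  uni <- s$univariate.tests
  adj <- s$pval.adjustments
  for (i in seq_len(nrow(mine))) {
    eff <- gsub(":", ":", mine$effect[i])
    expect_equal(mine$F[i], unname(uni[eff, "F value"]), tolerance = 1e-6)
    expect_equal(mine$p[i], unname(uni[eff, "Pr(>F)"]), tolerance = 1e-6)
    if (mine$df1[i] > 1) {
      expect_equal(mine$gg_epsilon[i], unname(adj[eff, "GG eps"]),
                   tolerance = 1e-6)
      expect_equal(mine$p_gg[i], unname(adj[eff, "Pr(>F[GG])"]),
                   tolerance = 1e-6)
    }
  }
})

test_that("sums of squares decompose the total exactly", {
  d <- null_cube(8, list(a = 2, b = 3), seed = 3, effect = 0.5)
  tab <- rm_anova(d, "value", "participant", c("a", "b"))
  subj_means <- tapply(d$value, d$participant, mean)
  ss_subject <- 6 * sum((subj_means - mean(d$value))^2)
  total <- sum((d$value - mean(d$value))^2)
  expect_equal(sum(tab$ss) + sum(tab$ss_error) + ss_subject, total,
               tolerance = total * 1e-6)
  expect_true(all(tab$gg_epsilon <= 1 &
                    tab$gg_epsilon >= 1 / tab$df1))
  expect_true(all(tab$peta2 >= 0 & tab$peta2 <= 1))
  expect_error(rm_anova(d[-1, ], "value", "participant", c("a", "b")),
               "complete")
})

test_that("an injected one-SD within-subject effect is detected at n = 24", {
  hits <- 0
  for (r in 1:60) {
    d <- null_cube(24, list(task = 2), seed = 400 + r)
    withr::with_seed(500 + r,
      d$value <- d$value + (as.integer(d$task) - 1) *
        stats::rnorm(1, mean = 1, sd = 0))
    a <- rm_anova(d, "value", "participant", "task")
    hits <- hits + (a$p < 0.05)
  }
  expect_gte(hits / 60, 0.8)
})

test_that("post-hoc paired t tests apply the Bonferroni rule", {
  d <- null_cube(10, list(task = 2, stage = 3), seed = 5, effect = 0.7)
  ph <- posthoc_paired_bonferroni(d, "value", "participant",
                                  compare = "task", per_level_of = "stage")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_bonf, pmin(1, ph$p * 3), tolerance = 1e-12)
  # oracle: direct paired t at one stratum
  s1 <- d[d$stage == 1, ]
  x <- s1$value[s1$task == 1][order(s1$participant[s1$task == 1])]
  y <- s1$value[s1$task == 2][order(s1$participant[s1$task == 2])]
  tt <- stats::t.test(x, y, paired = TRUE)
  expect_equal(ph$p[ph$stratum == "1"], tt$p.value, tolerance = 1e-9)
  # degenerate zero-difference comparison
  dz <- d
  dz$value[dz$task == 2] <- dz$value[dz$task == 1]
  phz <- posthoc_paired_bonferroni(dz, "value", "participant",
                                   compare = "task")
  expect_equal(phz$t, 0)
  expect_equal(phz$p_bonf, 1)
  expect_error(posthoc_paired_bonferroni(d[d$participant <= 2, ],
                                         "value", "participant", "task"),
               "participants")
})

test_that("significance markers follow the printed thresholds", {
  expect_equal(significance_annotation(c(0.049, 0.004, 0.20, 0.010, 0.0051)),
               c("*", "***", "", "**", "**"))
  expect_error(significance_annotation(1.5))
})
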