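test_that("one-way RM ANOVA handles degenerate and shifted data", {
  # no condition variance -> F = 0
  Y <- matrix(rep(rnorm(6), 4), 6, 4)
  res <- rm_anova_oneway(Y)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # adding a constant to one subject's whole row leaves F unchanged
  set.seed(2)
  Y2 <- matrix(rnorm(24), 6, 4)
  r1 <- rm_anova_oneway(Y2)
  Y3 <- Y2; Y3[2, ] <- Y3[2, ] + 100
  r2 <- rm_anova_oneway(Y3)
  expect_equal(r1$F, r2$F)
  expect_equal(r1$p, r2$p)
  # unit rescaling (uV -> mV) leaves the statistics unchanged
  r3 <- rm_anova_oneway(Y2 / 1000)
  expect_equal(r1$F, r3$F)
  expect_equal(r1$epsilon, r3$epsilon)
  # long input equals wide input
  long <- data.frame(subject = rep(1:6, 4), condition = rep(1:4, each = 6),
                     value = as.vector(Y2))
  expect_equal(rm_anova_oneway(long)$F, r1$F)
  expect_error(rm_anova_oneway(Y2[1:2, ]), "three subjects")
})

test_that("one-way RM ANOVA agrees with the car::Anova mlm route", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    n <- 5 + seed %% 4
    Y <- matrix(rnorm(n * 4, rep(c(0, 0.5, 1.2, 0.8), each = n)), n, 4)
    mine <- rm_anova_oneway(Y)
    mlm <- stats::lm(Y ~ 1)
    av <- car::Anova(mlm, idata = data.frame(day = factor(1:4)),
                     idesign = ~day, type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    expect_equal(mine$F, unname(s$univariate.tests["day", "F value"]),
                 tolerance = 1e-10)
    expect_equal(mine$epsilon, unname(s$pval.adjustments["day", "GG eps"]),
                 tolerance = 1e-10)
    expect_equal(mine$p, unname(s$pval.adjustments["day", "Pr(>F[GG])"]),
                 tolerance = 1e-10)
  }
})

test_that("GG epsilon hits its bounds on constructed covariance structures", {
  # exactly spherical sample covariance -> epsilon 1
  Y <- spherical_data(8, 4)
  expect_equal(rm_anova_oneway(Y + rep(c(0, 1, 2, 3), each = 8))$epsilon, 1)
  # rank-one within-subject structure -> epsilon at its 1/(k-1) floor
  x <- rnorm(8)
  Yr <- cbind(x, -x, 0.5 * x, 2 * x)
  expect_equal(rm_anova_oneway(Yr)$epsilon, 1 / 3, tolerance = 1e-9)
})

test_that("mixed ANOVA agrees with car for balanced and unbalanced groups", {
  for (cfg in list(c(6, 6, 31), c(6, 5, 32), c(4, 7, 33))) {
    set.seed(cfg[3])
    n1 <- cfg[1]; n2 <- cfg[2]; k <- 4
    Y <- rbind(
      matrix(rnorm(n1 * k, rep(c(0, 1, 2, 2.5), each = n1)), n1, k),
      matrix(rnorm(n2 * k, rep(c(0, 0.5, 0.5, 0.5), each = n2)), n2, k)
    )
    g <- c(rep("WT", n1), rep("AS", n2))
    long <- data.frame(subject = rep(seq_len(n1 + n2), k),
                       group = rep(g, k),
                       condition = rep(1:k, each = n1 + n2),
                       value = as.vector(Y))
    mine <- mixed_anova(long)
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    mlm <- stats::lm(Y ~ g, data = data.frame(g = factor(g)))
    av <- car::Anova(mlm, idata = data.frame(day = factor(1:k)),
                     idesign = ~day, type = 3)
    s <- suppressWarnings(summary(av, multivariate = FALSE))
    options(old)
    ut <- s$univariate.tests
    expect_equal(mine$F, unname(c(ut["g", "F value"], ut["day", "F value"],
                                  ut["g:day", "F value"])), tolerance = 1e-9)
    expect_equal(mine$epsilon[2], unname(s$pval.adjustments["day", "GG eps"]),
                 tolerance = 1e-10)
    expect_equal(mine$p[3],
                 unname(s$pval.adjustments["g:day", "Pr(>F[GG])"]),
                 tolerance = 1e-10)
  }
})

test_that("mixed ANOVA matches a brute-force sums-of-squares oracle under
           group-label permutation", {
  # 4-subject toy table, balanced; naive cell-mean oracle
  set.seed(44)
  Y <- matrix(rnorm(8, rep(c(0, 2), each = 4)), 4, 2)
  perms <- list(c("a", "a", "b", "b"), c("a", "b", "a", "b"),
                c("b", "a", "a", "b"))
  for (g in perms) {
    long <- data.frame(subject = rep(1:4, 2), group = rep(g, 2),
                       condition = rep(1:2, each = 4), value = as.vector(Y))
    mine <- mixed_anova(long)
    # oracle sums of squares, balanced two-group two-condition case
    gm <- mean(Y)
    sm <- rowMeans(Y); cm <- colMeans(Y)
    gmeans <- tapply(sm, g, mean)
    cellm <- sapply(1:2, function(cc) tapply(Y[, cc], g, mean))
    ssg <- 2 * sum(2 * (gmeans - gm)^2)
    sss <- 2 * sum((sm - gmeans[g])^2)
    ssc <- 4 * sum((cm - gm)^2)
    ssi <- sum(2 * (cellm - outer(gmeans, rep(1, 2)) -
                      outer(rep(1, 2), cm) + gm)^2)
    sse <- sum((Y - cellm[g, ] - as.numeric(sm - gmeans[g]))^2)
    expect_equal(mine$F[1], (ssg / 1) / (sss / 2), tolerance = 1e-9)
    expect_equal(mine$F[2], (ssc / 1) / (sse / 2), tolerance = 1e-9)
    expect_equal(mine$F[3], (ssi / 1) / (sse / 2), tolerance = 1e-9)
  }
  expect_error(mixed_anova(data.frame(subject = rep(1:4, 2),
                                      group = "a",
                                      condition = rep(1:2, each = 4),
                                      value = rnorm(8))), "two groups")
})

test_that("Sidak and Holm adjustments follow their closed forms", {
  expect_equal(sidak_adjust(0.01, 3), 0.029701)
  expect_equal(sidak_adjust(0.2, 1), 0.2)
  df <- data.frame(condition = rep(c("d1", "d2", "d3"), each = 6),
                   subject = rep(1:6, 3),
                   value = c(rnorm(6), rnorm(6, 3), rnorm(6, 3.2)))
  ph <- pairwise_posthoc(df, method = "sidak", subject = "subject")
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p_adj, sidak_adjust(ph$p, 3))
  ph_h <- pairwise_posthoc(df, method = "holm", subject = "subject")
  expect_equal(ph_h$p_adj, p.adjust(ph_h$p, "holm"))
  expect_error(pairwise_posthoc(df, comparisons = list(c("d1", "zz"))),
               "unknown level")
  # the worked Holm example: (0.001, 0.04, 0.03) -> (0.003, 0.06, 0.06)
  expect_equal(p.adjust(c(0.001, 0.04, 0.03), "holm"), c(0.003, 0.06, 0.06))
})

test_that("t tests match the textbook formulas and symmetries", {
  x <- c(1.1, 2.3, 3.1, 4.7); y <- c(2.0, 3.1, 4.4, 6.0)
  r <- t_test(x, y)
  # independent pooled-variance formula
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  expect_equal(r$t, t_manual)
  expect_equal(r$df, 6)
  expect_equal(r$p, 2 * pt(-abs(t_manual), 6))
  expect_equal(t_test(y, x)$t, -r$t)
  rp <- t_test(x, y, paired = TRUE)
  d <- x - y
  expect_equal(rp$t, mean(d) / (sd(d) / 2))
  # identical samples: t = 0; shared zero variance with different means errors
  expect_equal(t_test(x, x)$t, 0)
  expect_error(t_test(rep(1, 4), rep(2, 4)), "zero-variance")
})
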