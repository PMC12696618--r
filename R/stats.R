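# --- helpers ---------------------------------------------------------------

# long -> wide subjects x conditions matrix with completeness checks
rm_wide <- function(data, value = "value", subject = "subject",
                    condition = "condition") {
  if (is.matrix(data)) return(data)
  if (is.data.frame(data) && all(vapply(data, is.numeric, TRUE)) &&
      !all(c(value, subject, condition) %in% names(data))) {
    return(as.matrix(data))
  }
  stopifnot(all(c(value, subject, condition) %in% names(data)))
  subj <- factor(data[[subject]], levels = unique(data[[subject]]))
  cond <- factor(data[[condition]], levels = unique(data[[condition]]))
  tab <- table(subj, cond)
  if (any(tab != 1L))
    stop_veptime("repeated-measures design must have exactly one value per ",
                 "subject x condition cell")
  Y <- matrix(NA_real_, nlevels(subj), nlevels(cond),
              dimnames = list(levels(subj), levels(cond)))
  Y[cbind(as.integer(subj), as.integer(cond))] <- data[[value]]
  Y
}

# Greenhouse-Geisser epsilon from a within-condition covariance matrix
gg_epsilon <- function(S) {
  k <- ncol(S)
  Sd <- sweep(sweep(S, 1L, rowMeans(S)), 2L, colMeans(S)) + mean(S)
  lam <- eigen(Sd, symmetric = TRUE, only.values = TRUE)$values
  denom <- (k - 1) * sum(lam^2)
  if (denom <= 0) return(1)
  eps <- sum(lam)^2 / denom
  min(max(eps, 1 / (k - 1)), 1)
}

# --- one-way repeated measures ANOVA ---------------------------------------

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subjects F test of a single repeated factor (e.g.
#' training day), with the Greenhouse-Geisser sphericity epsilon estimated
#' from the sample covariance of the within-subject scores and applied
#' unconditionally to both degrees of freedom (fractional dfs are reported,
#' matching the convention of reporting e.g. F(1.8, 46.9)).
#'
#' @param data Either a subjects x conditions numeric matrix (or an
#'   all-numeric wide data frame), or a long data frame with `subject`,
#'   `condition` and `value` columns.
#' @param value,subject,condition Column names for long input.
#' @return A one-row tibble: `effect`, `F`, `df1`, `df2` (GG-corrected,
#'   fractional), `epsilon`, `p` (GG-corrected), plus the uncorrected
#'   `df1_unadj`, `df2_unadj`, `p_unadj`.
#' @examples
#' Y <- matrix(rnorm(24), 6, 4)
#' rm_anova_oneway(Y)
#' @export
rm_anova_oneway <- function(data, value = "value", subject = "subject",
                            condition = "condition") {
  Y <- rm_wide(data, value, subject, condition)
  n <- nrow(Y); k <- ncol(Y)
  if (k < 2L) stop_veptime("need at least two within-subject conditions")
  if (n < 3L) stop_veptime("need at least three subjects")
  if (anyNA(Y)) stop_veptime("missing cells in the repeated-measures design")

  gm <- mean(Y)
  cm <- colMeans(Y)
  rm_ <- rowMeans(Y)
  ss_cond <- n * sum((cm - gm)^2)
  resid <- Y - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)

  if (ss_cond <= 1e-12 * max(1, abs(gm))) {
    Fv <- 0; eps <- 1; p <- 1; p_un <- 1
  } else if (ss_err <= 0) {
    warning("zero within-subject error variance: F undefined")
    Fv <- NA_real_; eps <- NA_real_; p <- NA_real_; p_un <- NA_real_
  } else {
    Fv <- (ss_cond / df1) / (ss_err / df2)
    eps <- gg_epsilon(cov(Y))
    p <- pf(Fv, eps * df1, eps * df2, lower.tail = FALSE)
    p_un <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(
    effect = "condition", F = Fv,
    df1 = (if (is.na(eps)) NA_real_ else eps * df1),
    df2 = (if (is.na(eps)) NA_real_ else eps * df2),
    epsilon = eps, p = p,
    df1_unadj = df1, df2_unadj = df2, p_unadj = p_un
  )
}

# --- two-way mixed (split-plot) ANOVA --------------------------------------

#' Two-way mixed ANOVA (between group x within condition)
#'
#' Split-plot decomposition with one between-subjects factor (e.g.
#' genotype) and one within-subjects factor (e.g. session). The
#' Greenhouse-Geisser epsilon is estimated from the pooled within-group
#' covariance and applied unconditionally to the within and interaction
#' terms (the between-subjects test needs no sphericity correction).
#'
#' @param data Long data frame.
#' @param value,subject,group,condition Column names.
#' @return Tibble with one row per effect (`group`, `condition`,
#'   `group:condition`): `F`, `df1`, `df2` (GG-corrected where applicable),
#'   `epsilon`, `p`, and uncorrected dfs/p.
#' @export
mixed_anova <- function(data, value = "value", subject = "subject",
                        group = "group", condition = "condition") {
  stopifnot(all(c(value, subject, group, condition) %in% names(data)))
  subj <- factor(data[[subject]], levels = unique(data[[subject]]))
  grp_of <- tapply(as.character(data[[group]]), subj, function(g) {
    u <- unique(g)
    if (length(u) != 1L) stop_veptime("a subject appears in two groups")
    u
  })
  grp_lvls <- unique(as.character(data[[group]]))
  if (length(grp_lvls) < 2L) stop_veptime("need at least two groups")
  Y <- rm_wide(data, value, subject, condition)
  g <- factor(grp_of[rownames(Y)], levels = grp_lvls)
  n_g <- table(g)
  if (any(n_g < 2L)) stop_veptime("each group needs at least two subjects")
  n <- nrow(Y); k <- ncol(Y); G <- nlevels(g)

  gm <- mean(Y)
  subj_m <- rowMeans(Y)
  grp_m <- as.numeric(tapply(subj_m, g, mean))

  # between-subjects stratum (subject means)
  ss_group <- k * sum(n_g * (grp_m - gm)^2)
  ss_subj <- k * sum((subj_m - grp_m[as.integer(g)])^2)

  # within-subjects stratum on orthonormal condition contrasts; the session
  # main effect uses unweighted group means (type-III convention), so
  # unbalanced groups are handled as standard packages do
  M <- stats::contr.helmert(k)
  M <- sweep(M, 2L, sqrt(colSums(M^2)), `/`)
  Z <- Y %*% M
  zbar_g <- apply(Z, 2L, function(col) as.numeric(tapply(col, g, mean)))
  zbar_g <- matrix(zbar_g, nrow = G)
  m_u <- colMeans(zbar_g)                      # unweighted mean over groups
  ss_cond <- (G^2 / sum(1 / as.numeric(n_g))) * sum(m_u^2)
  zbar_w <- colMeans(Z)
  ss_int <- sum(as.numeric(n_g) *
                  rowSums(sweep(zbar_g, 2L, zbar_w)^2))
  ss_err <- sum((Z - zbar_g[as.integer(g), , drop = FALSE])^2)

  df_group <- G - 1
  df_subj <- n - G
  df_cond <- k - 1
  df_int <- (G - 1) * (k - 1)
  df_err <- (n - G) * (k - 1)

  # pooled within-group covariance
  Sp <- matrix(0, k, k)
  for (lev in levels(g)) {
    Yg <- Y[g == lev, , drop = FALSE]
    Sp <- Sp + (nrow(Yg) - 1) * cov(Yg)
  }
  Sp <- Sp / (n - G)
  eps <- gg_epsilon(Sp)

  F_group <- (ss_group / df_group) / (ss_subj / df_subj)
  F_cond <- (ss_cond / df_cond) / (ss_err / df_err)
  F_int <- (ss_int / df_int) / (ss_err / df_err)

  tibble::tibble(
    effect = c("group", "condition", "group:condition"),
    F = c(F_group, F_cond, F_int),
    df1 = c(df_group, eps * df_cond, eps * df_int),
    df2 = c(df_subj, eps * df_err, eps * df_err),
    epsilon = c(NA_real_, eps, eps),
    p = c(
      pf(F_group, df_group, df_subj, lower.tail = FALSE),
      pf(F_cond, eps * df_cond, eps * df_err, lower.tail = FALSE),
      pf(F_int, eps * df_int, eps * df_err, lower.tail = FALSE)
    ),
    df1_unadj = c(df_group, df_cond, df_int),
    df2_unadj = c(df_subj, df_err, df_err),
    p_unadj = c(
      pf(F_group, df_group, df_subj, lower.tail = FALSE),
      pf(F_cond, df_cond, df_err, lower.tail = FALSE),
      pf(F_int, df_int, df_err, lower.tail = FALSE)
    )
  )
}

# --- post hocs and t tests --------------------------------------------------

#' Sidak adjustment
#'
#' Closed form `p_adj = 1 - (1 - p)^m` for `m` simultaneous comparisons.
#'
#' @param p Raw p values.
#' @param m Number of comparisons (default `length(p)`).
#' @return Adjusted p values (capped at 1).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  pmin(1, 1 - (1 - p)^m)
}

#' Pairwise post hoc t tests with Sidak or Holm adjustment
#'
#' Runs a t test for each requested pair of factor levels (paired across
#' subjects when a subject column is supplied, two-sample otherwise) and
#' adjusts the p values for the number of comparisons. Exact
#' studentized-range (Tukey) and Dunnett distributions are deliberately not
#' implemented; Sidak (default) or Holm are used instead.
#'
#' @param data Long data frame.
#' @param comparisons List of length-2 character vectors of factor levels;
#'   default all pairs.
#' @param method `"sidak"` or `"holm"`.
#' @param value,factor,subject Column names; `subject = NULL` gives unpaired
#'   tests.
#' @param var_equal Pool variances in unpaired tests (classical t, default
#'   `TRUE`).
#' @return Tibble: level1, level2, estimate (mean difference level1-level2),
#'   t, df, p, p_adj, method.
#' @export
pairwise_posthoc <- function(data, comparisons = NULL,
                             method = c("sidak", "holm"),
                             value = "value", factor = "condition",
                             subject = NULL, var_equal = TRUE) {
  method <- match.arg(method)
  stopifnot(all(c(value, factor) %in% names(data)))
  lvls <- unique(as.character(data[[factor]]))
  if (is.null(comparisons)) {
    comparisons <- utils::combn(lvls, 2L, simplify = FALSE)
  }
  rows <- lapply(comparisons, function(cmp) {
    if (!all(cmp %in% lvls))
      stop_veptime("comparison references unknown level(s): ",
                   paste(setdiff(cmp, lvls), collapse = ", "))
    d1 <- data[data[[factor]] == cmp[1], ]
    d2 <- data[data[[factor]] == cmp[2], ]
    if (!is.null(subject)) {
      m <- match(d1[[subject]], d2[[subject]])
      if (anyNA(m)) stop_veptime("paired comparison with unmatched subjects")
      res <- t_test(d1[[value]], d2[[value]][m], paired = TRUE)
    } else {
      res <- t_test(d1[[value]], d2[[value]], var_equal = var_equal)
    }
    tibble::tibble(level1 = cmp[1], level2 = cmp[2],
                   estimate = mean(d1[[value]]) - mean(d2[[value]]),
                   t = res$t, df = res$df, p = res$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- switch(method,
    sidak = sidak_adjust(out$p),
    holm = p.adjust(out$p, method = "holm")
  )
  out$method <- method
  out
}

#' Two-sided t test
#'
#' Thin wrapper around [stats::t.test()] returning a tidy row; paired or
#' two-sample (classical pooled-variance by default, matching common
#' practice in the field's statistics packages).
#'
#' @param x,y Numeric samples (`y` the second sample, or the paired
#'   partner).
#' @param paired Paired test on `x - y`?
#' @param var_equal Pool variances for the unpaired test.
#' @return Tibble: `t`, `df`, `p`.
#' @export
t_test <- function(x, y, paired = FALSE, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L)
    stop_veptime("each sample needs at least two observations")
  zero_var <- if (paired) stats::var(x - y) == 0 else
    (stats::var(x) == 0 && stats::var(y) == 0)
  if (zero_var && isTRUE(all.equal(mean(x), mean(y)))) {
    df <- if (paired) length(x) - 1 else length(x) + length(y) - 2
    return(tibble::tibble(t = 0, df = df, p = 1))
  }
  if (zero_var) stop_veptime("zero-variance comparison")
  res <- stats::t.test(x, y, paired = paired, var.equal = var_equal)
  tibble::tibble(t = unname(res$statistic), df = unname(res$parameter),
                 p = res$p.value)
}
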