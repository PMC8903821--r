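# The experimental statistics battery: nonparametric tests, JZS Bayes
# factors, the mixed log-RT ANOVA, correlations and the normative
# regression for Brixton total errors.

#' Mann-Whitney rank-sum test
#'
#' Uses the U/W convention in which `W` counts, over all `n_x * n_y` pairs,
#' the pairs where the `x` observation exceeds the `y` observation (ties
#' count one half), so `W` lies in `[0, n_x * n_y]` with midpoint
#' `n_x * n_y / 2` for identical samples.  The two-tailed p-value uses the
#' normal approximation with the mid-rank tie correction.
#'
#' @param x,y Numeric samples.
#' @return List with `W` and two-tailed `p` (`p` is `NA` when the pooled
#'   sample is constant).
#' @export
mann_whitney_w <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- table(c(x, y))
  tie_corr <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((N + 1) - tie_corr / (N * (N - 1)))
  if (v <= 0) {
    warning("pooled sample is constant; p undefined")
    return(list(W = W, p = NA_real_))
  }
  z <- (W - nx * ny / 2) / sqrt(v)
  list(W = W, p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson chi-square for a 2x2 table
#'
#' No continuity correction is applied (the corrected statistic does not
#' reproduce standard textbook values for weak associations).
#'
#' @param tab A 2x2 matrix of non-negative counts with positive margins.
#' @return The chi-square statistic (1 df).
#' @export
chi2_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  e <- outer(rs, cs) / n
  sum((tab - e)^2 / e)
}

# JZS Bayes factor from a two-sample t statistic.  The Cauchy prior on
# the standardised effect is expressed as a scale mixture of normals with
# an inverse-gamma(1/2, scale^2/2) mixing density on g, so the marginal
# likelihood ratio reduces to a one-dimensional integral over g in which
# every factor is an ordinary power -- no noncentral densities needed.
jzs_bf10_from_t <- function(t, n1, n2, scale = 0.5) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)       # effective sample size
  log_igamma <- function(g) {
    0.5 * log(scale^2 / 2) - lgamma(0.5) - 1.5 * log(g) - scale^2 / (2 * g)
  }
  integrand <- function(g) {
    exp(-0.5 * log1p(N * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
          (nu + 1) / 2 * log1p(t^2 / nu) +
          log_igamma(g))
  }
  stats::integrate(integrand, lower = 0, upper = Inf,
                   rel.tol = 1e-10, abs.tol = 0)$value
}

#' Two-sample JZS Bayes factor
#'
#' Bayes factor for a two-sample comparison of means under a Cauchy prior
#' on the standardised effect size (location 0, scale `scale`; default
#' 1/2), computed by numerical integration of the marginal likelihood of
#' the observed t statistic.  `BF10 > 1` favours a difference;
#' `BF01 = 1/BF10`.
#'
#' @param x,y Numeric samples (at least two observations each).
#' @param scale Cauchy prior scale.
#' @return List with `BF10`, `BF01`, `t`, `df`.
#' @export
jzs_bf <- function(x, y, scale = 0.5) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  bf10 <- jzs_bf10_from_t(t, n1, n2, scale)
  list(BF10 = bf10, BF01 = 1 / bf10, t = t, df = n1 + n2 - 2)
}

#' Mixed 2x2 ANOVA on log response times
#'
#' Age group is a between-subjects factor and prior feedback a
#' within-subjects factor (one mean RT per participant per feedback
#' condition).  Sums of squares are computed by the standard mixed-design
#' partition; the between effect is tested against the subject-within-group
#' mean square, the within effect and the interaction against the
#' subject-by-feedback residual.
#'
#' @param data Long-format data frame with columns `participant`, `group`,
#'   `feedback` and `rt` (each participant contributes both feedback
#'   conditions).
#' @param log_transform Log-transform RTs before analysis (default TRUE).
#' @return Data frame with one row per effect (`group`, `feedback`,
#'   `group:feedback`): `F`, `df1`, `df2`, `p`, `peta2`, `SS`.  The subject
#'   and residual SS are stored in the `ss_error` attribute.
#' @export
anova2_logrt <- function(data, log_transform = TRUE) {
  stopifnot(all(c("participant", "group", "feedback", "rt") %in% names(data)))
  y <- if (log_transform) log(data$rt) else data$rt
  subj <- as.character(data$participant)
  grp  <- as.character(data$group)
  fbk  <- as.character(data$feedback)
  if (any(table(subj) != 2L)) stop("each participant needs both feedback conditions")
  n <- length(unique(subj))
  gm <- mean(y)

  subj_mean <- tapply(y, subj, mean)
  subj_grp  <- tapply(grp, subj, `[`, 1L)
  grp_mean  <- tapply(y, grp, mean)
  fbk_mean  <- tapply(y, fbk, mean)
  cell_mean <- tapply(y, list(grp, fbk), mean)
  n_per_grp <- table(subj_grp)

  ss_total <- sum((y - gm)^2)
  ss_bsubj <- 2 * sum((subj_mean - gm)^2)
  ss_group <- 2 * sum(n_per_grp * (grp_mean[names(n_per_grp)] - gm)^2)
  ss_subj  <- ss_bsubj - ss_group
  ss_fbk   <- sum(table(fbk) * (fbk_mean - gm)^2)
  ss_cells <- 0
  for (g in rownames(cell_mean)) for (f in colnames(cell_mean)) {
    ss_cells <- ss_cells + n_per_grp[[g]] * (cell_mean[g, f] - gm)^2
  }
  ss_int <- ss_cells - ss_group - ss_fbk
  ss_res <- ss_total - ss_bsubj - ss_fbk - ss_int

  df2 <- n - 2
  ms_subj <- ss_subj / df2
  ms_res  <- ss_res / df2
  eff <- data.frame(
    effect = c("group", "feedback", "group:feedback"),
    F  = c(ss_group / ms_subj, ss_fbk / ms_res, ss_int / ms_res),
    df1 = 1, df2 = df2,
    SS = c(ss_group, ss_fbk, ss_int),
    stringsAsFactors = FALSE
  )
  eff$p <- stats::pf(eff$F, 1, df2, lower.tail = FALSE)
  eff$peta2 <- c(ss_group / (ss_group + ss_subj),
                 ss_fbk / (ss_fbk + ss_res),
                 ss_int / (ss_int + ss_res))
  attr(eff, "ss_error") <- c(subject = ss_subj, residual = ss_res,
                             total = ss_total)
  eff
}

#' Pearson and first-order partial correlation
#'
#' The partial correlation removes the linear effect of a single covariate
#' from both variables, via the standard residual formula.
#'
#' @param x,y Numeric vectors (length >= 4).
#' @param covariate Numeric vector, same length.
#' @return List with `r` and `r_partial`.
#' @export
pearson_partial <- function(x, y, covariate) {
  stopifnot(length(x) == length(y), length(x) == length(covariate),
            length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(covariate) == 0) {
    stop("zero variance input")
  }
  rxy <- stats::cor(x, y)
  rxc <- stats::cor(x, covariate)
  ryc <- stats::cor(y, covariate)
  list(r = rxy,
       r_partial = (rxy - rxc * ryc) / sqrt((1 - rxc^2) * (1 - ryc^2)))
}

#' Normative prediction of Brixton total errors
#'
#' Published normative regression of total errors on age and years of
#' education from a sample of 283 healthy controls:
#' `TE = 6.12 + 0.23 * age - 0.24 * education`.
#'
#' @param age Age in years.
#' @param education Years of education.
#' @return Predicted total errors.
#' @export
normative_te <- function(age, education) {
  stopifnot(all(age >= 0), all(education >= 0))
  6.12 + 0.23 * age - 0.24 * education
}

#' Shapiro-Wilk normality screen
#'
#' Convenience wrapper used when reporting group measures.
#'
#' @param x Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_screen <- function(x) {
  s <- stats::shapiro.test(x)
  list(W = unname(s$statistic), p = s$p.value)
}
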