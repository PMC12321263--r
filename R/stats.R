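## Scheirer-Ray-Hare rank-based two-factor test and the two-predictor
## linear model of PER magnitude.

#' Scheirer–Ray–Hare test
#'
#' Rank-based nonparametric analogue of crossed two-way ANOVA. All `N`
#' observations are ranked jointly (midranks for ties); sums of squares for
#' the two main effects and their interaction are computed on the ranks
#' (type-II sums of squares, so unbalanced main-effect tests do not depend
#' on factor order; for balanced designs these equal the sequential sums).
#' Each effect's statistic is
#' `H = SS_effect / MS_total`, where `MS_total = SS_total / (N - 1)` is the
#' variance of the midranks — which already carries the tie reduction
#' `D = 1 - sum(t^3 - t) / (N^3 - N)`, making `H` the classical
#' tie-corrected statistic. `H` is referred to a chi-square upper tail with
#' `a-1`, `b-1` and `(a-1)(b-1)` degrees of freedom.
#'
#' With one factor held at a single level the other factor's `H` equals the
#' tie-corrected Kruskal–Wallis statistic on the same data.
#'
#' @param values numeric outcome vector.
#' @param factor_a,factor_b factors (or vectors coerced to factors) of the
#'   same length as `values`.
#' @return object of class `srh_result`: data.frame `table` with one row
#'   per effect (`H`, `df`, `p_value`), plus `tie_correction`, `N`,
#'   `ss_total`.
#' @export
scheirerRayHare <- function(values, factor_a, factor_b) {
  A <- factor(factor_a)
  B <- factor(factor_b)
  N <- length(values)
  if (length(A) != N || length(B) != N)
    stop("values and factors differ in length")
  if (anyNA(values) || anyNA(A) || anyNA(B))
    stop("missing values are not supported")
  a <- nlevels(A); b <- nlevels(B)
  if (a < 2L && b < 2L) stop("at least one factor needs >= 2 levels")
  if (a < 2L || b < 2L)
    warning("a factor has a single level; its effect and the interaction ",
            "have 0 degrees of freedom")
  cell <- table(A, B)
  if (any(cell == 0L)) {
    empty <- which(cell == 0L, arr.ind = TRUE)[1L, ]
    stop("empty cell: factor_a = ", levels(A)[empty[1]],
         ", factor_b = ", levels(B)[empty[2]],
         " (designs with empty cells are not supported)")
  }
  r <- rank(values)
  ss_total <- sum((r - mean(r))^2)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  df <- c(A = a - 1L, B = b - 1L, `A:B` = (a - 1L) * (b - 1L))
  if (ss_total == 0) {
    ss <- c(A = 0, B = 0, `A:B` = 0)
    H <- c(A = 0, B = 0, `A:B` = 0)
  } else {
    rss <- function(fml) {
      mm <- stats::model.matrix(fml, data = data.frame(A = A, B = B))
      sum(stats::lm.fit(mm, r)$residuals^2)
    }
    rss_a  <- if (a > 1L) rss(~A) else ss_total
    rss_b  <- if (b > 1L) rss(~B) else ss_total
    rss_ab <- if (a > 1L && b > 1L) rss(~ A + B)
              else min(rss_a, rss_b)
    rss_full <- if (a > 1L && b > 1L) rss(~ A * B) else rss_ab
    ## type-II sums of squares on ranks
    ss <- c(A = max(0, rss_b - rss_ab),
            B = max(0, rss_a - rss_ab),
            `A:B` = max(0, rss_ab - rss_full))
    ms_total <- ss_total / (N - 1)
    H <- ss / ms_total
  }
  p <- ifelse(df > 0, pchisq(H, df, lower.tail = FALSE), NA_real_)
  p[df > 0 & H == 0] <- 1
  tab <- data.frame(effect = c("factor_a", "factor_b", "interaction"),
                    SS = unname(ss), df = unname(df), H = unname(H),
                    p_value = unname(p), stringsAsFactors = FALSE)
  structure(list(table = tab, tie_correction = tie_corr, N = N,
                 ss_total = ss_total),
            class = "srh_result")
}

#' @export
print.srh_result <- function(x, ...) {
  cat("Scheirer-Ray-Hare test (N =", x$N, ", tie correction =",
      format(x$tie_correction, digits = 4), ")\n")
  tab <- x$table
  tab$H <- signif(tab$H, 5)
  tab$p_value <- signif(tab$p_value, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Linear model of PER magnitude from GRN responses
#'
#' Ordinary least squares of the per-odor PER magnitude on the
#' trial-averaged peak responses of sweet (Gr5a) and bitter (Gr66a) GRNs,
#' with an intercept by default. A positive weight marks a pathway that
#' enhances PER; a negative weight marks suppression. Model quality is the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param gr5a,gr66a numeric per-odor predictor vectors (trial-averaged
#'   peak dF/F).
#' @param per_magnitude numeric per-odor PER magnitude (e.g. mean
#'   integrated PER duration).
#' @param intercept fit an intercept (default TRUE).
#' @return object of class `per_linear_fit`: `weight_gr5a`, `weight_gr66a`,
#'   `intercept`, `r_squared`, `fitted`, `residuals`, `n`, and the
#'   underlying `lm` fit.
#' @export
fitPerModel <- function(gr5a, gr66a, per_magnitude, intercept = TRUE) {
  n <- length(per_magnitude)
  if (length(gr5a) != n || length(gr66a) != n)
    stop("predictor and outcome lengths differ")
  if (n < 3L) stop("need at least 3 odors")
  ss_tot <- sum((per_magnitude - mean(per_magnitude))^2)
  if (ss_tot == 0) stop("constant outcome: R^2 undefined")
  dat <- data.frame(y = per_magnitude, x1 = gr5a, x2 = gr66a)
  fml <- if (intercept) y ~ x1 + x2 else y ~ x1 + x2 - 1
  fit <- lm(fml, data = dat)
  if (anyNA(coef(fit)))
    stop("collinear predictors: model is rank deficient")
  ss_res <- sum(residuals(fit)^2)
  cf <- coef(fit)
  structure(list(
    weight_gr5a = unname(cf[["x1"]]),
    weight_gr66a = unname(cf[["x2"]]),
    intercept = if (intercept) unname(cf[["(Intercept)"]]) else 0,
    r_squared = 1 - ss_res / ss_tot,
    fitted = unname(fitted(fit)),
    residuals = unname(residuals(fit)),
    n = n, lm_fit = fit
  ), class = "per_linear_fit")
}

#' @export
print.per_linear_fit <- function(x, ...) {
  cat("PER ~ Gr5a + Gr66a linear model (n =", x$n, "odors)\n")
  cat("  weight Gr5a: ", format(x$weight_gr5a, digits = 4),
      "\n  weight Gr66a:", format(x$weight_gr66a, digits = 4),
      "\n  intercept:   ", format(x$intercept, digits = 4),
      "\n  R^2:         ", format(x$r_squared, digits = 4), "\n")
  invisible(x)
}

#' Bonferroni-adjusted p-values
#'
#' Convenience wrapper around `p.adjust(..., "bonferroni")`; not applied by
#' default anywhere in the package (per-test p-values are reported).
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) stats::p.adjust(p, method = "bonferroni")
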