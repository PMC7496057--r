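#' Spearman rank correlation with the t-approximation P value
#'
#' rho is the Pearson correlation of mid-ranks (ties get average ranks);
#' the two-sided P value comes from t = rho sqrt((n-2)/(1-rho^2)) on n-2
#' degrees of freedom — the large-sample approximation most scientific
#' stacks default to for breed-scale n.
#'
#' @param x,y numeric vectors of equal length >= 3, no missing values.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for a constant vector")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) {
    2 * stats::pt(-Inf, n - 2) + .Machine$double.xmin  # degenerate, ~0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p_value = min(1, max(p, .Machine$double.xmin)), n = n)
}

#' Jackknife bias-corrected Spearman correlation
#'
#' Returns n * rho_full - (n-1) * mean(leave-one-out rho): the first-order
#' bias-corrected estimate. Comparing it with the plain rho indicates how
#' much single observations (outlier breeds) drive the correlation.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return list with `estimate` (bias-corrected), `rho` (full-sample),
#'   `loo` (leave-one-out rho values), `n`.
#' @export
jackknife_correlation <- function(x, y) {
  n <- length(x)
  if (n < 4) stop("jackknife needs at least 4 observations")
  full <- spearman(x, y)$rho
  loo <- vapply(seq_len(n),
                function(i) spearman(x[-i], y[-i])$rho, 0)
  list(estimate = n * full - (n - 1) * mean(loo),
       rho = full, loo = loo, n = n)
}

#' Standardized regression residuals
#'
#' Ordinary least squares of a trait on one or more covariates (with
#' intercept), residuals divided by their sample standard deviation
#' (n-1 denominator), so the output has mean 0 and SD 1. Used to study a
#' trait (cancer mortality, longevity) independently of body weight and
#' life expectancy. `studentized = TRUE` returns internally studentized
#' (leverage-adjusted) residuals instead, rescaled to unit SD.
#'
#' @param trait numeric response vector.
#' @param covariates numeric vector, matrix or data.frame of covariates.
#' @param studentized use leverage-adjusted residuals (default FALSE).
#' @return numeric vector of standardized residuals.
#' @export
residualize <- function(trait, covariates, studentized = FALSE) {
  X <- as.matrix(covariates)
  if (nrow(X) != length(trait))
    stop("trait and covariates must have matching length")
  if (length(trait) <= ncol(X) + 1)
    stop("need more observations than covariates + 1")
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("rank-deficient design: collinear covariates")
  fit <- stats::lm(trait ~ X)
  r <- if (studentized) stats::rstandard(fit) else stats::residuals(fit)
  s <- stats::sd(r)
  if (s < .Machine$double.eps^0.5 * max(1, stats::sd(trait)))
    stop("degenerate fit: residual variance is zero")
  as.numeric(scale(r, center = TRUE, scale = TRUE))
}

#' Simple linear regression summary
#'
#' OLS of y on x with intercept; reports the slope, intercept, Pearson
#' correlation of the fit and its two-sided P value.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `slope`, `intercept`, `r`, `p_value`, `n`.
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("at least 3 observations are required")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  p <- stats::coef(summary(fit))["x", "Pr(>|t|)"]
  list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
       r = r, p_value = p, n = length(x))
}

#' Trait correlation and residualization report
#'
#' Augments a breed phenotype table with the residual traits the
#' association stages consume, and reports every pairwise correlation of
#' interest with Spearman rho, its P value and the jackknife bias-corrected
#' estimate:
#' weight vs cancer mortality, weight vs life expectancy, life expectancy
#' vs raw cancer mortality, and life expectancy vs weight-corrected cancer
#' residuals. Two cancer residual columns are emitted to keep the two uses
#' distinct: `cancer_residual_weight` (regression on weight only, the
#' descriptive residual) and `cancer_residual` (multiple regression on
#' weight and life expectancy, the association-scan trait).
#' `longevity_residual` is life expectancy regressed on weight.
#'
#' @param pheno breed phenotype data.frame (see [read_phenotypes()]).
#' @return list with `phenotypes` (augmented table) and `correlations`
#'   (data.frame: pair, rho, p_value, jackknife, n).
#' @export
trait_report <- function(pheno) {
  pheno <- validate_phenotypes(pheno)
  w <- pheno$body_weight_kg
  le <- pheno$life_expectancy_years
  cm <- pheno$cancer_mortality_pct
  pheno$cancer_residual_weight <- residualize(cm, w)
  pheno$cancer_residual <- residualize(cm, cbind(weight = w, lifespan = le))
  pheno$longevity_residual <- residualize(le, w)

  pairs <- list(
    weight_vs_cancer = list(w, cm),
    weight_vs_lifespan = list(w, le),
    lifespan_vs_cancer = list(le, cm),
    lifespan_vs_cancer_residual = list(le, pheno$cancer_residual_weight))
  rows <- lapply(names(pairs), function(nm) {
    xy <- pairs[[nm]]
    sp <- spearman(xy[[1]], xy[[2]])
    jk <- jackknife_correlation(xy[[1]], xy[[2]])
    data.frame(pair = nm, rho = sp$rho, p_value = sp$p_value,
               jackknife = jk$estimate, n = sp$n,
               stringsAsFactors = FALSE)
  })
  lf <- linear_fit(w, cm)
  list(phenotypes = pheno,
       correlations = do.call(rbind, rows),
       weight_cancer_linear = lf)
}
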