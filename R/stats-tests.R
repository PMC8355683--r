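#' Fit a generalized linear model of a residency metric
#'
#' Fits the response against total length and/or sex by least squares
#' (Gaussian family by default) and, when `select = TRUE`, chooses among the
#' candidate structures `{1, TL, sex, TL + sex, TL * sex}` by AIC. Sex is
#' coded with female as the reference level, so a negative sex effect reads
#' "males lower". For count-like responses fitted with a Poisson family the
#' dispersion statistic is reported and a negative binomial refit is
#' suggested when it exceeds 1.5.
#'
#' @param response name of the response column in `data`.
#' @param data data.frame containing the response, `tl_cm` and `sex`.
#' @param terms character vector of predictor terms used when
#'   `select = FALSE` (e.g. `c("tl_cm", "sex")`; `"tl_cm:sex"` adds the
#'   interaction). Empty vector fits the intercept-only model.
#' @param family a [stats::family()] object (default `gaussian()`).
#' @param select if `TRUE`, AIC model selection over the candidate set.
#' @return Object of class `"telemetry_glm"`: coefficient table (estimate,
#'   standard error, t, two-sided p), the fitted [stats::glm] object, the AIC
#'   table when selection was used, and dispersion diagnostics.
#' @export
fit_linear_model <- function(response, data, terms = c("tl_cm", "sex"),
                             family = stats::gaussian(), select = FALSE) {
  stopifnot(response %in% names(data))
  if ("sex" %in% names(data)) data$sex <- stats::relevel(factor(data$sex), ref = "F")
  data <- data[stats::complete.cases(data[, c(response, intersect(c("tl_cm", "sex"), names(data)))]), ]
  mk <- function(tms) stats::as.formula(
    paste(response, "~", if (length(tms)) paste(tms, collapse = " + ") else "1"))
  aic_table <- NULL
  if (select) {
    cands <- list(character(0), "tl_cm", "sex", c("tl_cm", "sex"), c("tl_cm * sex"))
    if (!"sex" %in% names(data) || length(unique(data$sex)) < 2)
      cands <- cands[1:2]  # sex inestimable in a single-sex cohort
    fits <- lapply(cands, function(tms) stats::glm(mk(tms), data = data, family = family))
    aics <- vapply(fits, stats::AIC, numeric(1))
    aic_table <- data.frame(
      model = vapply(cands, function(tms) if (length(tms)) paste(tms, collapse = " + ") else "1", ""),
      aic = aics)
    fit <- fits[[which.min(aics)]]
    terms <- cands[[which.min(aics)]]
  } else {
    fit <- stats::glm(mk(terms), data = data, family = family)
  }
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ", paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "std_error", "t_value", "p_value")
  dispersion <- sm$deviance / sm$df.residual
  structure(list(response = response,
                 terms = if (length(terms)) terms else "1",
                 coefficients = coefs,
                 family = family$family,
                 aic = stats::AIC(fit),
                 aic_table = aic_table,
                 dispersion = dispersion,
                 overdispersed = family$family == "poisson" && dispersion > 1.5,
                 fit = fit),
            class = "telemetry_glm")
}

#' @export
print.telemetry_glm <- function(x, digits = 4, ...) {
  cat("GLM (", x$family, "): ", x$response, " ~ ",
      paste(x$terms, collapse = " + "), "\n", sep = "")
  print(round(x$coefficients, digits))
  if (!is.null(x$aic_table)) {
    cat("selected by AIC from:\n")
    print(transform(x$aic_table, aic = round(aic, 2)), row.names = FALSE)
  }
  if (isTRUE(x$overdispersed))
    cat(sprintf("dispersion %.2f > 1.5: negative binomial refit suggested\n",
                x$dispersion))
  invisible(x)
}

#' @export
coef.telemetry_glm <- function(object, ...) stats::coef(object$fit)

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. Uses exact enumeration when
#' both samples have at most `exact_max_n` observations and no ties;
#' otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric samples (non-empty).
#' @param exact_max_n largest per-group size for the exact null distribution.
#' @return List with `U` (statistic for sample `a`), `p`, and `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max_n = 8) {
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= exact_max_n && length(b) <= exact_max_n && !ties
  ht <- stats::wilcox.test(a, b, exact = exact, correct = !exact)
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (exact) "exact" else "normal approximation, tie-corrected")
}

#' Kruskal-Wallis rank sum test
#'
#' @param groups list of non-empty numeric vectors.
#' @return List with `H` (tie-corrected statistic), `df`, and `p` from the
#'   chi-squared approximation.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(!lengths(groups))) stop("groups must be non-empty")
  ht <- stats::kruskal.test(groups)
  list(H = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Post hoc pairwise rank comparisons after Kruskal-Wallis
#'
#' Dunn-type z statistics on mean ranks with the tie-corrected pooled
#' variance, adjusted for multiple comparisons (Bonferroni by default).
#'
#' @param groups named list of numeric vectors.
#' @param alpha family-wise significance level for the `significant` column.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return data.frame with one row per pair: `group1`, `group2`, `z`,
#'   `p_adjusted`, `significant`.
#' @export
posthoc_kw <- function(groups, alpha = 0.05, p_adjust = "bonferroni") {
  if (length(groups) < 2) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  tie_sizes <- table(x)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_term
  pairs <- utils::combn(names(groups), 2)
  z <- apply(pairs, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) / sqrt(v * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             z = unname(z), p_adjusted = unname(p_adj),
             significant = unname(p_adj < alpha),
             stringsAsFactors = FALSE)
}
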