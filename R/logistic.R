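#' Odds ratio of a 2x2 contingency table
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for a table laid out as
#' exposed-case `a`, exposed-noncase `b`, reference-case `c`,
#' reference-noncase `d`.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @param haldane If `TRUE`, apply the Haldane-Anscombe 0.5 continuity
#'   correction to every cell (exploratory use with zero cells only;
#'   default `FALSE` errors on a zero `b` or `c`).
#' @return The odds ratio.
#' @export
or_2x2 <- function(a, b, c, d, haldane = FALSE) {
  check_counts(a, b, c, d)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  } else if (b * c == 0) {
    stop("zero cell in denominator: odds ratio undefined ",
         "(set haldane = TRUE for a continuity-corrected estimate)")
  }
  (a * d) / (b * c)
}

#' Wald confidence interval for a 2x2 odds ratio
#'
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` with
#' `z = qnorm((1 + level)/2)`.
#'
#' @inheritParams or_2x2
#' @param level Confidence level. Default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @export
wald_ci <- function(a, b, c, d, level = 0.95) {
  check_counts(a, b, c, d)
  if (any(c(a, b, c, d) == 0))
    stop("all four counts must be positive for a Wald interval")
  stopifnot(level >= 0, level < 1)
  lor <- log(or_2x2(a, b, c, d))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm((1 + level) / 2)
  exp(lor + c(-1, 1) * z * se)
}

check_counts <- function(a, b, c, d) {
  v <- c(a, b, c, d)
  stopifnot(length(v) == 4L, is.numeric(v))
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers")
  invisible(v)
}

#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least
#' squares, with the coefficient covariance taken as the inverse observed
#' information.  Thin wrapper over the standard IRLS machinery of
#' [stats::glm.fit()] with a tight convergence tolerance, plus explicit
#' failure on singular designs and on complete or quasi-complete
#' separation (diverging coefficients), which would otherwise yield
#' meaningless Wald statistics.
#'
#' @param x Design matrix including an intercept column.
#' @param y Binary outcome vector (0/1 or logical), both classes present.
#' @param maxit Maximum IRLS iterations. Default 50.
#' @return A `prs_logit` object with components `coefficients`, `vcov`,
#'   `fitted`, `linear_predictors`, `loglik`, `converged`, `n_iter`, `n`;
#'   methods: `print`, `summary`, `coef`, `vcov`, `logLik`, `predict`.
#' @export
fit_logistic <- function(x, y, maxit = 50L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  stopifnot(all(y %in% c(0, 1)), nrow(x) == length(y))
  if (!any(y == 0) || !any(y == 1))
    stop("outcome must contain both classes")
  if (is.null(colnames(x)))
    colnames(x) <- c("(Intercept)", paste0("x", seq_len(ncol(x) - 1L)))
  if (qr(x)$rank < ncol(x)) stop("singular design matrix")

  fit <- suppressWarnings(
    stats::glm.fit(x, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = maxit)))
  beta <- fit$coefficients
  if (anyNA(beta)) stop("singular design matrix")
  eta <- drop(x %*% beta)
  p <- stats::plogis(eta)
  # separation: coefficients diverge while fitted values pin to 0/1
  if ((any(abs(beta[-1L]) > 12) || !fit$converged) &&
      any(p > 1 - 1e-8 | p < 1e-8))
    stop("complete or quasi-complete separation detected: ",
         "coefficients diverge")
  w <- p * (1 - p)
  info <- crossprod(x, x * w)
  vc <- tryCatch(solve(info), error = function(e)
    stop("observed information is singular at the optimum"))
  dimnames(vc) <- list(colnames(x), colnames(x))
  ll <- sum(y * log(p) + (1 - y) * log1p(-p))
  structure(list(coefficients = beta, vcov = vc, fitted = p,
                 linear_predictors = eta, loglik = ll,
                 converged = fit$converged, n_iter = fit$iter,
                 n = length(y)),
            class = "prs_logit")
}

#' @export
coef.prs_logit <- function(object, ...) object$coefficients

#' @export
vcov.prs_logit <- function(object, ...) object$vcov

#' @export
logLik.prs_logit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n, class = "logLik")
}

#' @export
predict.prs_logit <- function(object, newdata = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  eta <- if (is.null(newdata)) object$linear_predictors
         else drop(as.matrix(newdata) %*% object$coefficients)
  if (type == "response") stats::plogis(eta) else eta
}

#' @export
print.prs_logit <- function(x, ...) {
  cat("Logistic fit (IRLS): n =", x$n,
      "| log-likelihood =", format(x$loglik, digits = 6),
      "| iterations =", x$n_iter, "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.prs_logit <- function(object, level = 0.95, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  q <- stats::qnorm((1 + level) / 2)
  tab <- data.frame(estimate = object$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)),
                    or = exp(object$coefficients),
                    or_low = exp(object$coefficients - q * se),
                    or_high = exp(object$coefficients + q * se))
  structure(list(table = tab, loglik = object$loglik, n = object$n),
            class = "summary.prs_logit")
}

#' @export
print.summary.prs_logit <- function(x, ...) {
  cat("Logistic fit, n =", x$n, "\n")
  print(round(x$table, 4))
  invisible(x)
}
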