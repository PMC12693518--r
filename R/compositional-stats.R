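## Compositional statistics for replicate proportion tables: pseudocount
## closure, Dirichlet regression (common parametrization, log link) with
## global likelihood-ratio tests, per-component beta regression, and
## Benjamini-Hochberg FDR control across components.

#' Close a composition table onto the open simplex
#'
#' Replaces zeros by a small pseudocount and renormalizes each row to unit
#' sum, so every observation lies strictly inside the simplex (required by
#' the Dirichlet and beta likelihoods).
#'
#' @param x numeric matrix (samples x classes) or
#'   \code{\linkS4class{CompositionTable}}.
#' @param pseudocount value substituted for zeros (default \code{1e-6}).
#' @return object of the same type, rows summing to 1 and strictly positive.
#' @examples
#' closeComposition(rbind(c(0, 0.5, 0.5)))
#' @export
closeComposition <- function(x, pseudocount = 1e-6) {
  isTab <- is(x, "CompositionTable")
  m <- if (isTab) proportions(x) else as.matrix(x)
  if (any(m < 0)) stop("proportions must be nonnegative (input error)",
                       call. = FALSE)
  if (any(rowSums(m) == 0)) stop("all-zero row (input error)", call. = FALSE)
  m[m == 0] <- pseudocount
  m <- m / rowSums(m)
  if (isTab) { x@proportions <- m; x } else m
}

#' @keywords internal
.dirichletNegLL <- function(par, X, logY, D) {
  B <- matrix(par, ncol = D)
  alpha <- exp(X %*% B)
  if (any(!is.finite(alpha)) || any(alpha <= 0)) return(1e10)
  -sum(lgamma(rowSums(alpha)) - rowSums(lgamma(alpha)) +
         rowSums((alpha - 1) * logY))
}

#' @keywords internal
.dirichletNegGrad <- function(par, X, logY, D) {
  B <- matrix(par, ncol = D)
  alpha <- exp(X %*% B)
  if (any(!is.finite(alpha))) return(rep(0, length(par)))
  dA <- (digamma(rowSums(alpha)) - digamma(alpha)) + logY
  -as.vector(crossprod(X, alpha * dA))
}

#' Fit a Dirichlet regression
#'
#' Common (one-parameter-set) parametrization with log link: for sample i and
#' class d, the concentration is \eqn{\alpha_{id} = \exp(x_i \beta_d)}. The
#' log-likelihood is the Dirichlet density
#' \eqn{\ln\Gamma(\sum_d \alpha_d) - \sum_d \ln\Gamma(\alpha_d) +
#' \sum_d (\alpha_d - 1)\ln y_d}, maximized by BFGS with the analytic
#' (digamma) gradient from a moment-matched start. Expected compositions per
#' group are \eqn{\alpha / \sum \alpha}.
#'
#' @param table a closed \code{\linkS4class{CompositionTable}} (see
#'   \code{\link{closeComposition}}); at least 2 samples per group.
#' @param model \code{"group"} (group factor as predictor) or
#'   \code{"intercept"} (null model).
#' @param maxit maximum BFGS iterations (default 500).
#' @return object of class \code{"dirichletFit"}: coefficients (covariate x
#'   class matrix on the log-concentration scale), \code{logLik},
#'   \code{converged}, \code{fitted} (group-wise expected compositions),
#'   \code{alpha} (group-wise concentrations), \code{npar}, \code{D},
#'   \code{groupLevels}.
#' @examples
#' tab <- simulateReplicates(c(a = 0.2, b = 0.8), precision = 50, n = 6,
#'                           seed = 1)
#' fitDirichlet(tab, model = "intercept")
#' @export
fitDirichlet <- function(table, model = c("group", "intercept"), maxit = 500L) {
  model <- match.arg(model)
  stopifnot(is(table, "CompositionTable"))
  Y <- proportions(table)
  if (any(Y <= 0) || any(Y >= 1))
    stop("table must be closed onto the open simplex; run closeComposition()",
         call. = FALSE)
  g <- droplevels(sampleGroups(table))
  if (model == "group" && any(tabulate(g) < 2L))
    stop("each group needs at least 2 samples (degenerate group)",
         call. = FALSE)
  X <- if (model == "group") stats::model.matrix(~g)
       else stats::model.matrix(~1, data.frame(row = seq_len(nrow(Y))))
  D <- ncol(Y); p <- ncol(X)
  logY <- log(Y)

  ## moment-matched start: intercept at log of the common moment estimate
  mbar <- colMeans(Y)
  v <- apply(Y, 2, var)
  sOK <- v > 0 & mbar > 0 & mbar < 1
  s <- if (any(sOK)) exp(mean(log(pmax(mbar[sOK] * (1 - mbar[sOK]) / v[sOK] - 1,
                                       1e-2)))) else 10
  B0 <- matrix(0, nrow = p, ncol = D)
  B0[1, ] <- log(pmax(s * mbar, 1e-6))
  startLL <- -.dirichletNegLL(as.vector(B0), X, logY, D)

  opt <- optim(as.vector(B0), .dirichletNegLL, .dirichletNegGrad,
               X = X, logY = logY, D = D, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-12))
  B <- matrix(opt$par, ncol = D,
              dimnames = list(colnames(X), colnames(Y)))
  ll <- -opt$value
  if (ll < startLL - 1e-8) {  # never fall below the moment start
    B <- B0; dimnames(B) <- list(colnames(X), colnames(Y))
    ll <- startLL
  }
  Xg <- unique(X)
  alphaG <- exp(Xg %*% B)
  lev <- if (model == "group") levels(g) else "(all)"
  rownames(alphaG) <- lev[seq_len(nrow(alphaG))]
  structure(list(coefficients = B, logLik = ll,
                 converged = opt$convergence == 0L,
                 fitted = alphaG / rowSums(alphaG), alpha = alphaG,
                 npar = length(B), D = D, model = model,
                 groupLevels = lev, n = nrow(Y)),
            class = "dirichletFit")
}

#' @export
print.dirichletFit <- function(x, ...) {
  cat(sprintf("Dirichlet regression (%s model), n = %d, D = %d, logLik = %.3f%s\n",
              x$model, x$n, x$D, x$logLik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  cat("expected compositions:\n")
  print(round(x$fitted, 4))
  invisible(x)
}

#' Global likelihood-ratio test between nested Dirichlet fits
#'
#' Tests for a global difference in product composition between groups:
#' statistic \eqn{2(\ell_{full} - \ell_{null})}, with \eqn{D (G-1)} degrees
#' of freedom for D classes and G group levels, referred to the upper
#' chi-square tail.
#'
#' @param fitFull group-model \code{dirichletFit}.
#' @param fitNull nested intercept-only \code{dirichletFit} on the same data.
#' @param table the \code{\linkS4class{CompositionTable}} both models were
#'   fitted to; required for the bootstrap p-value only.
#' @param pvalue \code{"chisq"} (default: upper chi-square tail) or
#'   \code{"bootstrap"} (parametric bootstrap under the fitted null; the
#'   chi-square reference is anticonservative at the assay's typical 3-6
#'   replicates per group, see the package vignette).
#' @param nBoot bootstrap replicates (default 199).
#' @param seed optional seed for the bootstrap.
#' @return list of class \code{"berTest"}: \code{statistic}, \code{df},
#'   \code{p.value}, \code{method}.
#' @export
lrtGlobal <- function(fitFull, fitNull, table = NULL,
                      pvalue = c("chisq", "bootstrap"), nBoot = 199L,
                      seed = NULL) {
  pvalue <- match.arg(pvalue)
  stopifnot(inherits(fitFull, "dirichletFit"), inherits(fitNull, "dirichletFit"))
  if (fitFull$npar <= fitNull$npar)
    stop("fitNull must be nested in fitFull", call. = FALSE)
  stat <- 2 * (fitFull$logLik - fitNull$logLik)
  if (stat < -1e-6)
    stop("full-model likelihood below null-model likelihood: optimization ",
         "failure", call. = FALSE)
  stat <- max(stat, 0)
  df <- fitFull$npar - fitNull$npar
  if (pvalue == "chisq") {
    p <- pchisq(stat, df, lower.tail = FALSE)
    method <- "Dirichlet regression LRT (chi-square)"
  } else {
    if (is.null(table))
      stop("the bootstrap p-value needs the fitted CompositionTable",
           call. = FALSE)
    alpha0 <- exp(fitNull$coefficients[1, ])
    g <- sampleGroups(table)
    n <- nrow(proportions(table))
    doBoot <- function() {
      tstar <- numeric(nBoot)
      for (b in seq_len(nBoot)) {
        m <- t(vapply(seq_len(n), function(i) {
          gg <- rgamma(length(alpha0), shape = alpha0, rate = 1)
          gg / sum(gg)
        }, numeric(length(alpha0))))
        colnames(m) <- names(alpha0)
        tb <- closeComposition(CompositionTable(m, group = g))
        tstar[b] <- tryCatch(
          max(0, 2 * (fitDirichlet(tb, "group")$logLik -
                        fitDirichlet(tb, "intercept")$logLik)),
          error = function(e) NA_real_)
      }
      tstar[!is.na(tstar)]
    }
    tstar <- if (is.null(seed)) doBoot() else .withSeed(seed, doBoot())
    p <- (1 + sum(tstar >= stat)) / (length(tstar) + 1)
    method <- sprintf("Dirichlet regression LRT (parametric bootstrap, B=%d)",
                      length(tstar))
  }
  structure(list(statistic = stat, df = df, p.value = p, method = method),
            class = "berTest")
}

#' @export
print.berTest <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %d, p = %.4g\n", x$method,
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' @keywords internal
.betaNegLL <- function(par, X, y) {
  eta <- X %*% par[seq_len(ncol(X))]
  mu <- stats::plogis(eta)
  phi <- exp(par[length(par)])
  if (any(mu <= 0) || any(mu >= 1) || !is.finite(phi)) return(1e10)
  -sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
}

#' @keywords internal
.betaFit <- function(X, y, maxit = 500L) {
  mbar <- mean(y)
  phi0 <- max(mbar * (1 - mbar) / max(var(y), 1e-10) - 1, 1)
  start <- c(stats::qlogis(min(max(mbar, 1e-6), 1 - 1e-6)),
             rep(0, ncol(X) - 1L), log(phi0))
  opt <- optim(start, .betaNegLL, X = X, y = y, method = "BFGS",
               hessian = TRUE, control = list(maxit = maxit, reltol = 1e-12))
  list(par = opt$par, logLik = -opt$value, hessian = opt$hessian,
       converged = opt$convergence == 0L)
}

#' Per-component beta regression tests
#'
#' For each class d, fits a beta regression of the class proportion on the
#' group factor (logit mean link, constant precision phi, maximum
#' likelihood) and tests the group effect by likelihood ratio against the
#' intercept-only fit. P-values are adjusted across classes with the
#' Benjamini-Hochberg procedure.
#'
#' @param table a closed \code{\linkS4class{CompositionTable}}.
#' @return data.frame with one row per class: \code{class}, \code{estimate}
#'   and \code{se} (group coefficient on the logit scale; NA unless exactly 2
#'   group levels), \code{statistic}, \code{df}, \code{p}, \code{q}
#'   (BH-adjusted). A class whose values are numerically identical yields an
#'   NA row (degenerate fit) rather than an error.
#' @export
betaComponentTests <- function(table) {
  stopifnot(is(table, "CompositionTable"))
  Y <- proportions(table)
  if (any(Y <= 0) || any(Y >= 1))
    stop("table must be closed onto the open simplex; run closeComposition()",
         call. = FALSE)
  g <- droplevels(sampleGroups(table))
  G <- nlevels(g)
  X1 <- stats::model.matrix(~g)
  X0 <- X1[, 1, drop = FALSE]
  rows <- lapply(seq_len(ncol(Y)), function(d) {
    y <- Y[, d]
    base <- data.frame(class = colnames(Y)[d], estimate = NA_real_,
                       se = NA_real_, statistic = NA_real_,
                       df = G - 1L, p = NA_real_)
    if (stats::sd(y) < 1e-12) return(base)   # degenerate: no variation
    full <- .betaFit(X1, y)
    null <- .betaFit(X0, y)
    stat <- max(0, 2 * (full$logLik - null$logLik))
    base$statistic <- stat
    base$p <- pchisq(stat, G - 1L, lower.tail = FALSE)
    if (G == 2L) {
      base$estimate <- full$par[2]
      se <- tryCatch(sqrt(diag(solve(full$hessian))[2]),
                     error = function(e) NA_real_)
      base$se <- se
    }
    base
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  ok <- !is.na(out$p)
  out$q[ok] <- bhAdjust(out$p[ok])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} m p_{(j)} / j},
#' capped at 1 and order-preserving.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1] (input error)", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}
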