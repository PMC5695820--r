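#' Options for the null mixed-model fit
#'
#' @param factr L-BFGS-B tolerance passed to [stats::optim()]; convergence
#'   when the reduction in the REML deviance is below `factr * .Machine$double.eps`.
#' @param maxit Maximum optimizer iterations.
#' @param lower_frac,upper_frac Bounds on each variance component as a
#'   fraction/multiple of the total phenotypic variance.
#' @param compute_se Whether to compute asymptotic standard errors of the
#'   variance components from the numerically differentiated REML Hessian.
#' @return List of options.
#' @export
null_model_options <- function(factr = 1e7, maxit = 200,
                               lower_frac = 1e-8, upper_frac = 1e3,
                               compute_se = TRUE) {
  list(factr = factr, maxit = maxit, lower_frac = lower_frac,
       upper_frac = upper_frac, compute_se = compute_se)
}

## indicator-based covariance structure for a grouping factor: 1 within
## cluster (incl. diagonal), 0 elsewhere
.cluster_structure <- function(ids) {
  f <- factor(ids)
  Z <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                            dims = c(length(f), nlevels(f)))
  methods::as(Matrix::forceSymmetric(Matrix::tcrossprod(Z)), "CsparseMatrix")
}

.as_dsc <- function(m) {
  methods::as(Matrix::forceSymmetric(Matrix::Matrix(m, sparse = TRUE)),
              "CsparseMatrix")
}

## REML criterion pieces for V = sum_i theta_i * structs_i; fresh sparse
## Cholesky each evaluation (sizes here are modest and the pattern can
## change with cancellation)
.reml_pieces <- function(theta, structs, y, X, cache = NULL) {
  if (!is.null(cache)) {
    ## one-time: align every structure's entries on the union sparsity
    ## pattern, so each evaluation is a numeric combination
    if (is.null(cache$U)) {
      U <- structs[[1]]
      for (i in seq_along(structs)[-1]) U <- U + structs[[i]]
      U <- .as_dsc(U)
      Ut <- methods::as(U, "TsparseMatrix")
      ukey <- paste(Ut@i, Ut@j)
      cache$xs <- vapply(structs, function(S) {
        St <- methods::as(.as_dsc(S), "TsparseMatrix")
        v <- numeric(length(ukey))
        v[match(paste(St@i, St@j), ukey)] <- St@x
        v
      }, numeric(length(ukey)))
      cache$U <- U
    }
    V <- cache$U
    V@x <- as.numeric(cache$xs %*% theta)
  } else {
    V <- structs[[1]] * theta[1]
    for (i in seq_along(structs)[-1]) V <- V + structs[[i]] * theta[i]
    V <- .as_dsc(V)
  }
  ## reuse the symbolic factorization across evaluations; the pattern is
  ## fixed because all components stay strictly positive
  ch <- NULL
  if (!is.null(cache) && !is.null(cache$ch0))
    ch <- tryCatch(Matrix::update(cache$ch0, V), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- Matrix::Cholesky(V, LDL = FALSE)
    if (!is.null(cache)) cache$ch0 <- ch
  }
  ViX <- as.matrix(Matrix::solve(ch, X))
  Viy <- as.numeric(Matrix::solve(ch, y))
  XtViX <- crossprod(X, ViX)
  XtViy <- crossprod(X, Viy)
  R <- chol(XtViX)
  beta <- backsolve(R, backsolve(R, XtViy, transpose = TRUE))
  quad <- sum(y * Viy) - sum(XtViy * beta)
  logdetV <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  logdetX <- 2 * sum(log(diag(R)))
  n <- length(y); p <- ncol(X)
  loglik <- -0.5 * (logdetV + logdetX + quad + (n - p) * log(2 * pi))
  list(loglik = loglik, ch = ch, ViX = ViX, Viy = Viy, XtViX = XtViX,
       R = R, beta = as.numeric(beta))
}

#' Fit the null linear mixed model by REML
#'
#' Fits `y = X b + g_kin + g_house + g_block + e` where the random effects
#' have covariances `sigma2_kin * K`, `sigma2_household * H`,
#' `sigma2_block * B` and `sigma2_resid * I`; `K` is the supplied kinship
#' (correlation) matrix and `H`, `B` are within-cluster indicator
#' structures. Variance components are estimated by restricted maximum
#' likelihood with a bounded quasi-Newton optimizer on the log-variance
#' scale, from a deterministic start (equal split of the residual
#' phenotypic variance), so the fit is reproducible given its inputs.
#' The fitted inverse-covariance factor is retained so that many
#' fixed-effect tests (local ancestry intervals, variant dosages) can reuse
#' one null fit, the usual practice in mixed-model genome scans.
#'
#' @param y Numeric outcome vector.
#' @param X Fixed-effect design matrix (including intercept). A data frame
#'   is converted with [stats::model.matrix()].
#' @param kinship Symmetric PSD kinship/correlation matrix (dense or
#'   sparse), or `NULL` to omit the component.
#' @param household,block Cluster identifier vectors, or `NULL`.
#' @param options See [null_model_options()].
#' @return An object of class `null_model_fit` with elements `theta`
#'   (named variance components), `theta_se`, `beta` (fixed-effect table),
#'   `loglik` (REML), `converged`, `counts`, and the factorization pieces
#'   reused by [test_fixed_effect()].
#' @seealso [test_fixed_effect()], [scan_ancestry()]
#' @export
fit_null_model <- function(y, X, kinship = NULL, household = NULL,
                           block = NULL, options = null_model_options()) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.data.frame(X)) X <- stats::model.matrix(~ ., data = X)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("y and X have different numbers of rows")
  if (n <= ncol(X)) stop("need more observations than fixed effects")
  if (anyNA(y) || anyNA(X)) stop("y and X must be complete")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is singular")

  structs <- list()
  if (!is.null(kinship)) {
    kinship <- .as_dsc(kinship)
    if (nrow(kinship) != n) stop("kinship dimension does not match y")
    structs$kinship <- kinship
  }
  if (!is.null(household)) {
    if (length(household) != n || anyNA(household))
      stop("household ids must be complete and match y")
    structs$household <- .cluster_structure(household)
  }
  if (!is.null(block)) {
    if (length(block) != n || anyNA(block))
      stop("block ids must be complete and match y")
    structs$block <- .cluster_structure(block)
  }
  structs$resid <- Matrix::Diagonal(n)
  .fit_core(y, X, structs, options)
}

## REML optimization given assembled covariance structures
.fit_core <- function(y, X, structs, options) {
  n <- length(y)
  ncomp <- length(structs)
  vartot <- stats::var(stats::lm.fit(X, y)$residuals)
  lb <- log(options$lower_frac * vartot)
  ub <- log(options$upper_frac * vartot)
  par0 <- rep(log(vartot / ncomp), ncomp)

  cache <- new.env(parent = emptyenv())
  nll <- function(lt) -.reml_pieces(exp(lt), structs, y, X, cache)$loglik
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(factr = options$factr,
                                     maxit = options$maxit))
  theta <- exp(opt$par)
  names(theta) <- names(structs)

  pieces <- .reml_pieces(theta, structs, y, X, cache)
  XtViX_inv <- chol2inv(pieces$R)
  Py <- pieces$Viy - pieces$ViX %*% pieces$beta
  se_beta <- sqrt(diag(XtViX_inv))
  beta_tab <- data.frame(term = colnames(X) %||% paste0("b", seq_len(ncol(X))),
                         effect = pieces$beta, se = se_beta,
                         stringsAsFactors = FALSE)

  theta_se <- rep(NA_real_, ncomp)
  if (isTRUE(options$compute_se)) {
    h <- tryCatch({
      nll_theta <- function(th) -.reml_pieces(th, structs, y, X, cache)$loglik
      H <- stats::optimHess(theta, nll_theta)
      sqrt(diag(solve(H)))
    }, error = function(e) rep(NA_real_, ncomp))
    theta_se <- h
  }
  names(theta_se) <- names(structs)

  structure(list(theta = theta, theta_se = theta_se, beta = beta_tab,
                 loglik = pieces$loglik, converged = opt$convergence == 0,
                 counts = opt$counts, message = opt$message,
                 ch = pieces$ch, ViX = pieces$ViX,
                 XtViX_inv = XtViX_inv, Py = as.numeric(Py),
                 y = y, X = X, structs = structs, n = n, p = ncol(X),
                 options = options),
            class = "null_model_fit")
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("Null mixed model (REML): n =", x$n, ", loglik =",
      format(x$loglik, digits = 8), "\n")
  cat("Variance components:\n")
  print(round(rbind(estimate = x$theta, se = x$theta_se), 4))
  invisible(x)
}

#' @export
logLik.null_model_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta) + object$p,
            class = "logLik")
}

#' Recompute the REML log-likelihood of a fitted null model
#'
#' Rebuilds the trait covariance from the stored structures at the given
#' variance components and re-evaluates the REML criterion from scratch;
#' at `fit$theta` this reproduces `fit$loglik`.
#'
#' @param fit A `null_model_fit`.
#' @param theta Variance components (defaults to the fitted values).
#' @return The REML log-likelihood.
#' @export
reml_loglik <- function(fit, theta = fit$theta) {
  .reml_pieces(theta, fit$structs, fit$y, fit$X)$loglik
}

#' Extend the fixed-effect design of a fitted null model
#'
#' Adds covariate columns (e.g. lead-variant dosages for a conditional
#' scan) while holding the variance components at the null fit. Columns
#' collinear with the existing design are dropped with a warning.
#'
#' @param fit A `null_model_fit`.
#' @param extra Matrix (or vector) of additional covariates.
#' @param names Column names for `extra`.
#' @return A new `null_model_fit` with the extended design; dropped column
#'   names are recorded in attribute `"dropped"`.
#' @export
update_fixed_effects <- function(fit, extra, names = NULL) {
  extra <- as.matrix(extra)
  if (nrow(extra) != fit$n) stop("extra covariates do not match n")
  if (!is.null(names)) colnames(extra) <- names
  if (is.null(colnames(extra)))
    colnames(extra) <- paste0("cov", seq_len(ncol(extra)))
  keep <- logical(ncol(extra))
  Xc <- fit$X
  for (j in seq_len(ncol(extra))) {
    cand <- cbind(Xc, extra[, j])
    if (qr(cand)$rank == ncol(cand)) {
      Xc <- cand
      colnames(Xc)[ncol(Xc)] <- colnames(extra)[j]
      keep[j] <- TRUE
    }
  }
  if (any(!keep))
    warning("dropped collinear covariate(s): ",
            paste(colnames(extra)[!keep], collapse = ", "))
  pieces <- .reml_pieces(fit$theta, fit$structs, fit$y, Xc)
  XtViX_inv <- chol2inv(pieces$R)
  Py <- pieces$Viy - pieces$ViX %*% pieces$beta
  out <- fit
  out$X <- Xc
  out$p <- ncol(Xc)
  out$beta <- data.frame(term = colnames(Xc), effect = pieces$beta,
                         se = sqrt(diag(XtViX_inv)),
                         stringsAsFactors = FALSE)
  out$loglik <- pieces$loglik
  out$ch <- pieces$ch
  out$ViX <- pieces$ViX
  out$XtViX_inv <- XtViX_inv
  out$Py <- as.numeric(Py)
  attr(out, "dropped") <- colnames(extra)[!keep]
  out
}

#' Wald test of focal fixed effects added to a fitted null model
#'
#' Tests one or two focal predictor columns (a local ancestry count, a
#' variant dosage, or a pair of ancestry counts for the joint test) added
#' to the null design, with variance components held at the null REML
#' estimates. The statistic is the Wald quadratic form, referred to a
#' chi-square distribution with as many degrees of freedom as focal
#' columns.
#'
#' @param null A `null_model_fit`.
#' @param focal Numeric vector or matrix (one or two columns) aligned with
#'   the fitted individuals.
#' @param names Optional focal column names (used in error messages).
#' @param refit Re-estimate the variance components with the focal
#'   predictor(s) in the fixed-effect design before testing (per-marker
#'   refit), instead of the default reuse of the null estimates.
#' @return An object of class `fixed_effect_test`: list with `coefficients`
#'   (term, effect, se), `stat`, `df` and `p`.
#' @export
test_fixed_effect <- function(null, focal, names = NULL, refit = FALSE) {
  stopifnot(inherits(null, "null_model_fit"))
  G <- as.matrix(focal)
  if (nrow(G) != null$n) stop("focal predictor does not match fitted n")
  if (anyNA(G)) stop("focal predictor contains missing values")
  if (!is.null(names)) colnames(G) <- names
  if (is.null(colnames(G))) colnames(G) <- paste0("focal", seq_len(ncol(G)))
  if (isTRUE(refit)) {
    if (qr(cbind(null$X, G))$rank < ncol(null$X) + ncol(G))
      stop("focal column(s) collinear with the null design: ",
           paste(colnames(G), collapse = ", "))
    opts <- null$options
    opts$compute_se <- FALSE
    null <- .fit_core(null$y, cbind(null$X, G), null$structs, opts)
    idx <- seq(null$p - ncol(G) + 1L, null$p)
    covb <- null$XtViX_inv[idx, idx, drop = FALSE]
    beta <- null$beta$effect[idx]
    stat <- as.numeric(crossprod(beta, solve(covb, beta)))
    return(structure(list(
      coefficients = data.frame(term = colnames(G), effect = beta,
                                se = sqrt(diag(covb)),
                                stringsAsFactors = FALSE),
      stat = stat, df = ncol(G),
      p = stats::pchisq(stat, df = ncol(G), lower.tail = FALSE)),
      class = "fixed_effect_test"))
  }

  ViG <- as.matrix(Matrix::solve(null$ch, G))
  A <- crossprod(G, ViG)
  B <- crossprod(G, null$ViX)
  S <- A - B %*% null$XtViX_inv %*% t(B)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(abs(ev)) * 1e-10) {
    bad <- colnames(G)[qr(cbind(null$X, G))$rank - ncol(null$X) <
                         seq_len(ncol(G))]
    if (!length(bad)) bad <- colnames(G)
    stop("focal column(s) collinear with the null design: ",
         paste(bad, collapse = ", "))
  }
  u <- crossprod(G, null$Py)
  beta <- solve(S, u)
  covb <- solve(S)
  stat <- as.numeric(crossprod(u, beta))
  df <- ncol(G)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(
    coefficients = data.frame(term = colnames(G),
                              effect = as.numeric(beta),
                              se = sqrt(diag(covb)),
                              stringsAsFactors = FALSE),
    stat = stat, df = df, p = p),
    class = "fixed_effect_test")
}

#' @export
print.fixed_effect_test <- function(x, ...) {
  print(x$coefficients)
  cat(sprintf("Wald chi-square = %.4g on %d df, p = %.3g\n",
              x$stat, x$df, x$p))
  invisible(x)
}
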