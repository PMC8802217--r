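#' @title Recursive path analysis by maximum likelihood
#'
#' @description
#' Standardized recursive (acyclic) path models over observed variables, fit
#' by iterative maximum likelihood: the free parameters (path coefficients,
#' endogenous residual variances, exogenous variances and covariances) are
#' chosen to minimize the ML discrepancy between the sample covariance matrix
#' and the model-implied matrix `Sigma = (I-A)^-1 Psi (I-A)^-T`. Fit is
#' summarized by the chi-square statistic `(n-1) F_ML` against the saturated
#' model, RMSEA, and CFI against the independence baseline. For recursive
#' models the ML estimates coincide with per-equation least squares, which is
#' retained as an internal cross-check. Non-significant paths can be pruned
#' one at a time (least significant first) and the model refit.
#'
#' @name burstloco-path
NULL

#' Standardize a table of variables to z-scores
#'
#' Columns are centred and scaled to unit sd (denominator n - 1). Affine
#' transformations of a column leave its z-scores unchanged.
#'
#' @param data data frame of numeric columns.
#' @return Data frame of z-scores.
#' @export
standardize <- function(data) {
  if (any(vapply(data, stats::sd, 0) == 0)) {
    stop("degenerate-variance error: constant column")
  }
  as.data.frame(lapply(data, function(x) as.numeric(scale(x))))
}

#' Specify a recursive path model
#'
#' Directed edges may be given as a data frame with columns `from`, `to` or as
#' character strings `"from -> to"`. All variables without incoming edges are
#' exogenous; their pairwise covariances are free (double-headed) parameters.
#'
#' @param edges edge list (see above).
#' @param vars optional character vector of variable names (defaults to the
#'   union of edge endpoints); extra names enter as isolated exogenous
#'   variables.
#' @return A `path_spec`: list with `vars`, `edges` (data frame), `endogenous`,
#'   `exogenous`.
#' @export
path_spec <- function(edges, vars = NULL) {
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L)) stop("format error: edges must read 'from -> to'")
    edges <- data.frame(from = trimws(vapply(parts, `[`, "", 1)),
                        to = trimws(vapply(parts, `[`, "", 2)))
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  vars <- union(vars, unique(c(edges$from, edges$to)))
  # acyclicity by repeated removal of sink-free variables (topological sort)
  rem <- edges
  left <- vars
  repeat {
    src <- setdiff(left, rem$to)
    if (!length(src)) break
    left <- setdiff(left, src)
    rem <- rem[!(rem$from %in% src), , drop = FALSE]
    if (!nrow(rem)) break
  }
  if (nrow(rem)) stop("validation error: path model must be recursive (acyclic)")
  endo <- unique(edges$to)
  structure(list(vars = vars, edges = edges, endogenous = endo,
                 exogenous = setdiff(vars, endo)),
            class = "path_spec")
}

# parameter bookkeeping: betas (one per edge), log residual variances
# (endogenous), log variances (exogenous), covariances (exogenous pairs)
.path_parlist <- function(spec) {
  exo <- spec$exogenous
  exo_pairs <- if (length(exo) > 1L) utils::combn(exo, 2) else
    matrix(character(0), nrow = 2)
  list(n_beta = nrow(spec$edges), endo = spec$endogenous, exo = exo,
       pairs = exo_pairs,
       n_free = nrow(spec$edges) + length(spec$endogenous) + length(exo) +
         ncol(exo_pairs))
}

.path_sigma <- function(theta, spec, pl) {
  p <- length(spec$vars)
  A <- matrix(0, p, p, dimnames = list(spec$vars, spec$vars))
  nb <- pl$n_beta
  if (nb) A[cbind(spec$edges$to, spec$edges$from)] <- theta[seq_len(nb)]
  Psi <- matrix(0, p, p, dimnames = list(spec$vars, spec$vars))
  i <- nb
  for (v in pl$endo) { i <- i + 1L; Psi[v, v] <- exp(theta[i]) }
  for (v in pl$exo) { i <- i + 1L; Psi[v, v] <- exp(theta[i]) }
  if (ncol(pl$pairs)) for (k in seq_len(ncol(pl$pairs))) {
    i <- i + 1L
    Psi[pl$pairs[1, k], pl$pairs[2, k]] <- theta[i]
    Psi[pl$pairs[2, k], pl$pairs[1, k]] <- theta[i]
  }
  B <- solve(diag(p) - A)
  B %*% Psi %*% t(B)
}

.fml <- function(sigma, S) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ld <- 2 * sum(log(diag(ch)))
  ld + sum(diag(S %*% chol2inv(ch))) - determinant(S)$modulus[1] - nrow(S)
}

# per-equation least squares on the same data: the recursive-model ML solution
.path_ols <- function(spec, data) {
  out <- list()
  for (v in spec$endogenous) {
    pars <- spec$edges$from[spec$edges$to == v]
    f <- stats::as.formula(paste(v, "~", paste(pars, collapse = "+")))
    m <- stats::lm(f, data = data)
    out[[v]] <- list(beta = stats::coef(m)[pars],
                     psi = sum(stats::resid(m)^2) / nrow(data))
  }
  out
}

#' Fit a recursive path model by maximum likelihood
#'
#' @param spec a [path_spec()].
#' @param data data frame containing all model variables, conventionally
#'   z-scored (see [standardize()]) so coefficients are standardized
#'   beta-weights.
#' @return A `path_fit`: list with `edges` (data frame: `from, to, beta, se,
#'   z, p`), `r2` (per endogenous variable), `chisq`, `df`, `p_chisq`,
#'   `rmsea`, `cfi`, `implied` (model-implied correlation matrix), `fml`,
#'   `n`, `ols` (per-equation least-squares cross-check), `converged`.
#' @export
fit_path <- function(spec, data) {
  stopifnot(inherits(spec, "path_spec"))
  miss <- setdiff(spec$vars, names(data))
  if (length(miss)) stop(sprintf("format error: data lacks variable(s): %s",
                                 paste(miss, collapse = ", ")))
  d <- data[spec$vars]
  n <- nrow(d)
  pl <- .path_parlist(spec)
  if (n <= pl$n_free) stop("validation error: n must exceed the number of free parameters")
  S <- stats::cov(d)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12) stop("data error: sample covariance matrix is not positive definite")

  theta0 <- c(rep(0, pl$n_beta), rep(0, length(pl$endo) + length(pl$exo)),
              rep(0, ncol(pl$pairs)))
  obj <- function(th) .fml(.path_sigma(th, spec, pl), S)
  ctrl <- list(maxit = 2000, reltol = 1e-15,
               ndeps = rep(1e-7, length(theta0)))
  opt <- stats::optim(theta0, obj, method = "BFGS", control = ctrl)
  # restart to polish (resets the Hessian approximation)
  opt <- stats::optim(opt$par, obj, method = "BFGS", hessian = TRUE,
                      control = ctrl)
  if (opt$convergence != 0) {
    eps <- 1e-6
    g <- max(abs(vapply(seq_along(opt$par), function(i) {
      th <- opt$par; th[i] <- th[i] + eps
      (obj(th) - opt$value) / eps
    }, 0)))
    stop(sprintf("non-convergence: optimizer code %d (last gradient norm %.3g)",
                 opt$convergence, g))
  }
  theta <- opt$par
  sigma <- .path_sigma(theta, spec, pl)
  fml <- .fml(sigma, S)

  # asymptotic covariance of the estimates from the observed information
  vcov_th <- tryCatch(2 / (n - 1) * solve(opt$hessian), error = function(e) NULL)
  se <- if (is.null(vcov_th)) rep(NA_real_, pl$n_beta) else
    sqrt(pmax(diag(vcov_th)[seq_len(pl$n_beta)], 0))

  beta <- theta[seq_len(pl$n_beta)]
  zstat <- beta / se
  edges <- data.frame(spec$edges, beta = beta, se = se, z = zstat,
                      p = 2 * stats::pnorm(-abs(zstat)))

  pvars <- length(spec$vars)
  df <- pvars * (pvars + 1) / 2 - pl$n_free
  chisq <- max((n - 1) * fml, 0)
  # independence baseline for CFI
  chisq_b <- (n - 1) * .fml(diag(diag(S)), S)
  df_b <- pvars * (pvars + 1) / 2 - pvars
  num <- max(chisq - df, 0)
  den <- max(chisq_b - df_b, chisq - df, 0)
  cfi <- if (den <= 0) 1 else 1 - num / den
  rmsea <- if (df <= 0) 0 else sqrt(max(chisq - df, 0) / (df * (n - 1)))

  r2 <- vapply(spec$endogenous, function(v) {
    i <- pl$n_beta + match(v, pl$endo)
    1 - exp(theta[i]) / sigma[v, v]
  }, 0)

  structure(list(edges = edges, r2 = r2, chisq = chisq, df = df,
                 p_chisq = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
                 rmsea = rmsea, cfi = min(max(cfi, 0), 1),
                 implied = stats::cov2cor(sigma), fml = fml, n = n,
                 ols = .path_ols(spec, d), spec = spec,
                 converged = TRUE),
            class = "path_fit")
}

#' @exportS3Method base::print
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> chi2(%d) = %.3f, p = %s, RMSEA = %.3f, CFI = %.3f\n",
              x$df, x$chisq,
              if (is.na(x$p_chisq)) "-" else sprintf("%.3f", x$p_chisq),
              x$rmsea, x$cfi))
  print(x$edges, digits = 3)
  cat("R2:", paste(sprintf("%s = %.2f", names(x$r2), x$r2), collapse = ", "), "\n")
  invisible(x)
}

#' Standardized total effect along all directed paths
#'
#' Sum over every directed path from `from` to `to` of the product of its
#' path coefficients (direct + indirect effects).
#'
#' @param fit a [fit_path()] result.
#' @param from,to variable names.
#' @return Numeric total effect.
#' @export
total_effect <- function(fit, from, to) {
  stopifnot(inherits(fit, "path_fit"))
  e <- fit$edges
  walk <- function(v) {
    if (v == to) return(1)
    out <- e[e$from == v, , drop = FALSE]
    if (!nrow(out)) return(0)
    sum(out$beta * vapply(out$to, walk, 0))
  }
  walk(from) - as.numeric(from == to)
}

#' Prune non-significant paths and refit
#'
#' Iteratively removes the least-significant directed edge with p > alpha and
#' refits, until every retained edge is significant. If removals leave an
#' endogenous variable with no incoming paths, a warning is raised and the
#' variable is dropped from the model.
#'
#' @param spec a [path_spec()].
#' @param data the (z-scored) data.
#' @param alpha significance threshold.
#' @return List with `spec` (pruned), `fit` (refit on the pruned spec), and
#'   `removed` (data frame logging the removal order: `from, to, p`).
#' @export
prune <- function(spec, data, alpha = 0.05) {
  removed <- data.frame(from = character(0), to = character(0), p = numeric(0))
  repeat {
    fit <- fit_path(spec, data)
    worst <- which.max(fit$edges$p)
    if (!length(worst) || fit$edges$p[worst] <= alpha) break
    removed <- rbind(removed, fit$edges[worst, c("from", "to", "p")])
    edges <- spec$edges[-worst, , drop = FALSE]
    orphan <- setdiff(spec$endogenous, edges$to)
    vars <- spec$vars
    if (length(orphan)) {
      warning(sprintf("variable(s) dropped from model (no remaining incoming paths): %s",
                      paste(orphan, collapse = ", ")))
      vars <- setdiff(vars, orphan)
      edges <- edges[!(edges$from %in% orphan) & !(edges$to %in% orphan), , drop = FALSE]
    }
    if (!nrow(edges)) {
      spec <- path_spec(edges = data.frame(from = character(0), to = character(0)),
                        vars = vars)
      fit <- NULL
      break
    }
    spec <- path_spec(edges, vars = vars)
  }
  list(spec = spec, fit = fit, removed = removed)
}
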