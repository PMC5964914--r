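#' Random term for a mixed model
#'
#' One random term `Z u`, `u ~ N(0, K sigma2)`. Supply either a dense
#' covariance `K` (a [relmatrix()] or matrix; inverted internally after a
#' diagonal ridge), a precomputed sparse precision `Kinv` (e.g. from
#' [nrm_inverse()]), or neither for i.i.d. effects (`K = I`).
#'
#' @param label term name (unique within a model).
#' @param Z design matrix (n x q), dense or sparse.
#' @param K covariance matrix (q x q) or `NULL`.
#' @param Kinv precision matrix (q x q, sparse) or `NULL`.
#' @param ridge diagonal ridge added to `K` before inversion.
#' @return object of class `mm_random`.
#' @export
mm_random <- function(label, Z, K = NULL, Kinv = NULL, ridge = 1e-6) {
  Z <- methods::as(methods::as(Matrix::Matrix(Z), "generalMatrix"), "CsparseMatrix")
  q <- ncol(Z)
  if (!is.null(K) && !is.null(Kinv)) stop("supply K or Kinv, not both")
  if (!is.null(K)) {
    Kv <- add_ridge(K, ridge)
    if (nrow(Kv) != q) stop("K dimension does not match Z columns for term ", label)
    ch <- tryCatch(chol(Kv), error = function(e) {
      stop("covariance for term ", label, " is not positive definite: ",
           conditionMessage(e))
    })
    Kinv <- Matrix::Matrix(chol2inv(ch), sparse = FALSE)
    logdetK <- 2 * sum(log(diag(ch)))
  } else if (!is.null(Kinv)) {
    if (nrow(Kinv) != q) stop("Kinv dimension does not match Z columns for term ", label)
    Kinv <- Matrix::forceSymmetric(Matrix::Matrix(Kinv, sparse = TRUE))
    logdetK <- -as.numeric(Matrix::determinant(Kinv, logarithm = TRUE)$modulus)
  } else {
    Kinv <- Matrix::Diagonal(q)
    logdetK <- 0
  }
  structure(list(label = label, Z = Z, Kinv = Kinv, logdetK = logdetK, q = q),
            class = "mm_random")
}

#' Mixed-model specification
#'
#' Linear mixed model on the observed scale:
#' `y = X b + sum_k Z_k u_k + e`, with `u_k ~ N(0, K_k sigma2_k)` and
#' `e ~ N(0, I sigma2_e)`. Binary traits are modelled on the observed 0/1
#' scale throughout the package.
#'
#' @param y numeric response (no missing values).
#' @param X fixed-effect design matrix; default intercept-only.
#' @param random list of [mm_random()] terms (possibly empty).
#' @return object of class `mm_spec`.
#' @export
mm_spec <- function(y, X = NULL, random = list()) {
  y <- as.numeric(y)
  n <- length(y)
  if (anyNA(y)) stop("response contains missing values")
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (nrow(X) != n) stop("X row count does not match y")
  if (inherits(random, "mm_random")) random <- list(random)
  labs <- vapply(random, function(r) r$label, "")
  if (anyDuplicated(labs)) stop("duplicate random term labels")
  for (r in random) {
    if (nrow(r$Z) != n) stop("Z row count for term ", r$label, " does not match y")
  }
  if (n < ncol(X) + 2) stop("need n >= number of fixed effects + 2")
  structure(list(y = y, X = X, random = random, n = n, p = ncol(X)),
            class = "mm_spec")
}

# Upper-storage symmetric CsparseMatrix, for pattern-stable assembly.
as_dsc_upper <- function(M) {
  M <- Matrix::forceSymmetric(methods::as(Matrix::Matrix(M, sparse = TRUE),
                                          "CsparseMatrix"), uplo = "U")
  methods::as(M, "CsparseMatrix")
}

# Entry keys (row + q * column) of a column-compressed sparse matrix.
dsc_keys <- function(M) {
  cols <- rep(seq_len(ncol(M)), diff(M@p))
  M@i + as.numeric(ncol(M)) * (cols - 1)
}

# Precompute cross-products and the sparse assembly template shared across
# likelihood evaluations: Cuu(gamma) = Z'Z + blockdiag(Kinv_k / gamma_k) is
# rebuilt per evaluation by filling the numeric slot of a fixed pattern.
mm_workspace <- function(spec) {
  Zs <- lapply(spec$random, function(r) r$Z)
  Z <- if (length(Zs)) do.call(cbind, Zs) else NULL
  X <- spec$X; y <- spec$y
  ws <- list(
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
    qk = vapply(spec$random, function(r) r$q, 0L),
    logdetK = vapply(spec$random, function(r) r$logdetK, 0))
  if (!is.null(Z)) {
    ws$ZtZ <- as_dsc_upper(Matrix::crossprod(Z))
    ws$ZtX <- Matrix::crossprod(Z, X)
    ws$Zty <- Matrix::crossprod(Z, y)
    ws$Z <- Z
    offs <- c(0L, cumsum(ws$qk))
    q <- sum(ws$qk)
    ws$Bk <- lapply(seq_along(spec$random), function(k) {
      Kinv <- as_dsc_upper(spec$random[[k]]$Kinv)
      cols <- rep(seq_len(ncol(Kinv)), diff(Kinv@p))
      Matrix::sparseMatrix(i = Kinv@i + 1L + offs[k], j = cols + offs[k],
                           x = Kinv@x, dims = c(q, q), symmetric = TRUE)
    })
    ws$Bk <- lapply(ws$Bk, as_dsc_upper)
    tmpl <- ws$ZtZ
    for (B in ws$Bk) tmpl <- tmpl + B
    tmpl <- as_dsc_upper(tmpl)
    tmpl@x[] <- 0
    keys <- dsc_keys(tmpl)
    ws$tmpl <- tmpl
    ws$idx_Z <- match(dsc_keys(ws$ZtZ), keys)
    ws$idx_B <- lapply(ws$Bk, function(B) match(dsc_keys(B), keys))
  }
  ws
}

# Assemble Cuu(gamma) from the workspace template.
mm_cuu <- function(ws, gamma) {
  x <- numeric(length(ws$tmpl@x))
  zz <- ws$ZtZ@x
  x[ws$idx_Z] <- zz
  for (k in seq_along(ws$Bk)) {
    x[ws$idx_B[[k]]] <- x[ws$idx_B[[k]]] + ws$Bk[[k]]@x / gamma[k]
  }
  Cuu <- ws$tmpl
  Cuu@x <- x
  Cuu
}

# Core likelihood/solution engine at variance ratios gamma = sigma2_k/sigma2_e.
# Returns profiled ML and REML -2 log-likelihoods and the MME solutions.
mm_eval <- function(spec, gamma, ws, env = NULL, want_solutions = FALSE) {
  n <- spec$n; p <- spec$p
  if (!length(spec$random)) {
    XtXi <- tryCatch(solve(ws$XtX), error = function(e)
      stop("singular fixed-effect design: columns ",
           paste(colnames(spec$X), collapse = ", ")))
    b <- XtXi %*% ws$Xty
    r2 <- ws$yty - sum(b * ws$Xty)
    s2_ml <- r2 / n; s2_reml <- r2 / (n - p)
    out <- list(
      m2ll_ml = n * log(2 * pi) + n * log(s2_ml) + n,
      m2ll_reml = (n - p) * (log(2 * pi) + log(s2_reml) + 1) +
        as.numeric(Matrix::determinant(ws$XtX, logarithm = TRUE)$modulus),
      r2 = r2, b = as.numeric(b), u = list())
    return(out)
  }
  Cuu <- mm_cuu(ws, gamma)
  ch <- NULL
  if (!is.null(env)) {
    if (is.null(env$sym_chol)) {
      env$sym_chol <- Matrix::Cholesky(Cuu, LDL = TRUE)
      ch <- env$sym_chol
    } else {
      ch <- tryCatch(Matrix::update(env$sym_chol, Cuu),
                     error = function(e) Matrix::Cholesky(Cuu, LDL = TRUE))
    }
  } else {
    ch <- Matrix::Cholesky(Cuu, LDL = TRUE)
  }
  logdetCuu <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
  u0 <- Matrix::solve(ch, ws$Zty, system = "A")
  CZX <- Matrix::solve(ch, ws$ZtX, system = "A")
  S <- as.matrix(ws$XtX - Matrix::crossprod(ws$ZtX, CZX))
  Sc <- tryCatch(chol(S), error = function(e)
    stop("singular coefficient matrix; confounded fixed columns among: ",
         paste(colnames(spec$X), collapse = ", ")))
  b <- backsolve(Sc, forwardsolve(t(Sc), as.numeric(ws$Xty - Matrix::crossprod(ws$ZtX, u0))))
  u <- as.numeric(u0 - CZX %*% b)
  r2 <- ws$yty - sum(b * ws$Xty) - sum(u * ws$Zty)
  r2 <- max(r2, 1e-12)
  logdetH <- sum(ws$qk * log(gamma) + ws$logdetK) + logdetCuu
  logdetS <- 2 * sum(log(diag(Sc)))
  s2_ml <- r2 / n; s2_reml <- r2 / (n - p)
  out <- list(
    m2ll_ml = n * (log(2 * pi) + log(s2_ml) + 1) + logdetH,
    m2ll_reml = (n - p) * (log(2 * pi) + log(s2_reml) + 1) + logdetH + logdetS,
    r2 = r2, b = as.numeric(b))
  if (want_solutions) {
    split_idx <- rep(seq_along(ws$qk), ws$qk)
    out$u <- split(u, split_idx)
    names(out$u) <- vapply(spec$random, function(r) r$label, "")
  }
  out
}

#' Solve the mixed-model equations at given variance components
#'
#' Henderson's mixed-model equations at fixed variance components: returns
#' fixed-effect solutions, BLUPs per random term, fitted values and a
#' residual check of the equations.
#'
#' @param spec a [mm_spec()].
#' @param sigma2 named numeric vector of random-term variances (names
#'   matching the term labels; omit if there are no random terms).
#' @param sigma2_e residual variance (> 0).
#' @return list with `b` (named fixed effects), `u` (list of BLUPs), `yhat`,
#'   `fitted_terms` (per-term fitted vectors), and `mme_residual` (relative
#'   residual norm of the equations).
#' @export
solve_mme <- function(spec, sigma2 = numeric(0), sigma2_e, ws = NULL) {
  stopifnot(sigma2_e > 0, all(sigma2 >= 0))
  K <- length(spec$random)
  labs <- vapply(spec$random, function(r) r$label, "")
  if (K > 0) {
    if (is.null(names(sigma2))) names(sigma2) <- labs
    sigma2 <- sigma2[labs]
    if (anyNA(sigma2)) stop("missing variance for term(s): ",
                            paste(labs[is.na(sigma2)], collapse = ", "))
  }
  gamma <- pmax(sigma2 / sigma2_e, 1e-10)
  if (is.null(ws)) ws <- mm_workspace(spec)
  sol <- mm_eval(spec, gamma, ws, want_solutions = TRUE)
  b <- stats::setNames(sol$b, colnames(spec$X))
  fitted_terms <- list(fixed = as.numeric(spec$X %*% sol$b))
  yhat <- fitted_terms$fixed
  for (k in seq_len(K)) {
    fk <- as.numeric(spec$random[[k]]$Z %*% sol$u[[k]])
    fitted_terms[[labs[k]]] <- fk
    yhat <- yhat + fk
  }
  # Henderson-system residual check, computed blockwise:
  #   top:    X'X b + X'Z u - X'y
  #   bottom: Z'X b + (Z'Z + blockdiag(Kinv/gamma)) u - Z'y
  if (K > 0) {
    u <- unlist(sol$u, use.names = FALSE)
    top <- as.numeric(ws$XtX %*% sol$b) + as.numeric(Matrix::crossprod(ws$ZtX, u)) -
      as.numeric(ws$Xty)
    bot <- as.numeric(ws$ZtX %*% sol$b) + as.numeric(mm_cuu(ws, gamma) %*% u) -
      as.numeric(ws$Zty)
    rhs2 <- sum(ws$Xty^2) + sum(ws$Zty^2)
    resid_norm <- sqrt(sum(top^2) + sum(bot^2)) / max(sqrt(rhs2), 1e-12)
  } else {
    top <- as.numeric(ws$XtX %*% sol$b) - as.numeric(ws$Xty)
    resid_norm <- sqrt(sum(top^2)) / max(sqrt(sum(ws$Xty^2)), 1e-12)
  }
  list(b = b, u = sol$u, yhat = yhat, fitted_terms = fitted_terms,
       mme_residual = resid_norm)
}

#' Estimate variance components by ML or REML
#'
#' Profile-likelihood optimisation over the variance ratios
#' `gamma_k = sigma2_k / sigma2_e` (on the log scale, residual variance
#' profiled out in closed form), using `optim(L-BFGS-B)`. Boundary estimates
#' (ratios at the lower box) are allowed and flagged.
#'
#' @param spec a [mm_spec()].
#' @param method `"ML"` or `"REML"`.
#' @param gamma_start optional starting ratios (default 0.5 for each term).
#' @param lower,upper box constraints on `log(gamma)`.
#' @param maxit maximum optimiser iterations.
#' @return object of class `mm_fit`: fixed effects, BLUPs, variance
#'   components (`sigma2`, `sigma2_e`), `logLik_ML`/`logLik_REML` evaluated
#'   at the estimates, `AIC` (from the ML likelihood,
#'   `n_parameters = p + #variance components`), convergence diagnostics and
#'   per-term fitted components.
#' @export
fit_variance_components <- function(spec, method = c("REML", "ML"),
                                    gamma_start = NULL,
                                    lower = log(1e-8), upper = log(1e8),
                                    maxit = 200) {
  method <- match.arg(method)
  K <- length(spec$random)
  ws <- mm_workspace(spec)
  env <- new.env()
  crit <- if (method == "ML") "m2ll_ml" else "m2ll_reml"
  if (K == 0) {
    sol <- mm_eval(spec, numeric(0), ws)
    gamma <- numeric(0)
    conv <- list(convergence = 0L, counts = c(0, 0), boundary = logical(0))
  } else {
    if (is.null(gamma_start)) gamma_start <- rep(0.5, K)
    obj <- function(rho) {
      mm_eval(spec, exp(rho), ws, env = env)[[crit]]
    }
    opt <- stats::optim(log(gamma_start), obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = maxit, factr = 1e9))
    if (opt$convergence != 0 && opt$convergence != 1) {
      stop("variance-component optimisation failed to converge: ",
           opt$convergence, " ", opt$message)
    }
    gamma <- exp(opt$par)
    conv <- list(convergence = opt$convergence, counts = opt$counts,
                 boundary = opt$par <= lower + 1e-6)
    sol <- mm_eval(spec, gamma, ws, env = env)
  }
  n <- spec$n; p <- spec$p
  sigma2_e <- if (method == "ML") sol$r2 / n else sol$r2 / (n - p)
  sigma2 <- stats::setNames(gamma * sigma2_e,
                            vapply(spec$random, function(r) r$label, ""))
  mme <- solve_mme(spec, sigma2, sigma2_e, ws = ws)
  n_par <- p + K + 1
  fit <- list(spec = spec, method = method,
              b = mme$b, u = mme$u, yhat = mme$yhat,
              fitted_terms = mme$fitted_terms, mme_residual = mme$mme_residual,
              gamma = gamma, sigma2 = sigma2, sigma2_e = sigma2_e,
              logLik_ML = -0.5 * sol$m2ll_ml,
              logLik_REML = -0.5 * sol$m2ll_reml,
              n_parameters = n_par,
              AIC = sol$m2ll_ml + 2 * n_par,
              convergence = conv, n = n, p = p,
              y_checksum = sum(spec$y) + 1e-3 * sum(spec$y * seq_len(n)))
  class(fit) <- "mm_fit"
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("mm_fit (%s): n=%d, logLik_ML=%.3f, AIC=%.2f\n",
              x$method, x$n, x$logLik_ML, x$AIC))
  cat("  sigma2_e =", signif(x$sigma2_e, 5), "\n")
  for (nm in names(x$sigma2)) {
    cat("  sigma2[", nm, "] =", signif(x$sigma2[[nm]], 5), "\n")
  }
  invisible(x)
}

#' Serialise a fit to JSON
#'
#' Writes the portable summary of a fit (fixed effects, variance
#' components, log-likelihoods, AIC, convergence) as JSON; BLUP vectors are
#' included optionally.
#'
#' @param fit an `mm_fit`.
#' @param path output path (or `NULL` to return the JSON string).
#' @param include_blups include the random-effect solutions.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_fit_json <- function(fit, path = NULL, include_blups = FALSE) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("jsonlite is required for JSON serialisation")
  }
  out <- list(method = fit$method, n = fit$n,
              fixed_effects = as.list(fit$b),
              sigma2 = as.list(fit$sigma2), sigma2_e = fit$sigma2_e,
              logLik_ML = fit$logLik_ML, logLik_REML = fit$logLik_REML,
              n_parameters = fit$n_parameters, AIC = fit$AIC,
              convergence = fit$convergence,
              model_id = fit$model_id, trait = fit$trait, marker = fit$marker)
  if (include_blups) out$u <- fit$u
  js <- jsonlite::toJSON(out[!vapply(out, is.null, TRUE)],
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Compare fitted models by AIC
#'
#' Ranks fits by AIC (ML likelihoods) and reports the AIC difference
#' relative to the declared null model; the lowest AIC is flagged best
#' (ties resolved in favour of the earlier-listed model).
#'
#' @param fits list of [fit_variance_components()] fits of the same response.
#' @param labels optional model labels.
#' @param null index of the null model for the difference column.
#' @return data.frame with `model`, `n_parameters`, `logLik`, `AIC`,
#'   `dAIC` (`AIC_null - AIC`, positive = better than null), `best`.
#' @export
aic_compare <- function(fits, labels = NULL, null = 1) {
  if (is.null(labels)) labels <- paste0("model", seq_along(fits))
  ys <- vapply(fits, function(f) f$y_checksum, 0)
  ns <- vapply(fits, function(f) f$n, 0L)
  if (length(unique(ns)) > 1 || max(abs(ys - ys[1])) > 1e-8 * max(1, abs(ys[1]))) {
    stop("fits are not on an identical response/data")
  }
  meth <- vapply(fits, function(f) f$method, "")
  ps <- vapply(fits, function(f) f$p, 0L)
  if (any(meth == "REML") && length(unique(ps)) > 1) {
    stop("REML likelihoods are not comparable across different fixed structures")
  }
  aic <- vapply(fits, function(f) f$AIC, 0)
  out <- data.frame(model = labels,
                    n_parameters = vapply(fits, function(f) f$n_parameters, 0),
                    logLik = vapply(fits, function(f) f$logLik_ML, 0),
                    AIC = aic, dAIC = aic[null] - aic,
                    best = seq_along(fits) == which.min(aic),
                    stringsAsFactors = FALSE)
  out[order(out$AIC), , drop = FALSE]
}

#' Proportion of phenotypic variance explained by the marker term
#'
#' Variance of the fitted marker component over the variance of the
#' response, optionally also including the polygenic component.
#'
#' @param fit an `mm_fit` whose model contains the named term(s).
#' @param marker_terms labels of the marker term(s).
#' @param polygenic_term label of the polygenic term, or `NULL`.
#' @return list with `marker` (marker-only proportion) and, when a
#'   polygenic term is given, `marker_plus_polygenic`.
#' @export
variance_explained_by_marker <- function(fit, marker_terms,
                                         polygenic_term = NULL) {
  y <- fit$spec$y
  vy <- stats::var(y)
  if (vy == 0) stop("zero phenotypic variance")
  miss <- setdiff(c(marker_terms, polygenic_term), names(fit$fitted_terms))
  if (length(miss)) stop("fit has no term(s): ", paste(miss, collapse = ", "))
  mk <- Reduce(`+`, fit$fitted_terms[marker_terms])
  out <- list(marker = stats::var(mk) / vy)
  if (!is.null(polygenic_term)) {
    out$marker_plus_polygenic <-
      stats::var(mk + fit$fitted_terms[[polygenic_term]]) / vy
  }
  out
}

#' Observed-scale to liability-scale heritability
#'
#' Dempster-Lerner transformation for a binary trait:
#' `h2_liab = h2_obs * K (1 - K) / z^2`, where `K` is the prevalence and
#' `z` the standard-normal density at the `K`-th upper quantile.
#'
#' @param h2_obs observed-scale heritability in `[0, 1]`.
#' @param prevalence trait prevalence in `(0, 1)`.
#' @return liability-scale heritability.
#' @export
observed_to_liability_h2 <- function(h2_obs, prevalence) {
  stopifnot(h2_obs >= 0, h2_obs <= 1)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  z <- stats::dnorm(stats::qnorm(prevalence))
  h2_obs * prevalence * (1 - prevalence) / z^2
}

#' @rdname observed_to_liability_h2
#' @param h2_liab liability-scale heritability.
#' @export
liability_to_observed_h2 <- function(h2_liab, prevalence) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  z <- stats::dnorm(stats::qnorm(prevalence))
  h2_liab * z^2 / (prevalence * (1 - prevalence))
}
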