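#' Gaussian GEE for clustered condition effects
#'
#' Marginal (population-averaged) regression of a response on a categorical
#' condition with repeated measures per slice, fitted by generalized
#' estimating equations with a Gaussian family and identity link.  GEE with
#' a cluster-robust (sandwich) covariance is used instead of ANOVA because
#' drug conditions routinely change the response variance across groups
#' (homogeneity of variances fails).  Working correlation is exchangeable by
#' default (repeated epochs within a slice); independence is offered for
#' sensitivity analysis.  With singleton clusters and independence the fit
#' reduces exactly to ordinary least squares.
#'
#' @param data data.frame with columns `slice_id` (cluster), `condition`
#'   (categorical) and `response` (finite numeric), e.g. the normalized
#'   period column of an epoch-summary table.
#' @param corr working correlation, `"exchangeable"` or `"independence"`.
#' @param tol convergence tolerance on the max absolute coefficient change
#'   (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 100).
#' @return A list of class `gee_fit`: `coefficients` (intercept = reference
#'   condition mean, plus condition offsets), `vcov` (sandwich), `robust_se`,
#'   `rho` (estimated exchangeable correlation), `phi` (dispersion),
#'   `corr`, `levels`, `n_clusters`, `n_obs`, `iterations`, `converged`.
#' @export
fit_gee <- function(data, corr = c("exchangeable", "independence"),
                    tol = 1e-8, max_iter = 100) {
  corr <- match.arg(corr)
  stopifnot(all(c("slice_id", "condition", "response") %in% names(data)))
  if (any(!is.finite(data$response))) stop("responses must be finite")
  cond <- factor(data$condition)
  if (nlevels(cond) < 2) stop("need at least 2 conditions")
  id <- factor(data$slice_id)
  if (nlevels(id) < 2) stop("need at least 2 clusters")
  X <- stats::model.matrix(~cond)
  colnames(X) <- c("(Intercept)", paste0("condition", levels(cond)[-1]))
  y <- data$response
  p <- ncol(X)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  N <- length(y)
  rows <- split(seq_len(N), id)

  beta <- qr.solve(X, y)  # OLS start
  rho <- 0
  iter <- 0L
  converged <- FALSE
  phi <- NA_real_
  while (iter < max_iter) {
    iter <- iter + 1L
    r <- y - X %*% beta
    phi <- sum(r^2) / (N - p)
    if (phi < 1e-12) {
      warning("degenerate (zero) residual variance")
      phi <- 0
      converged <- TRUE
      break
    }
    if (corr == "exchangeable") {
      num <- 0; cnt <- 0
      for (ix in rows) {
        ni <- length(ix)
        if (ni < 2) next
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        cnt <- cnt + ni * (ni - 1) / 2
      }
      rho <- if (cnt > p) num / ((cnt - p) * phi) else 0
      nmax <- max(lengths(rows))
      rho <- min(max(rho, -1 / (nmax - 1) + 1e-6), 0.999)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ix in rows) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      yi <- y[ix]
      # V_i^{-1} up to 1/phi: ((1-rho)I + rho J)^{-1}
      # = 1/(1-rho) [I - rho/(1 - rho + ni*rho) J]
      if (ni == 1 || rho == 0) {
        XtVi <- t(Xi)
      } else {
        f <- rho / (1 - rho + ni * rho)
        XtVi <- t(Xi) / (1 - rho) -
          matrix(colSums(Xi), p, 1) %*% matrix(1, 1, ni) * (f / (1 - rho))
      }
      A <- A + XtVi %*% Xi
      b <- b + XtVi %*% yi
    }
    beta_new <- solve(A, b)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (!converged && phi > 0) {
    cnd <- simpleError(sprintf("GEE did not converge in %d iterations",
                               max_iter))
    cnd$last_beta <- as.numeric(beta)
    stop(cnd)
  }

  # sandwich covariance
  if (phi == 0) {
    V <- matrix(0, p, p)
  } else {
    r <- y - X %*% beta
    A <- matrix(0, p, p)
    M <- matrix(0, p, p)
    for (ix in rows) {
      ni <- length(ix)
      Xi <- X[ix, , drop = FALSE]
      ri <- r[ix]
      if (ni == 1 || rho == 0) {
        XtVi <- t(Xi)
      } else {
        f <- rho / (1 - rho + ni * rho)
        XtVi <- t(Xi) / (1 - rho) -
          matrix(colSums(Xi), p, 1) %*% matrix(1, 1, ni) * (f / (1 - rho))
      }
      A <- A + XtVi %*% Xi
      u <- XtVi %*% ri
      M <- M + u %*% t(u)
    }
    Ainv <- solve(A)
    V <- Ainv %*% M %*% Ainv
  }
  beta <- as.numeric(beta)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = beta, vcov = V,
                 robust_se = sqrt(pmax(diag(V), 0)),
                 rho = if (corr == "exchangeable") rho else 0,
                 phi = phi, corr = corr, levels = levels(cond),
                 n_clusters = nlevels(id), n_obs = N,
                 iterations = iter, converged = converged,
                 contrasts = NULL),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Gaussian GEE (%s working correlation), %d obs in %d clusters\n",
              x$corr, x$n_obs, x$n_clusters))
  print(data.frame(estimate = x$coefficients, robust_se = x$robust_se))
  if (!is.null(x$contrasts)) {
    cat("Contrasts (Bonferroni-adjusted):\n")
    print(x$contrasts)
  }
  invisible(x)
}

#' Bonferroni-adjusted pairwise condition contrasts
#'
#' Wald z-tests of condition differences using the robust (sandwich)
#' standard errors of a [fit_gee()] fit, with the Bonferroni adjustment
#' `p_bonferroni = min(1, k * p_raw)` over the k requested contrasts.
#'
#' @param fit a `gee_fit`.
#' @param contrasts list of length-2 character vectors
#'   `c(condition_A, condition_B)`; each contrast estimates mean(A) -
#'   mean(B).  Default: every condition vs the reference (first) level.
#' @return The fit with a `contrasts` data.frame added: `label`, `estimate`,
#'   `se`, `z`, `p_raw`, `p_bonferroni`.
#' @export
bonferroni_contrasts <- function(fit, contrasts = NULL) {
  stopifnot(inherits(fit, "gee_fit"))
  if (!fit$converged) stop("fit did not converge")
  lev <- fit$levels
  if (is.null(contrasts))
    contrasts <- lapply(lev[-1], function(l) c(l, lev[1]))
  coefv <- function(l) {  # coefficient vector of mean(condition l)
    v <- numeric(length(fit$coefficients))
    v[1] <- 1
    if (l != lev[1]) {
      j <- match(paste0("condition", l), names(fit$coefficients))
      if (is.na(j)) stop("unknown condition: ", l)
      v[j] <- 1
    }
    v
  }
  k <- length(contrasts)
  rows <- lapply(contrasts, function(ctr) {
    if (!all(ctr %in% lev)) stop("unknown condition in contrast: ",
                                 paste(setdiff(ctr, lev), collapse = ", "))
    L <- coefv(ctr[1]) - coefv(ctr[2])
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    z <- if (se > 0) est / se else ifelse(est == 0, 0, sign(est) * Inf)
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(label = paste(ctr[1], "-", ctr[2]), estimate = est, se = se,
               z = z, p_raw = p, p_bonferroni = min(1, k * p),
               stringsAsFactors = FALSE)
  })
  fit$contrasts <- do.call(rbind, rows)
  fit
}
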