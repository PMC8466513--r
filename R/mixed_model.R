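#' Factor levels accepted by the association model
#'
#' Canonical level sets for the fixed factors of the repeated-measures
#' animal model: genotype, sex, breeder, weather at the start and end of the
#' race, and race category.
#'
#' @return Named list of character vectors.
#' @export
model_factor_levels <- function() {
  list(genotype = genotype_levels(),
       sex = c("male", "female"),
       breeder = c("A", "B"),
       weather_start = c("sunny", "changeable"),
       weather_end = c("sunny", "changeable", "rainy", "windy", "cloudy"),
       category = c("short", "long"))
}

#' Build the design structure for the animal model
#'
#' Assembles the response vector, the full-rank fixed-effect incidence
#' matrix (treatment coding, reference levels dropped and recorded), the
#' record-to-bird incidence, and the additive relationship submatrix for
#' the phenotyped birds. The model is
#' \deqn{y = \mu + g + s + h + ps + pp + k + i + a + e}
#' with fixed genotype (g), sex (s), breeder (h), weather at start (ps) and
#' end (pp) and race category (k); random permanent-environment effect i
#' (iid per bird, carrying the repeated records), polygenic effect a with
#' covariance proportional to the relationship matrix, and residual e.
#'
#' Factors observed at a single level are dropped with a warning; factor
#' values outside their canonical level sets are an error.
#'
#' @param records Scored race records (see [score_races()]) with covariate
#'   columns `sex`, `breeder`, `weather_start`, `weather_end`, `category`.
#' @param genotypes Data frame `pigeon_id`, `genotype`; merged onto records.
#' @param A Additive relationship matrix whose dimnames cover every pigeon
#'   in `records` (see [additive_relationship_matrix()]).
#' @param response Name of the response column (default `"ap"`).
#' @param fixed Character vector of fixed-factor names to include (default
#'   all of [model_factor_levels()]).
#' @param on_singular What to do when the fixed-effect design is rank
#'   deficient (e.g. race-level covariates aliased by chance in a short
#'   season): `"error"` (default) or `"drop"`, which removes aliased
#'   columns with a warning, as `lm()` does.
#' @return A list of class `"pr_design"` with elements `y`, `X`, `bird`
#'   (factor of length n), `A` (q x q, phenotyped birds), `xlev` (observed
#'   levels used), `dropped` (single-level factors removed) and `response`.
#' @export
build_design <- function(records, genotypes = NULL, A,
                         response = "ap",
                         fixed = names(model_factor_levels()),
                         on_singular = c("error", "drop")) {
  on_singular <- match.arg(on_singular)
  if (!response %in% names(records))
    stop(sprintf("records lack response column '%s'", response), call. = FALSE)
  if (!is.null(genotypes)) {
    if (anyDuplicated(genotypes$pigeon_id))
      stop("duplicate pigeon_id in genotypes", call. = FALSE)
    records$genotype <- genotypes$genotype[match(records$pigeon_id,
                                                 genotypes$pigeon_id)]
    if (anyNA(records$genotype))
      stop("genotype missing for at least one phenotyped pigeon", call. = FALSE)
  }
  canon <- model_factor_levels()
  fixed <- intersect(names(canon), fixed)
  miss <- setdiff(fixed, names(records))
  if (length(miss))
    stop(sprintf("records lack factor column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)

  birds <- unique(as.character(records$pigeon_id))
  absent <- setdiff(birds, rownames(A))
  if (length(absent))
    stop(sprintf("pigeon(s) missing from the relationship matrix: %s",
                 paste(utils::head(absent, 5L), collapse = ", ")),
         call. = FALSE)

  xlev <- list()
  dropped <- character(0)
  dat <- data.frame(row.names = seq_len(nrow(records)))
  for (f in fixed) {
    vals <- as.character(records[[f]])
    bad <- setdiff(unique(vals), canon[[f]])
    if (length(bad))
      stop(sprintf("unknown level '%s' in factor '%s'", bad[1L], f),
           call. = FALSE)
    obs <- intersect(canon[[f]], unique(vals))  # canonical order
    if (length(obs) < 2L) {
      warning(sprintf("factor '%s' has a single observed level; dropped", f),
              call. = FALSE)
      dropped <- c(dropped, f)
      next
    }
    dat[[f]] <- factor(vals, levels = obs)
    xlev[[f]] <- obs
  }
  form <- if (length(xlev))
    stats::as.formula(paste("~", paste(names(xlev), collapse = " + ")))
  else stats::as.formula("~ 1")
  X <- stats::model.matrix(form, dat)
  qrX <- qr(X)
  aliased <- character(0)
  if (qrX$rank < ncol(X)) {
    if (on_singular == "error")
      stop("fixed-effect design is singular", call. = FALSE)
    keep <- qrX$pivot[seq_len(qrX$rank)]
    aliased <- colnames(X)[-keep]
    warning(sprintf("aliased fixed-effect column(s) dropped: %s",
                    paste(aliased, collapse = ", ")), call. = FALSE)
    X <- X[, sort(keep), drop = FALSE]
  }

  structure(list(y = as.numeric(records[[response]]),
                 X = X,
                 bird = factor(as.character(records$pigeon_id), levels = birds),
                 A = A[birds, birds, drop = FALSE],
                 xlev = xlev,
                 formula = form,
                 dropped = dropped,
                 aliased = aliased,
                 response = response),
            class = "pr_design")
}

# profiled restricted log-likelihood machinery --------------------------------
#
# V = sigma2_e * H with H = I + Z W Z', W = lambda_i I + lambda_a A over the
# q phenotyped birds and Z the n x q record-to-bird incidence. All per-
# evaluation work is reduced to q x q algebra via the Woodbury identity and
# the matrix determinant lemma; sigma2_e is profiled out analytically.

.design_sufficient <- function(design) {
  Zi <- as.integer(design$bird)
  q <- nlevels(design$bird)
  X <- design$X; y <- design$y
  list(XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2),
       ZtX = rowsum(X, Zi), Zty = as.numeric(rowsum(y, Zi)),
       D = as.numeric(table(Zi)), n = length(y), p = ncol(X), q = q)
}

# minus twice the restricted log-likelihood profiled over sigma2_e, plus the
# GLS quantities at the given variance ratios
.reml_eval <- function(lambda_i, lambda_a, suf, A) {
  q <- suf$q
  W <- diag(lambda_i, q) + lambda_a * A
  # W must be SPD for the factorisation; guarantee a floor
  R <- chol(W + diag(1e-12, q))          # upper triangular, W = R'R
  # with F = Z R' (n x q): H = I + F F', |H| = |I + F'F|, F'F = R D R'
  M <- sweep(R, 2L, sqrt(suf$D), "*")    # R %*% diag(sqrt(D))
  K <- diag(q) + tcrossprod(M)           # I + R D R'
  cK <- chol(K)
  logdetH <- 2 * sum(log(diag(cK)))
  # H^{-1} = I - Z R' K^{-1} R Z'
  RZtX <- R %*% suf$ZtX
  RZty <- as.numeric(R %*% suf$Zty)
  Ki_RZtX <- backsolve(cK, forwardsolve(t(cK), RZtX))
  Ki_RZty <- backsolve(cK, forwardsolve(t(cK), RZty))
  XtHiX <- suf$XtX - crossprod(RZtX, Ki_RZtX)
  XtHiy <- suf$Xty - crossprod(RZtX, Ki_RZty)
  ytHiy <- suf$yty - sum(RZty * Ki_RZty)
  cC <- tryCatch(chol(XtHiX), error = function(e) NULL)
  if (is.null(cC)) return(list(value = Inf))
  beta <- backsolve(cC, forwardsolve(t(cC), XtHiy))
  yPy <- max(ytHiy - sum(XtHiy * beta), 1e-300)
  np <- suf$n - suf$p
  sigma2_e <- yPy / np
  logdetC <- 2 * sum(log(diag(cC)))
  m2ll <- np * log(2 * pi * sigma2_e) + logdetH + logdetC + np
  list(value = m2ll, beta = as.numeric(beta), sigma2_e = sigma2_e,
       XtHiX = XtHiX, cC = cC)
}

#' Fit the repeated-measures animal model by REML
#'
#' Maximises the restricted log-likelihood of the two-random-component
#' animal model over the variance components (permanent environment,
#' polygenic, residual). The residual variance is profiled out analytically
#' and the optimisation runs over the log variance ratios
#' `log(sigma2_i / sigma2_e)` and `log(sigma2_a / sigma2_e)`, which imposes
#' the non-negativity bounds by construction. Two default starts (equal
#' split and residual-dominant) are tried, Nelder-Mead exploration is
#' polished with L-BFGS-B, and the best optimum is kept; given the data and
#' start the fit is deterministic.
#'
#' @param design A [build_design()] structure.
#' @param start Optional named numeric `c(sigma2_i=, sigma2_a=, sigma2_e=)`
#'   used as an additional start.
#' @param tol Convergence tolerance on the relative change of -2 log RL.
#' @param max_iter Maximum optimizer iterations per start.
#' @param fix Optional named list fixing components at a value, e.g.
#'   `list(sigma2_a = 0)` drops the polygenic term, and
#'   `list(sigma2_i = 0, sigma2_a = 0)` reduces the fit to ordinary least
#'   squares.
#' @return A list of class `"pr_fit"`: `sigma2` (named `i`, `a`, `e`),
#'   `beta`, `se`, `vcov_beta`, `loglik_reml`, `converged`, `iterations`,
#'   `lsmeans` (genotype least-squares means, if genotype is in the model),
#'   and the design.
#' @export
fit_reml <- function(design, start = NULL, tol = 1e-8, max_iter = 200L,
                     fix = NULL) {
  stopifnot(inherits(design, "pr_design"))
  suf <- .design_sufficient(design)
  if (suf$n <= suf$p)
    stop("more fixed-effect parameters than records", call. = FALSE)
  A <- design$A
  fix_i <- if (!is.null(fix$sigma2_i)) as.numeric(fix$sigma2_i) else NA_real_
  fix_a <- if (!is.null(fix$sigma2_a)) as.numeric(fix$sigma2_a) else NA_real_
  if ((!is.na(fix_i) && fix_i < 0) || (!is.na(fix_a) && fix_a < 0))
    stop("fixed variance components must be non-negative", call. = FALSE)

  free <- c(i = is.na(fix_i), a = is.na(fix_a))
  # fixing a component is only meaningful at 0 here (drops the term)
  if ((!is.na(fix_i) && fix_i != 0) || (!is.na(fix_a) && fix_a != 0))
    stop("only fixing variance components at 0 is supported", call. = FALSE)

  lambda_of <- function(theta) {
    k <- 1L
    li <- if (free[["i"]]) { v <- exp(theta[k]); k <- k + 1L; v } else 0
    la <- if (free[["a"]]) exp(theta[k]) else 0
    c(li, la)
  }
  objective <- function(theta) {
    lam <- lambda_of(theta)
    .reml_eval(lam[1L], lam[2L], suf, A)$value
  }

  n_free <- sum(free)
  iterations <- 0L
  if (n_free == 0L) {
    ev <- .reml_eval(0, 0, suf, A)
    best <- list(par = numeric(0), value = ev$value, convergence = 0L)
  } else {
    starts <- list(rep(log(0.5), n_free), rep(log(0.05), n_free))
    if (!is.null(start)) {
      s_e <- max(start[["sigma2_e"]], 1e-8)
      th <- log(pmax(c(if (free[["i"]]) start[["sigma2_i"]],
                       if (free[["a"]]) start[["sigma2_a"]]) / s_e, 1e-8))
      starts <- c(starts, list(th))
    }
    fits <- lapply(starts, function(th0) {
      nm <- if (n_free == 1L) {
        op <- stats::optimize(function(t) objective(t), interval = th0 + c(-25, 25),
                              tol = max(tol, 1e-10))
        list(par = op$minimum, value = op$objective, convergence = 0L,
             counts = c(`function` = 50L))
      } else {
        stats::optim(th0, objective, method = "Nelder-Mead",
                     control = list(maxit = max_iter * 10L, reltol = tol))
      }
      lb <- tryCatch(
        stats::optim(nm$par, objective, method = "L-BFGS-B",
                     lower = rep(log(1e-10), n_free),
                     upper = rep(log(1e10), n_free),
                     control = list(maxit = max_iter, factr = 1e3)),
        error = function(e) nm)
      it <- nm$counts[["function"]] + lb$counts[["function"]]
      if (lb$value <= nm$value) c(lb, list(iters = it)) else c(nm, list(iters = it))
    })
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
    iterations <- best$iters
  }
  lam <- lambda_of(best$par)
  ev <- .reml_eval(lam[1L], lam[2L], suf, A)
  sigma2_e <- ev$sigma2_e
  # ratios driven to the numerical floor are structural zeros
  lam[lam <= 1e-8] <- 0
  sigma2 <- c(i = lam[1L] * sigma2_e, a = lam[2L] * sigma2_e, e = sigma2_e)

  Ci <- chol2inv(ev$cC)
  vcov_beta <- sigma2_e * Ci
  dimnames(vcov_beta) <- list(colnames(design$X), colnames(design$X))
  beta <- stats::setNames(ev$beta, colnames(design$X))
  fit <- structure(list(sigma2 = sigma2,
                        beta = beta,
                        se = sqrt(diag(vcov_beta)),
                        vcov_beta = vcov_beta,
                        loglik_reml = -ev$value / 2,
                        converged = isTRUE(best$convergence == 0L),
                        iterations = iterations,
                        design = design),
                   class = "pr_fit")
  if ("genotype" %in% names(design$xlev))
    fit$lsmeans <- .genotype_lsmeans(fit)
  fit
}

# least-squares means: average model-matrix rows over a balanced reference
# grid of the other factors
.genotype_lsmeans <- function(fit) {
  design <- fit$design
  grid <- expand.grid(design$xlev, stringsAsFactors = FALSE)
  for (f in names(design$xlev))
    grid[[f]] <- factor(grid[[f]], levels = design$xlev[[f]])
  Mm <- stats::model.matrix(design$formula, grid)
  Mm <- Mm[, colnames(design$X), drop = FALSE]  # respect aliased drops
  lev <- design$xlev$genotype
  L <- t(vapply(lev, function(g) colMeans(Mm[grid$genotype == g, , drop = FALSE]),
                numeric(ncol(Mm))))
  est <- as.numeric(L %*% fit$beta)
  se <- sqrt(rowSums((L %*% fit$vcov_beta) * L))
  list(table = data.frame(genotype = lev, lsmean = est, se = se,
                          stringsAsFactors = FALSE),
       L = L)
}

#' Pairwise genotype contrasts from a fitted animal model
#'
#' Wald tests on differences of genotype least-squares means, using the
#' large-sample normal approximation for the reference distribution.
#'
#' @param fit A [fit_reml()] result whose model includes genotype.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @return Data frame with one row per ordered pair (level2 - level1):
#'   `estimate`, `se`, `z`, `p_value`, `significant`.
#' @export
genotype_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "pr_fit"))
  if (is.null(fit$lsmeans))
    stop("genotype is not a factor of the fitted model", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  L <- fit$lsmeans$L
  lev <- fit$lsmeans$table$genotype
  pairs <- utils::combn(seq_along(lev), 2L)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    l <- L[j, ] - L[i, ]
    est <- sum(l * fit$beta)
    se <- sqrt(as.numeric(t(l) %*% fit$vcov_beta %*% l))
    z <- if (se > 0) est / se else 0
    data.frame(contrast = paste(lev[j], "-", lev[i]),
               estimate = est, se = se, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Raw ace-point means by genotype and race category
#'
#' Arithmetic means and standard errors of per-record ace points, grouped by
#' genotype for all races and within the short and long categories, with
#' race-record counts. Records whose pigeon has no genotype are excluded
#' with a warning giving the count.
#'
#' @param records Scored race records (must carry `ap` and `category`).
#' @param genotypes Data frame `pigeon_id`, `genotype`.
#' @return Data frame `genotype`, `scope` (all/short/long), `n_records`,
#'   `mean_ap`, `se`; empty groups are absent rows.
#' @export
summarize_by_genotype <- function(records, genotypes) {
  g <- genotypes$genotype[match(records$pigeon_id, genotypes$pigeon_id)]
  drop <- is.na(g)
  if (any(drop)) {
    warning(sprintf("%d record(s) without a genotype excluded", sum(drop)),
            call. = FALSE)
    records <- records[!drop, , drop = FALSE]
    g <- g[!drop]
  }
  scopes <- list(all = rep(TRUE, nrow(records)),
                 short = records$category == "short",
                 long = records$category == "long")
  out <- do.call(rbind, lapply(names(scopes), function(sc) {
    idx <- scopes[[sc]]
    do.call(rbind, lapply(intersect(genotype_levels(), unique(g[idx])),
                          function(gl) {
      ap <- records$ap[idx & g == gl]
      data.frame(genotype = gl, scope = sc, n_records = length(ap),
                 mean_ap = mean(ap),
                 se = stats::sd(ap) / sqrt(length(ap)),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.pr_fit <- function(x, ...) {
  cat("Repeated-measures animal model (REML)\n")
  cat(sprintf("  variance components: perm. env = %.3f, polygenic = %.3f, residual = %.3f\n",
              x$sigma2[["i"]], x$sigma2[["a"]], x$sigma2[["e"]]))
  cat(sprintf("  restricted log-likelihood: %.3f (%s, %d function evaluations)\n",
              x$loglik_reml, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  fixed effects:\n")
  print(data.frame(estimate = x$beta, se = x$se), digits = 4)
  if (!is.null(x$lsmeans)) {
    cat("  genotype least-squares means:\n")
    print(x$lsmeans$table, digits = 4)
  }
  invisible(x)
}
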