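#' Assemble phenotype data for an animal model
#'
#' Matches phenotype records to pedigree positions and builds the fixed-effect
#' design `X` (intercept first) and the record-to-individual incidence `Z`.
#' Records with a missing trait value are excluded from `y`/`X`/`Z`;
#' unphenotyped pedigree members still contribute through the relatedness
#' structure.
#'
#' @param ped ordered pedigree tibble (grouped or not).
#' @param phenotypes data frame with column `id`, the trait column, and any
#'   fixed-effect covariates.
#' @param trait name of the trait column.
#' @param fixed character vector of covariate names to put in `X` (factors get
#'   treatment contrasts); `NULL` for an intercept-only model.
#' @return a `gg_model_data` list with `y`, `X`, `Z`, `ids` (pedigree order)
#'   and `record_id`.
#' @export
build_model_data <- function(ped, phenotypes, trait = "y", fixed = NULL) {
  assert_ordered(ped)
  phenotypes <- tibble::as_tibble(phenotypes)
  if (!"id" %in% names(phenotypes)) abort("phenotypes need an 'id' column")
  if (!trait %in% names(phenotypes))
    abort(sprintf("trait column '%s' not in phenotypes", trait))
  phenotypes$id <- as.character(phenotypes$id)
  miss <- setdiff(phenotypes$id, ped$id)
  if (length(miss))
    abort(sprintf("phenotype id absent from pedigree: %s",
                  paste(head(miss, 5), collapse = ", ")))
  keep <- !is.na(phenotypes[[trait]])
  phen <- phenotypes[keep, ]
  m <- nrow(phen)
  if (m == 0) abort("no non-missing phenotype records")
  form <- if (is.null(fixed)) ~1 else reformulate(fixed)
  X <- model.matrix(form, data = phen)
  if (nrow(X) != m)
    abort("missing values in fixed-effect covariates are not allowed")
  n <- nrow(ped)
  Z <- Matrix::sparseMatrix(i = seq_len(m), j = match(phen$id, ped$id), x = 1,
                            dims = c(m, n), dimnames = list(NULL, ped$id))
  structure(list(y = phen[[trait]], X = X, Z = Z, ids = ped$id,
                 record_id = phen$id),
            class = "gg_model_data")
}

# Solve the mixed-model equations
#   [ X'X  X'W        ] [beta]   [X'y]
#   [ W'X  W'W + l*K  ] [eff ] = [W'y]
# (all in residual-variance units), optionally deleting constrained
# equations. Returns solutions (zeros reinserted at dropped positions),
# log|C|, y'Py and the Cholesky factor for later standard errors.
solve_mme <- function(X, W, y, Kpen, lambda, drop = integer(0)) {
  Xs <- as(X, "CsparseMatrix")
  XtX <- Matrix::crossprod(Xs)
  XtW <- Matrix::crossprod(Xs, W)
  WtW <- Matrix::crossprod(W)
  C <- rbind(cbind(XtX, XtW), cbind(Matrix::t(XtW), WtW + lambda * Kpen))
  C <- Matrix::forceSymmetric(C)
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(W, y)))
  p_all <- length(rhs)
  keep <- setdiff(seq_len(p_all), drop)
  ch <- tryCatch(Matrix::Cholesky(C[keep, keep], LDL = FALSE, perm = TRUE),
                 error = function(e)
                   abort(paste0("singular mixed-model equations (confounded effects,",
                                " e.g. groups collinear with the intercept): ",
                                conditionMessage(e))))
  sol_k <- as.numeric(Matrix::solve(ch, rhs[keep]))
  sol <- numeric(p_all)
  sol[keep] <- sol_k
  list(sol = sol,
       logdet = 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus),
       ypy = sum(y^2) - sum(sol_k * rhs[keep]),
       ch = ch, keep = keep, p_all = p_all)
}

# standard errors of selected equations: sqrt(diag(C^-1) * sigma2_E)
mme_se <- function(ms, pos, sigma2_E) {
  se <- rep(NA_real_, ms$p_all)
  inkeep <- match(pos, ms$keep)
  want <- pos[!is.na(inkeep)]
  if (length(want)) {
    E <- Matrix::sparseMatrix(i = inkeep[!is.na(inkeep)],
                              j = seq_along(want),
                              x = 1, dims = c(length(ms$keep), length(want)))
    Ci <- Matrix::solve(ms$ch, E)
    se[want] <- sqrt(pmax(0, Matrix::diag(Matrix::t(E) %*% Ci)) * sigma2_E)
  }
  se[pos]
}

#' Fit an animal model by sparse BLUP, with or without genetic groups
#'
#' Solves Henderson's mixed-model equations for one of three models:
#' \describe{
#'   \item{`"basic"`}{`y = X b + Z a + e`, breeding values with covariance
#'     `sigma2_A * A`; the model that is biased when unknown parents are
#'     genetically non-random.}
#'   \item{`"explicit"`}{adds the genetic-group contributions `Q` as fixed
#'     covariate regressions (`y = X b + Q g + Z a + e`); the reference
#'     group's column is dropped (its effect fixed at zero) so the remaining
#'     coefficients are contrasts.}
#'   \item{`"implicit"`}{fits total additive genetic effects `u` through the
#'     group-augmented inverse `A*`, with the reference group's equation
#'     removed. Group effects are read off the group positions; both routes
#'     yield identical group-effect estimates.}
#' }
#' Either way the fit reports breeding values `a`, total additive genetic
#' effects `u = Q g + a`, group contrasts `g` (with Wald standard errors) and
#' the variance components used.
#'
#' @param ped ordered pedigree; a grouped pedigree (see [assign_groups()]) is
#'   required for the two group modes.
#' @inheritParams build_model_data
#' @param mode model flavour; see Details.
#' @param varcomp variance components: `NULL` to estimate by REML (see
#'   [reml_estimate()]), a `gg_varcomp` object, or a list with elements
#'   `sigma2_A` and `sigma2_E`.
#' @param lambda_range search range for the REML variance ratio
#'   `lambda = sigma2_E / sigma2_A`.
#' @return a `gg_fit` object; inspect with [tidy.gg_fit()], `glance()` and
#'   [autoplot.gg_fit()].
#' @export
fit_animal_model <- function(ped, phenotypes, trait = "y", fixed = NULL,
                             mode = c("explicit", "implicit", "basic"),
                             varcomp = NULL, lambda_range = c(1e-4, 1e4)) {
  mode <- match.arg(mode)
  grouped <- mode != "basic"
  if (grouped) {
    check_grouped(ped)
    labels <- group_labels(ped)
    ref <- match(reference_group(ped), labels)
    Q <- q_matrix(ped)
  } else {
    labels <- NULL; ref <- NA_integer_; Q <- NULL
  }
  plain <- tibble::as_tibble(ped)
  md <- build_model_data(plain, phenotypes, trait, fixed)
  if (is.null(varcomp))
    varcomp <- reml_estimate(ped, phenotypes, trait = trait, fixed = fixed,
                             mode = mode, lambda_range = lambda_range)
  if (!inherits(varcomp, "gg_varcomp")) {
    stopifnot(is.list(varcomp), all(c("sigma2_A", "sigma2_E") %in% names(varcomp)))
    varcomp <- structure(list(sigma2_A = varcomp$sigma2_A,
                              sigma2_E = varcomp$sigma2_E,
                              lambda = varcomp$sigma2_E / varcomp$sigma2_A,
                              loglik = NA_real_, converged = NA,
                              n_obs = length(md$y)),
                         class = "gg_varcomp")
  }
  lambda <- varcomp$lambda
  n <- nrow(plain)
  p <- ncol(md$X)
  r <- length(labels)

  if (mode == "explicit") {
    Qrec <- as.matrix(md$Z %*% Q[, -ref, drop = FALSE])
    if (ncol(Qrec) > 0) colnames(Qrec) <- paste0("g:", labels[-ref])
    Xa <- cbind(md$X, Qrec)
    ms <- solve_mme(Xa, md$Z, md$y, a_inverse(plain), lambda)
    pa <- ncol(Xa)
    beta <- setNames(ms$sol[seq_len(p)], colnames(md$X))
    gcoef <- ms$sol[p + seq_len(r - 1)]
    g <- insert_ref(gcoef, ref, labels)
    a <- setNames(ms$sol[pa + seq_len(n)], plain$id)
    u <- as.numeric(Q %*% g) + a
    se_pos <- seq_len(pa)
  } else if (mode == "implicit") {
    Astar <- a_star(ped)
    Zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(length(md$y), r))
    W <- cbind(Zero, md$Z)
    ms <- solve_mme(md$X, W, md$y, Astar, lambda, drop = p + ref)
    beta <- setNames(ms$sol[seq_len(p)], colnames(md$X))
    g <- setNames(ms$sol[p + seq_len(r)], labels)
    u <- setNames(ms$sol[p + r + seq_len(n)], plain$id)
    a <- u - as.numeric(Q %*% g)
    se_pos <- c(seq_len(p), p + seq_len(r))
  } else {
    ms <- solve_mme(md$X, md$Z, md$y, a_inverse(plain), lambda)
    beta <- setNames(ms$sol[seq_len(p)], colnames(md$X))
    a <- setNames(ms$sol[p + seq_len(n)], plain$id)
    g <- NULL
    u <- a
    se_pos <- seq_len(p)
  }
  se <- mme_se(ms, se_pos, varcomp$sigma2_E)
  if (mode == "explicit") {
    beta_se <- setNames(se[seq_len(p)], names(beta))
    g_se <- insert_ref(se[p + seq_len(r - 1)], ref, labels, fill = NA_real_)
  } else if (mode == "implicit") {
    beta_se <- setNames(se[seq_len(p)], names(beta))
    g_se <- setNames(se[p + seq_len(r)], labels)
    g_se[ref] <- NA_real_
  } else {
    beta_se <- setNames(se, names(beta))
    g_se <- NULL
  }
  meta <- plain[intersect(c("id", "cohort", "sex", "immigrant"), names(plain))]
  structure(list(mode = mode, trait = trait,
                 beta = beta, beta_se = beta_se,
                 g = g, g_se = g_se, reference = if (grouped) labels[ref],
                 a = setNames(as.numeric(a), plain$id),
                 u = setNames(as.numeric(u), plain$id),
                 Q = Q, varcomp = varcomp, meta = meta,
                 n_obs = length(md$y)),
            class = "gg_fit")
}

insert_ref <- function(x, ref, labels, fill = 0) {
  out <- rep(fill, length(labels))
  out[-ref] <- x
  setNames(out, labels)
}

#' REML variance components for a single additive genetic term
#'
#' Profiles the residual maximum likelihood over the variance ratio
#' `lambda = sigma2_E / sigma2_A`: a log-scale grid search refined by
#' golden-section to relative tolerance `1e-6`. Each evaluation is one sparse
#' Cholesky factorization of the mixed-model coefficient matrix, using the
#' identity `log|V| + log|X'V^-1 X|` \eqn{=} `log|A| - n log(lambda) +
#' log|C|` (up to the residual-variance scale), so no dense matrix is formed.
#'
#' For the group modes the likelihood is evaluated with the group
#' contributions as fixed covariate regressions (the explicit
#' parameterization); the implicit formulation is the statistically identical
#' model, so the profile is the same, while `A*` itself is singular and has
#' no determinant to profile over.
#'
#' @inheritParams fit_animal_model
#' @param grid_n number of initial grid points across `lambda_range`.
#' @return a `gg_varcomp` object: `sigma2_A`, `sigma2_E`, `lambda`, `loglik`
#'   (full REML log-likelihood at the optimum), `converged` (`FALSE` when the
#'   optimum sits on the search boundary, e.g. `sigma2_A` at zero), and the
#'   evaluated `profile`.
#' @export
reml_estimate <- function(ped, phenotypes, trait = "y", fixed = NULL,
                          mode = c("explicit", "implicit", "basic"),
                          lambda_range = c(1e-4, 1e4), grid_n = 15) {
  mode <- match.arg(mode)
  grouped <- mode != "basic"
  if (grouped) {
    check_grouped(ped)
    Q <- q_matrix(ped)
    ref <- match(reference_group(ped), group_labels(ped))
  }
  plain <- tibble::as_tibble(ped)
  md <- build_model_data(plain, phenotypes, trait, fixed)
  Xl <- if (grouped) cbind(md$X, as.matrix(md$Z %*% Q[, -ref, drop = FALSE])) else md$X
  m <- length(md$y); p <- ncol(Xl); n <- nrow(plain)
  if (m < p + 2) abort("too few records for REML")
  Kinv <- a_inverse(plain)
  logdetA <- -sum(log(mendelian_variances(plain)))  # log|A^-1| = -log|A|
  m2l <- function(lambda) {
    ms <- solve_mme(Xl, md$Z, md$y, Kinv, lambda)
    s2e <- ms$ypy / (m - p)
    (m - p) * (log(2 * pi * s2e) + 1) - logdetA - n * log(lambda) + ms$logdet
  }
  lgrid <- exp(seq(log(lambda_range[1]), log(lambda_range[2]), length.out = grid_n))
  vals <- vapply(lgrid, m2l, numeric(1))
  best <- which.min(vals)
  boundary <- best %in% c(1L, grid_n)
  lo <- log(lgrid[max(1L, best - 1L)])
  hi <- log(lgrid[min(grid_n, best + 1L)])
  gs <- golden_section(function(l) m2l(exp(l)), lo, hi, tol = 1e-6)
  lambda <- exp(gs$x)
  ms <- solve_mme(Xl, md$Z, md$y, Kinv, lambda)
  s2e <- ms$ypy / (m - p)
  structure(list(sigma2_A = s2e / lambda, sigma2_E = s2e, lambda = lambda,
                 loglik = -0.5 * gs$f, converged = !boundary,
                 boundary = boundary,
                 profile = tibble::tibble(lambda = lgrid, loglik = -0.5 * vals),
                 n_obs = m),
            class = "gg_varcomp")
}

golden_section <- function(f, lo, hi, tol = 1e-6, max_iter = 200) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d_ <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d_)
  for (it in seq_len(max_iter)) {
    if (abs(b - a) < tol * (abs(a) + abs(b) + 1)) break
    if (fc < fd) {
      b <- d_; d_ <- c_; fd <- fc
      c_ <- b - gr * (b - a); fc <- f(c_)
    } else {
      a <- c_; c_ <- d_; fc <- fd
      d_ <- a + gr * (b - a); fd <- f(d_)
    }
  }
  if (fc < fd) list(x = c_, f = fc) else list(x = d_, f = fd)
}

#' Convert between breeding values and total additive genetic effects
#'
#' `u = Q g + a`: an individual's total additive genetic effect is the
#' group-contribution-weighted sum of group effects plus its breeding value.
#' The two functions are exact inverses of each other.
#'
#' @param a,u numeric vectors of breeding values / total effects.
#' @param Q contribution matrix ([q_matrix()]).
#' @param g group effects, ordered as `Q`'s columns (reference entry 0).
#' @return numeric vector (`u` or `a`).
#' @export
total_additive_effects <- function(a, Q, g) {
  stopifnot(length(a) == nrow(Q), length(g) == ncol(Q))
  as.numeric(Q %*% g) + a
}

#' @rdname total_additive_effects
#' @export
breeding_values_from_total <- function(u, Q, g) {
  stopifnot(length(u) == nrow(Q), length(g) == ncol(Q))
  u - as.numeric(Q %*% g)
}

#' @export
#' @method print gg_fit
print.gg_fit <- function(x, ...) {
  cat(sprintf("Animal model fit (mode = %s), %d records\n", x$mode, x$n_obs))
  cat(sprintf("  sigma2_A = %.4f, sigma2_E = %.4f\n",
              x$varcomp$sigma2_A, x$varcomp$sigma2_E))
  if (!is.null(x$g)) {
    cat(sprintf("  genetic group effects (reference = %s):\n", x$reference))
    for (j in seq_along(x$g))
      cat(sprintf("    %-12s %8.4f  (se %s)\n", names(x$g)[j], x$g[j],
                  ifelse(is.na(x$g_se[j]), "--", sprintf("%.4f", x$g_se[j]))))
  }
  invisible(x)
}

#' @export
#' @method print gg_varcomp
print.gg_varcomp <- function(x, ...) {
  cat(sprintf("REML variance components (%d records)\n", x$n_obs))
  cat(sprintf("  sigma2_A = %.4f  sigma2_E = %.4f  lambda = %.4f\n",
              x$sigma2_A, x$sigma2_E, x$lambda))
  cat(sprintf("  loglik = %.3f  converged = %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Tidy an animal model fit
#'
#' @param x a `gg_fit`.
#' @param effects `"groups"` (group contrasts with Wald tests), `"fixed"`
#'   (fixed-effect coefficients) or `"ranef"` (per-individual breeding values
#'   `a` and total additive effects `u`).
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.gg_fit <- function(x, effects = c("groups", "fixed", "ranef"), ...) {
  effects <- match.arg(effects)
  if (effects == "ranef") {
    out <- tibble::tibble(id = names(x$a), a = unname(x$a), u = unname(x$u))
    return(dplyr::left_join(out, x$meta, by = "id"))
  }
  if (effects == "groups") {
    if (is.null(x$g)) return(tibble::tibble())
    est <- x$g; se <- x$g_se
    term <- paste0("group_", names(x$g))
  } else {
    est <- x$beta; se <- x$beta_se
    term <- names(x$beta)
  }
  z <- est / se
  tibble::tibble(term = term, estimate = unname(est), std.error = unname(se),
                 statistic = unname(z),
                 p.value = unname(2 * pnorm(-abs(z))))
}

#' @export
glance.gg_fit <- function(x, ...) {
  tibble::tibble(mode = x$mode, nobs = x$n_obs,
                 sigma2_A = x$varcomp$sigma2_A, sigma2_E = x$varcomp$sigma2_E,
                 lambda = x$varcomp$lambda, loglik = x$varcomp$loglik,
                 converged = x$varcomp$converged)
}

#' @export
tidy.gg_varcomp <- function(x, ...) {
  tibble::tibble(component = c("sigma2_A", "sigma2_E"),
                 estimate = c(x$sigma2_A, x$sigma2_E))
}

#' @export
glance.gg_varcomp <- function(x, ...) {
  tibble::tibble(sigma2_A = x$sigma2_A, sigma2_E = x$sigma2_E,
                 lambda = x$lambda, loglik = x$loglik,
                 converged = x$converged, nobs = x$n_obs)
}

#' Plot cohort trends of predicted genetic effects
#'
#' Cohort means of predicted breeding values `a` and total additive genetic
#' effects `u`. With genetic groups modelled, `a` should show no temporal
#' trend in the absence of selection while `u` tracks gene flow; a basic
#' model's spurious trend in `a` is directly visible here.
#'
#' @param object a `gg_fit` whose pedigree carried a `cohort` column.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.gg_fit <- function(object, ...) {
  if (!"cohort" %in% names(object$meta))
    abort("autoplot needs a pedigree with a 'cohort' column")
  df <- tidy(object, effects = "ranef")
  df <- tidyr::pivot_longer(df[c("cohort", "a", "u")], c("a", "u"),
                            names_to = "effect", values_to = "value")
  df <- dplyr::summarise(dplyr::group_by(df, .data$cohort, .data$effect),
                         mean = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$cohort, .data$mean,
                                   colour = .data$effect)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cohort", y = "cohort mean predicted effect",
                  colour = NULL,
                  title = sprintf("Predicted genetic effects (%s model)", object$mode)) +
    ggplot2::theme_minimal()
}
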