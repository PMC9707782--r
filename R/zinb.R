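#' Specify a candidate habitat-use model
#'
#' A candidate model for site-month detection counts. All candidates share
#' the same chassis: a zero-inflated negative binomial response with an
#' intercept-only zero-inflation probability on the logit scale, a random
#' intercept for camera site, and `log(effort)` as an offset. Candidates
#' differ in their fixed-effect terms (given as a one-sided formula) and in
#' the negative-binomial variance structure: `"nb2"` has variance
#' `mu * (1 + mu / theta)` (quadratic), `"nb1"` has `mu * (1 + alpha)`
#' (linear).
#'
#' The parameter count used for AICc is
#' `k = (fixed-effect columns incl. intercept) + 1 (random-intercept sd) +
#' 1 (dispersion) + 1 (zero-inflation intercept)`.
#'
#' @param fixed One-sided formula of fixed-effect terms, e.g.
#'   `~ HD + I(HD^2) + TD + HD:TD`. Use `~ 1` for the null model.
#' @param family `"nb2"` (default) or `"nb1"`.
#' @param name Label for the model.
#' @param set Hypothesis-set label used for within/between-set comparison.
#' @return An object of class `btk_spec`.
#' @export
model_spec <- function(fixed = ~1, family = c("nb2", "nb1"),
                       name = NULL, set = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(fixed, "formula"))
  name <- name %||% paste(deparse(fixed[[length(fixed)]]), collapse = "")
  structure(
    list(fixed = fixed, family = family, name = name, set = set %||% name),
    class = "btk_spec"
  )
}

#' @export
print.btk_spec <- function(x, ...) {
  cat(sprintf("<btk_spec> %s [%s] %s\n", x$name, x$family,
              paste(deparse(x$fixed), collapse = "")))
  invisible(x)
}

#' Build design matrices for a candidate model
#'
#' Expands the fixed-effect formula against the site-month data, attaches
#' the `log(effort)` offset and the site grouping, and reports the model's
#' parameter count. Rows with zero effort have an undefined offset and are
#' dropped with a message. Factors use treatment contrasts, so a `season`
#' term contributes three indicator columns with spring as the reference.
#'
#' @param spec A [model_spec()].
#' @param data Site-month tibble with `count`, `effort`, `site_id` and every
#'   covariate named in the spec.
#' @return List with `X` (fixed-effect matrix), `y`, `offset`, `site`
#'   (integer index), `site_levels`, `k`, `n`, `n_dropped`.
#' @export
build_design <- function(spec, data) {
  vars <- all.vars(spec$fixed)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    stop("covariates missing from data: ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(c("count", "effort", "site_id") %in% names(data)))
  drop <- data$effort <= 0 | is.na(data$effort)
  if (any(drop)) {
    message(sum(drop), " rows with zero effort dropped (offset undefined)")
    data <- data[!drop, , drop = FALSE]
  }
  X <- stats::model.matrix(spec$fixed, data = data)
  site <- factor(data$site_id)
  ord <- order(as.integer(site))
  list(
    X = X[ord, , drop = FALSE],
    y = as.integer(data$count[ord]),
    offset = log(data$effort[ord]),
    site = as.integer(site[ord]) - 1L,
    site_levels = levels(site),
    k = ncol(X) + 3L,
    n = nrow(X),
    n_dropped = sum(drop)
  )
}

# Gauss-Hermite nodes/weights for weight function exp(-x^2), by
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- function(n) {
  if (n == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

#' Marginal negative log-likelihood of a zero-inflated NB mixed model
#'
#' Evaluates the exact marginal negative log-likelihood at a parameter
#' vector, integrating the site random intercept out by adaptive
#' Gauss-Hermite quadrature (or Laplace). Exposed mainly so the quadrature
#' can be validated against brute-force integration; [fit_zinb()] is the
#' user-facing entry point.
#'
#' @param par Numeric vector `c(beta, log_sigma, log_dispersion, logit_pi)`.
#' @param design Output of [build_design()].
#' @param family `"nb2"` or `"nb1"`.
#' @param nagq Number of quadrature nodes (default 15).
#' @param method `"agq"` or `"laplace"`.
#' @return Scalar negative log-likelihood.
#' @export
zinb_nll <- function(par, design, family = c("nb2", "nb1"), nagq = 15,
                     method = c("agq", "laplace")) {
  family <- match.arg(family)
  method <- match.arg(method)
  gh <- gauss_hermite(nagq)
  stopifnot(length(par) == ncol(design$X) + 3)
  .zinb_nll_cpp(par, design$X, design$y, design$offset, design$site,
                length(design$site_levels), if (family == "nb2") 2L else 1L,
                gh$nodes, gh$weights, if (method == "agq") 1L else 0L)
}

#' Fit a zero-inflated negative binomial mixed model
#'
#' Maximizes the marginal likelihood (random intercept integrated out by
#' adaptive Gauss-Hermite quadrature) by quasi-Newton BFGS from several
#' starting points: a moment-based start plus seeded jittered restarts. The
#' reported fit is the best converged optimum; standard errors come from
#' the numeric Hessian at the optimum. The dispersion, random-intercept sd
#' and zero-inflation probability are estimated on log / log / logit scales.
#'
#' @param data Site-month tibble (see [build_design()]).
#' @param spec A [model_spec()]; or a formula, which is promoted with
#'   defaults.
#' @param n_starts Number of optimization starts (default 5).
#' @param seed Seed for the jittered starts.
#' @param nagq Quadrature nodes (default 15).
#' @param method `"agq"` (default) or `"laplace"` for the faster
#'   approximation.
#' @param verbose Print progress.
#' @return An object of class `btk_zinb` with coefficient table, variance
#'   components, `logLik`, `k`, `n`, `AICc` and a `converged` flag.
#' @export
fit_zinb <- function(data, spec = ~1, n_starts = 5, seed = 1, nagq = 15,
                     method = c("agq", "laplace"), verbose = FALSE) {
  method <- match.arg(method)
  if (inherits(spec, "formula")) spec <- model_spec(spec)
  design <- build_design(spec, data)
  p <- ncol(design$X)
  gh <- gauss_hermite(nagq)
  fam_code <- if (spec$family == "nb2") 2L else 1L
  m_code <- if (method == "agq") 1L else 0L

  nll <- function(par) {
    v <- .zinb_nll_cpp(par, design$X, design$y, design$offset, design$site,
                       length(design$site_levels), fam_code,
                       gh$nodes, gh$weights, m_code)
    if (!is.finite(v)) 1e10 else v
  }

  # moment-based start: intercept at the raw log rate, others at zero
  base_start <- numeric(p + 3)
  names(base_start) <- c(colnames(design$X), "log_sigma", "log_disp",
                         "logit_pi")
  rate <- sum(design$y) / sum(exp(design$offset))
  if ("(Intercept)" %in% colnames(design$X)) {
    base_start["(Intercept)"] <- log(max(rate, 1e-6))
  }
  base_start["log_sigma"] <- log(0.5)
  base_start["log_disp"] <- 0
  base_start["logit_pi"] <- stats::qlogis(0.2)

  starts <- list(base_start)
  if (n_starts > 1) {
    jitters <- with_preserved_seed(seed, {
      lapply(seq_len(n_starts - 1), function(s) stats::rnorm(p + 3, sd = 0.5))
    })
    starts <- c(starts, lapply(jitters, function(j) base_start + j))
  }

  best <- NULL
  for (s in seq_along(starts)) {
    opt <- try(stats::optim(starts[[s]], nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    conv <- opt$convergence == 0 && opt$value < 1e9
    if (verbose) {
      message(sprintf("start %d: nll %.4f conv %s", s, opt$value, conv))
    }
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && opt$value < best$value - 1e-8)) {
      best <- list(par = opt$par, value = opt$value, conv = conv)
    }
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  if (!best$conv) {
    warning("model '", spec$name, "' did not converge; ",
            "result flagged and should be excluded from comparisons",
            call. = FALSE)
  }

  H <- try(stats::optimHess(best$par, nll), silent = TRUE)
  vcov_par <- matrix(NA_real_, p + 3, p + 3)
  if (!inherits(H, "try-error")) {
    Vi <- try(solve(H), silent = TRUE)
    if (!inherits(Vi, "try-error") && all(is.finite(diag(Vi))) &&
        all(diag(Vi) > 0)) {
      vcov_par <- Vi
    }
  }
  dimnames(vcov_par) <- list(names(base_start), names(base_start))

  par <- best$par
  se <- sqrt(diag(vcov_par))
  beta <- par[seq_len(p)]
  coef_tbl <- tibble::tibble(
    term = colnames(design$X),
    estimate = unname(beta),
    std_error = unname(se[seq_len(p)]),
    statistic = unname(beta / se[seq_len(p)]),
    p_value = 2 * stats::pnorm(-abs(unname(beta / se[seq_len(p)])))
  )
  logLik <- -best$value
  k <- design$k
  n <- design$n

  structure(list(
    spec = spec,
    coefficients = coef_tbl,
    sigma_site = unname(exp(par[p + 1])),
    dispersion = unname(exp(par[p + 2])),
    zi_prob = unname(stats::plogis(par[p + 3])),
    par = par,
    vcov = vcov_par,
    logLik = logLik,
    k = k,
    n = n,
    n_sites = length(design$site_levels),
    n_dropped = design$n_dropped,
    AICc = aicc(logLik, k, n),
    converged = best$conv,
    nagq = nagq,
    method = method,
    seed = seed
  ), class = "btk_zinb")
}

# evaluate expr under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' @export
print.btk_zinb <- function(x, ...) {
  cat(sprintf(
    "Zero-inflated %s mixed model '%s' (%s, %d nodes)\n",
    toupper(x$spec$family), x$spec$name, x$method, x$nagq))
  cat(sprintf("  n = %d site-months, %d sites; logLik = %.3f; k = %d; AICc = %.2f\n",
              x$n, x$n_sites, x$logLik, x$k, x$AICc))
  cat(sprintf("  sigma_site = %.3f; dispersion = %.3f; zi prob = %.3f; converged: %s\n",
              x$sigma_site, x$dispersion, x$zi_prob, x$converged))
  print(x$coefficients)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.btk_zinb <- function(x, ...) x$coefficients

#' @export
glance.btk_zinb <- function(x, ...) {
  tibble::tibble(
    model = x$spec$name, set = x$spec$set, family = x$spec$family,
    logLik = x$logLik, df = x$k, n = x$n, AICc = x$AICc,
    sigma_site = x$sigma_site, dispersion = x$dispersion,
    zi_prob = x$zi_prob, converged = x$converged
  )
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1) / (n - k - 1)`; requires
#' `n > k + 1`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations.
#' @return Scalar AICc.
#' @examples
#' aicc(-5, 3, 10) # 20
#' @export
aicc <- function(logLik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: n must exceed k + 1", call. = FALSE)
  }
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights
#'
#' The relative likelihood of each model, `exp(-delta_i / 2)`, divided by
#' the sum across the compared set, where `delta` is each model's AICc
#' difference from the set minimum.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to one.
#' @export
akaike_weights <- function(aicc_values) {
  stopifnot(length(aicc_values) >= 1, all(is.finite(aicc_values)))
  rel <- exp(-(aicc_values - min(aicc_values)) / 2)
  rel / sum(rel)
}

#' Compare fitted candidate models within and between hypothesis sets
#'
#' Produces the candidate-model comparison table: each model's df and AICc,
#' its AICc difference from the best model *within* its hypothesis set, the
#' difference of each set's best model from the overall best (*between*
#' sets), and Akaike weights computed within set. Non-converged fits are
#' excluded with a warning. Sub-models more than `within_cutoff` above
#' their set's best can be filtered by the caller (the presentation rule
#' keeps those within 2).
#'
#' @param fits List of `btk_zinb` fits.
#' @return Tibble with one row per model, ordered by set rank then
#'   within-set delta.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warning(sum(!conv), " non-converged fits excluded from comparison",
            call. = FALSE)
    fits <- fits[conv]
  }
  if (length(fits) == 0) stop("no converged fits to compare", call. = FALSE)
  tab <- purrr::map_dfr(fits, glance)
  tab <- tab |>
    dplyr::group_by(.data$set) |>
    dplyr::mutate(
      within_delta = .data$AICc - min(.data$AICc),
      weight = akaike_weights(.data$AICc)
    ) |>
    dplyr::ungroup()
  set_best <- tab |>
    dplyr::group_by(.data$set) |>
    dplyr::summarise(set_aicc = min(.data$AICc), .groups = "drop") |>
    dplyr::mutate(between_delta = .data$set_aicc - min(.data$set_aicc))
  tab |>
    dplyr::left_join(set_best, by = "set") |>
    dplyr::arrange(.data$between_delta, .data$within_delta) |>
    dplyr::select("set", "model", "family", "df", "AICc", "within_delta",
                  "between_delta", "weight", "converged")
}

#' The habitat-use candidate model set
#'
#' The five hypothesis sets for spatial habitat use — conflict,
#' anthropogenic, environmental, full, and null — each anthropogenic-
#' containing set with a sub-model dropping the trail-by-human-density
#' interaction. All use the quadratic human-density term and the nb2
#' variance structure. Expected covariate columns: `HD`, `RD`, `TD`,
#' `EVI`, `DUrb`, `DAg`, `DW`, `Ele`, `Sal`, `Con`.
#'
#' @return Named list of [model_spec()] objects.
#' @export
table1_model_set <- function() {
  list(
    conflict_int = model_spec(
      ~ HD + I(HD^2) + RD + EVI + DUrb + DAg + Ele + TD + TD:HD,
      name = "conflict + TD:HD", set = "conflict"),
    conflict = model_spec(
      ~ HD + I(HD^2) + RD + EVI + DUrb + DAg + Ele + TD,
      name = "conflict", set = "conflict"),
    full_int = model_spec(
      ~ HD + I(HD^2) + RD + EVI + DUrb + DAg + Con + DW + Sal + Ele + TD + TD:HD,
      name = "full + TD:HD", set = "full"),
    full = model_spec(
      ~ HD + I(HD^2) + RD + EVI + DUrb + DAg + Con + DW + Sal + Ele + TD,
      name = "full", set = "full"),
    anthropogenic_int = model_spec(
      ~ HD + I(HD^2) + RD + DUrb + DAg + Con + TD + TD:HD,
      name = "anthropogenic + TD:HD", set = "anthropogenic"),
    anthropogenic = model_spec(
      ~ HD + I(HD^2) + RD + DUrb + DAg + Con + TD,
      name = "anthropogenic", set = "anthropogenic"),
    environmental = model_spec(
      ~ EVI + DW + Sal + Ele,
      name = "environmental", set = "environmental"),
    null = model_spec(~1, name = "null", set = "null")
  )
}

#' The seasonal conflict-probability candidate model set
#'
#' Eight hypotheses relating detection counts to the seasonal conflict
#' probability (`conflict_prob`), season (factor, spring reference) and
#' stratum: conflict x season, conflict + season, season, conflict +
#' strata, conflict x strata, conflict alone, strata alone, and the null.
#' Each hypothesis is specified under both nb1 and nb2 variance structures;
#' [fit_table2()] retains whichever fits with the lower AICc.
#'
#' @return Named list: each element has `$nb1` and `$nb2` [model_spec()]s.
#' @export
table2_model_set <- function() {
  forms <- list(
    "conflict x season" = ~ conflict_prob + season + conflict_prob:season,
    "conflict + season" = ~ conflict_prob + season,
    "season" = ~season,
    "conflict + strata" = ~ conflict_prob + stratum,
    "conflict x strata" = ~ conflict_prob + stratum + conflict_prob:stratum,
    "conflict" = ~conflict_prob,
    "strata" = ~stratum,
    "null" = ~1
  )
  purrr::imap(forms, function(f, nm) {
    list(nb1 = model_spec(f, family = "nb1", name = nm, set = nm),
         nb2 = model_spec(f, family = "nb2", name = nm, set = nm))
  })
}

#' Fit the seasonal candidate set under both variance structures
#'
#' Fits every hypothesis in [table2_model_set()] under nb1 and nb2 and
#' keeps, per hypothesis, the family with the lower AICc.
#'
#' @param data Site-month tibble with `conflict_prob`, `season`, `stratum`.
#' @param ... Passed to [fit_zinb()].
#' @return List of retained `btk_zinb` fits (one per hypothesis).
#' @export
fit_table2 <- function(data, ...) {
  purrr::map(table2_model_set(), function(pair) {
    f1 <- fit_zinb(data, pair$nb1, ...)
    f2 <- fit_zinb(data, pair$nb2, ...)
    if (f1$AICc <= f2$AICc) f1 else f2
  })
}
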