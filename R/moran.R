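#' Per-site averaged Pearson residuals
#'
#' Residual for each site-month is `(count - fitted mean) / sqrt(fitted
#' variance)` under the fitted zero-inflated NB model at the population
#' level (random intercept at its mean of zero), averaged within site.
#' These site means feed the spatial autocorrelation diagnostic.
#'
#' @param fit A `btk_zinb` fit.
#' @param data The site-month tibble the model was fitted to.
#' @return Tibble with `site_id` and `residual`.
#' @export
site_residuals <- function(fit, data) {
  stopifnot(inherits(fit, "btk_zinb"))
  design <- suppressMessages(build_design(fit$spec, data))
  p <- ncol(design$X)
  beta <- fit$par[seq_len(p)]
  mu <- exp(as.vector(design$X %*% beta) + design$offset)
  pi <- fit$zi_prob
  mean_y <- (1 - pi) * mu
  nb_var <- if (fit$spec$family == "nb2") {
    mu * (1 + mu / fit$dispersion)
  } else {
    mu * (1 + fit$dispersion)
  }
  # variance of the zero-inflated mixture
  var_y <- (1 - pi) * (nb_var + pi * mu^2)
  r <- (design$y - mean_y) / sqrt(var_y)
  tibble::tibble(site_id = design$site_levels[design$site + 1L],
                 residual = r) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(residual = mean(.data$residual), .groups = "drop")
}

#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of site values:
#' `I = (n / S0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2`, with expectation `-1/(n-1)` under no autocorrelation. The
#' p-value is one-sided for positive autocorrelation, from `n_perm` random
#' permutations of the values over the sites:
#' `p = (1 + #\{I_perm >= I_obs\}) / (n_perm + 1)`.
#'
#' @param values Numeric vector (non-constant).
#' @param coords Two-column matrix or data frame of site coordinates
#'   (planar metres); rows must be distinct.
#' @param scheme Spatial weights: `"idw"` (inverse Euclidean distance, zero
#'   diagonal, row-standardized; the default) or `"binary"` for
#'   nearest-neighbour adjacency within `neighbour_dist`.
#' @param neighbour_dist Adjacency distance for the binary scheme.
#' @param n_perm Number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param row_standardize Row-standardize the weight matrix (default TRUE).
#' @return Tibble of class `btk_moran`: `I`, `expected`, `p_value`,
#'   `n_perm`, `seed`, `scheme`.
#' @export
morans_i <- function(values, coords, scheme = c("idw", "binary"),
                     neighbour_dist = NULL, n_perm = 999, seed = 1,
                     row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(coords)
  n <- length(values)
  stopifnot(n >= 3, nrow(coords) == n)
  if (stats::sd(values) == 0) {
    stop("Moran's I undefined for constant values", call. = FALSE)
  }
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coordinates must be distinct", call. = FALSE)
  }
  w <- switch(scheme,
    idw = 1 / d,
    binary = (d <= (neighbour_dist %||% min(d[d > 0]) * 1.0001)) * 1
  )
  diag(w) <- 0
  if (row_standardize) w <- w / rowSums(w)

  stat <- function(x) {
    z <- x - mean(x)
    n / sum(w) * sum(w * tcrossprod(z)) / sum(z^2)
  }
  i_obs <- stat(values)
  i_perm <- with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(k) stat(sample(values)), numeric(1))
  })
  p <- (1 + sum(i_perm >= i_obs)) / (n_perm + 1)
  out <- tibble::tibble(
    I = i_obs, expected = -1 / (n - 1), p_value = p,
    n_perm = n_perm, seed = seed,
    scheme = paste0(scheme, if (row_standardize) " row-standardized")
  )
  class(out) <- c("btk_moran", class(out))
  attr(out, "permutations") <- i_perm
  out
}
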