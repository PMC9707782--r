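# Shared fixtures, built in code.

# Small zero-inflated NB mixed dataset with known truth, for likelihood and
# recovery checks.
make_zinb_data <- function(n_sites = 20, n_occ = 5, beta = c(-3, 0.5),
                           sigma = 0.7, theta = 1.2, pi = 0.2,
                           family = "nb2", seed = 42) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(site_id = sprintf("s%03d", seq_len(n_sites)),
                            occ = seq_len(n_occ))
    d$x1 <- stats::rnorm(nrow(d))
    d$effort <- sample(20:30, nrow(d), replace = TRUE)
    u <- stats::rnorm(n_sites, 0, sigma)
    names(u) <- sprintf("s%03d", seq_len(n_sites))
    mu <- exp(beta[1] + beta[2] * d$x1 + u[d$site_id] + log(d$effort))
    size <- if (family == "nb2") theta else mu / theta
    d$count <- ifelse(stats::runif(nrow(d)) < pi, 0L,
                      stats::rnbinom(nrow(d), size = size, mu = mu))
    d
  })
}

# Brute-force marginal negative log-likelihood by dense trapezoid
# integration over the random effect; the independent oracle for the
# quadrature.
trapezoid_nll <- function(par, design, family = "nb2", n_grid = 4001,
                          span = 8) {
  p <- ncol(design$X)
  beta <- par[seq_len(p)]
  sig <- exp(par[p + 1])
  disp <- exp(par[p + 2])
  pi <- stats::plogis(par[p + 3])
  eta <- as.vector(design$X %*% beta) + design$offset
  ug <- seq(-span * sig, span * sig, length.out = n_grid)
  du <- ug[2] - ug[1]
  ll <- 0
  for (s in unique(design$site)) {
    i <- design$site == s
    f <- vapply(ug, function(u) {
      mu <- exp(eta[i] + u)
      size <- if (family == "nb2") disp else mu / disp
      nb <- stats::dnbinom(design$y[i], size = size, mu = mu)
      sum(log(ifelse(design$y[i] == 0, pi + (1 - pi) * nb, (1 - pi) * nb))) +
        stats::dnorm(u, 0, sig, log = TRUE)
    }, numeric(1))
    m <- max(f)
    # trapezoid rule in the exp domain
    w <- exp(f - m)
    ll <- ll + m + log((sum(w) - (w[1] + w[n_grid]) / 2) * du)
  }
  -ll
}

# One default-size synthetic study, generated once per test run.
study_bundle <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) cache <<- generate_study(truth_config(seed = seed))
    cache
  }
})

# Minimal deployment calendar for count-only simulations (no timestamps).
flat_deployments <- function(strata_sizes = c(urban = 11, rural = 19,
                                              wild = 24),
                             months = format(seq(as.Date("2018-07-01"),
                                                 by = "month",
                                                 length.out = 13),
                                             "%Y-%m"),
                             effort = 25) {
  sites <- tibble::tibble(
    site_id = sprintf("S%03d", seq_len(sum(strata_sizes))),
    stratum = factor(rep(names(strata_sizes), strata_sizes),
                     levels = c("wild", "rural", "urban"))
  )
  tidyr::expand_grid(sites, month = months) |>
    dplyr::mutate(active_days = effort)
}
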