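#' Rank-abundance vector
#'
#' Positive counts sorted in decreasing order, with richness `S` and total
#' community size `J`.
#'
#' @param counts count vector (zeros dropped) or a single OTU-table row.
#' @return object of class `rank_abundance`: list with `abund`, `S`, `J`.
#' @export
rank_abundance <- function(counts) {
  x <- as.numeric(counts)
  x <- x[x > 0]
  if (any(x != round(x))) stop("counts must be integers")
  x <- sort(x, decreasing = TRUE)
  if (length(x) < 2L) stop("rank abundance needs at least 2 species")
  structure(list(abund = x, S = length(x), J = sum(x)),
            class = "rank_abundance")
}

as_rank_abundance <- function(ra) {
  if (inherits(ra, "rank_abundance")) ra else rank_abundance(ra)
}

sad_fit <- function(model, parameters, logLik, npar, converged, fitted) {
  structure(list(model = model, parameters = parameters, logLik = logLik,
                 npar = as.integer(npar), aic = 2 * npar - 2 * logLik,
                 converged = converged, fitted = fitted),
            class = "sad_fit")
}

#' @export
print.sad_fit <- function(x, ...) {
  cat(sprintf("%s fit: logLik %.3f, npar %d, AIC %.3f%s\n", x$model,
              x$logLik, x$npar, x$aic,
              if (!x$converged) " (not converged)" else ""))
  if (length(x$parameters))
    cat("  ", paste(names(x$parameters), signif(unlist(x$parameters), 5),
                    sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

pois_ll <- function(x, mu) sum(stats::dpois(x, mu, log = TRUE))

# Expected abundances of each classical model given parameters.
rad_expected <- function(model, r, S, J, par) {
  switch(model,
    brokenstick = (J / S) * rev(cumsum(1 / (S:1))),
    preemption = {
      a <- par$alpha
      J * a * (1 - a)^(r - 1) / (1 - (1 - a)^S)
    },
    lognormal = exp(par$mu + par$sigma * rev(qnorm(ppoints(S)))),
    zipf = J * par$c * r^par$gamma,
    mandelbrot = J * par$c * (r + par$beta)^par$gamma)
}

#' Fit a classical rank-abundance model
#'
#' Maximum likelihood under independent Poisson observations at each rank,
#' the convention of the standard rank-abundance fitting routines, so that
#' models with different parameter counts are comparable by AIC
#' (`AIC = 2 npar - 2 logLik`). Mean functions, with rank `r`, richness `S`
#' and community size `J`:
#' \describe{
#'   \item{brokenstick}{`(J/S) * sum_{k=r}^{S} 1/k`; no free parameters (the
#'     zero-parameter "null" model of rank-abundance comparisons).}
#'   \item{preemption}{`J * alpha (1-alpha)^(r-1)`, normalized over the `S`
#'     observed ranks; 1 parameter.}
#'   \item{lognormal}{`exp(mu + sigma * z_r)` with `z_r` the reversed normal
#'     quantiles of `ppoints(S)`; 2 parameters.}
#'   \item{zipf}{`J * c * r^gamma`; 2 parameters.}
#'   \item{mandelbrot}{`J * c * (r + beta)^gamma`; 3 parameters. The fit is
#'     profiled over `beta` and always evaluates `beta = 0`, so the Zipf
#'     model is exactly nested and `AIC(mandelbrot) <= AIC(zipf) + 2`.}
#' }
#'
#' @param ra [rank_abundance()] object (or a count vector).
#' @param model one of `"brokenstick"`, `"preemption"`, `"lognormal"`,
#'   `"zipf"`, `"mandelbrot"`.
#' @return a `sad_fit` object.
#' @export
fit_rad <- function(ra, model = c("brokenstick", "preemption", "lognormal",
                                  "zipf", "mandelbrot")) {
  model <- match.arg(model)
  ra <- as_rank_abundance(ra)
  x <- ra$abund; S <- ra$S; J <- ra$J; r <- seq_len(S)
  npar <- c(brokenstick = 0L, preemption = 1L, lognormal = 2L, zipf = 2L,
            mandelbrot = 3L)[[model]]
  if (S < npar + 1L) stop("richness too low to fit ", model)
  conv <- TRUE
  par <- list()
  if (model == "brokenstick") {
    mu <- rad_expected(model, r, S, J, par)
  } else if (model == "preemption") {
    nll <- function(a) -pois_ll(x, rad_expected("preemption", r, S, J,
                                                list(alpha = a)))
    op <- optimize(nll, c(1e-8, 1 - 1e-8))
    par <- list(alpha = op$minimum)
    mu <- rad_expected(model, r, S, J, par)
  } else if (model == "lognormal") {
    z <- rev(qnorm(ppoints(S)))
    fit <- glm(x ~ z, family = poisson(link = "log"))
    conv <- fit$converged
    par <- list(mu = unname(coef(fit)[1]), sigma = unname(coef(fit)[2]))
    mu <- fit$fitted.values
  } else if (model == "zipf") {
    fit <- glm(x ~ log(r), family = poisson(link = "log"))
    conv <- fit$converged
    par <- list(c = exp(unname(coef(fit)[1])) / J,
                gamma = unname(coef(fit)[2]))
    mu <- fit$fitted.values
  } else { # mandelbrot: profile the Poisson GLM over beta, beta = 0 included
    prof <- function(beta) {
      f <- tryCatch(glm(x ~ log(r + beta), family = poisson(link = "log")),
                    error = function(e) NULL, warning = function(w)
                      suppressWarnings(glm(x ~ log(r + beta),
                                           family = poisson(link = "log"))))
      if (is.null(f)) return(list(ll = -Inf, fit = NULL))
      list(ll = pois_ll(x, f$fitted.values), fit = f)
    }
    op <- optimize(function(t) -prof(exp(t) - 1)$ll,
                   c(log(0.1), log(1e5 + 1)))
    cand_beta <- c(0, exp(op$minimum) - 1)
    lls <- lapply(cand_beta, prof)
    best <- which.max(vapply(lls, `[[`, numeric(1), "ll"))
    beta <- cand_beta[best]
    fit <- lls[[best]]$fit
    conv <- fit$converged
    par <- list(c = exp(unname(coef(fit)[1])) / J, beta = beta,
                gamma = unname(coef(fit)[2]))
    mu <- fit$fitted.values
  }
  sad_fit(model, par, pois_ll(x, mu), npar, conv, as.numeric(mu))
}

# ---- zero-sum multinomial (neutral) likelihood -----------------------------

# Elementwise log(exp(a) + exp(b)), tolerating -Inf entries.
logaddexp <- function(a, b) {
  mx <- pmax(a, b)
  out <- mx + log1p(exp(pmin(a, b) - mx))
  out[is.infinite(mx) & mx < 0] <- -Inf
  out
}

# log unsigned Stirling numbers of the first kind, rows for the distinct
# abundances in `ns`; row n has entries a = 1..n.
log_stirling_rows <- function(ns) {
  ns <- sort(unique(ns))
  out <- vector("list", length(ns))
  names(out) <- as.character(ns)
  row <- 0 # log s(1,1) = log 1
  if (1 %in% ns) out[["1"]] <- row
  nmax <- max(ns)
  if (nmax >= 2) {
    for (n in 2:nmax) {
      # s(n, a) = (n-1) s(n-1, a) + s(n-1, a-1)
      row <- logaddexp(log(n - 1) + c(row, -Inf), c(-Inf, row))
      if (n %in% ns) out[[as.character(n)]] <- row
    }
  }
  out
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# Row-wise logsumexp of a matrix (rows may contain -Inf).
row_logsumexp <- function(M) {
  mx <- do.call(pmax, as.data.frame(M))
  out <- mx + log(rowSums(exp(M - mx)))
  out[!is.finite(mx)] <- -Inf
  out
}

#' Etienne coefficient table for the neutral sampling formula
#'
#' `log K(D, A)` for `A = S..J`: the combinatorial coefficients of the
#' dispersal-limited neutral sampling formula, where `A` is the number of
#' immigration events (ancestors) behind the `J` sampled individuals. For
#' each species the per-ancestor coefficients
#' `s(n_i, a) * (a-1)! / (n_i-1)!` (unsigned Stirling numbers of the first
#' kind) are convolved across species in log space, which keeps the
#' astronomically scaled terms finite.
#'
#' @param abund positive integer abundance vector.
#' @return numeric vector of `log K(D, A)` indexed `A = S..J`.
#' @export
etienne_logK <- function(abund) {
  abund <- as.integer(abund[abund > 0])
  S <- length(abund); J <- sum(abund)
  lrows <- log_stirling_rows(abund)
  n_single <- sum(abund == 1L)           # each contributes exactly one ancestor
  cur <- 0                               # log K over A-offset grid
  for (n in abund[abund > 1L]) {
    lk <- lrows[[as.character(n)]] + lgamma(seq_len(n)) - lgamma(n)
    L <- length(cur)
    M <- matrix(-Inf, L + n - 1L, n)
    for (a in seq_len(n)) M[a:(a + L - 1L), a] <- cur + lk[a]
    cur <- row_logsumexp(M)
  }
  # cur is indexed by (A - #species entering the convolution); singletons
  # shift A by one each.
  out <- cur
  names(out) <- seq(S, S + length(out) - 1L)
  stopifnot(length(out) == J - S + 1L)
  out
}

#' Neutral (zero-sum multinomial) log-likelihood
#'
#' Log probability of an abundance configuration under the dispersal-limited
#' neutral sampling formula with biodiversity number `theta` and immigration
#' probability `m` (`I = m (J-1) / (1-m)` immigration parameter). In the
#' limit `m -> 1` this approaches the Ewens sampling formula.
#'
#' @param abund positive integer abundances.
#' @param theta fundamental biodiversity number (> 0).
#' @param m immigration probability in (0, 1].
#' @param logK optional precomputed [etienne_logK()] table (reused across
#'   likelihood evaluations during optimization).
#' @return scalar log-likelihood.
#' @export
zsm_loglik <- function(abund, theta, m, logK = NULL) {
  abund <- as.integer(abund[abund > 0])
  S <- length(abund); J <- sum(abund)
  if (theta <= 0 || m <= 0 || m > 1) return(-Inf)
  if (is.null(logK)) logK <- etienne_logK(abund)
  phi <- table(abund)
  const <- lgamma(J + 1) - sum(log(abund)) - sum(lgamma(as.numeric(phi) + 1))
  if (m == 1) # Ewens limit
    return(const + S * log(theta) + lgamma(theta) - lgamma(theta + J))
  I <- m * (J - 1) / (1 - m)
  A <- as.integer(names(logK))
  terms <- logK + A * log(I) - (lgamma(theta + A) - lgamma(theta))
  const + S * log(theta) - (lgamma(I + J) - lgamma(I)) + logsumexp(terms)
}

#' Fit the neutral zero-sum multinomial by maximum likelihood
#'
#' Maximizes [zsm_loglik()] over `(theta, m)`: a coarse grid on
#' `(log theta, logit m)` followed by Nelder-Mead refinement. The
#' coefficient table is computed once per dataset and is `O(J^2)`, so `J`
#' is capped (default 20,000); subsample larger communities first, e.g.
#' with [rarefy_table()].
#'
#' @param ra [rank_abundance()] object or count vector.
#' @param j_cap refuse communities larger than this.
#' @return a `sad_fit` with parameters `theta` and `m` (`npar = 2`).
#' @export
fit_zsm <- function(ra, j_cap = 20000L) {
  ra <- as_rank_abundance(ra)
  if (ra$J > j_cap)
    stop("J = ", ra$J, " exceeds cap ", j_cap, "; subsample first")
  if (ra$S == ra$J)
    warning("all species are singletons; theta is at a boundary")
  x <- ra$abund
  logK <- etienne_logK(x)
  obj <- function(p) -zsm_loglik(x, exp(p[1]), stats::plogis(p[2]), logK)
  grid <- expand.grid(lt = log(ra$S * c(0.2, 0.5, 1, 2, 5)),
                      lm = stats::qlogis(c(0.01, 0.05, 0.2, 0.5, 0.9, 0.99)))
  vals <- apply(grid, 1, obj)
  st <- as.numeric(grid[which.min(vals), ])
  op <- optim(st, obj, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-10))
  theta <- exp(op$par[1]); m <- stats::plogis(op$par[2])
  sad_fit("zsm", list(theta = theta, m = m), -op$value, 2L,
          op$convergence == 0, NULL)
}

#' Fit and rank all rank-abundance models by AIC
#'
#' Fits the five classical models plus (optionally) the neutral zero-sum
#' multinomial, and ranks them by AIC (ties broken toward fewer
#' parameters). Individual model failures are recorded and the comparison
#' proceeds over the successful fits.
#'
#' @param ra [rank_abundance()] or count vector.
#' @param models character vector of models to fit.
#' @param j_cap passed to [fit_zsm()].
#' @return data.frame with columns `model`, `npar`, `logLik`, `aic`,
#'   `delta_aic`, `rank`, `converged`, ordered best-first; the full fits are
#'   in `attr(, "fits")`.
#' @export
compare_models <- function(ra, models = c("zsm", "brokenstick", "preemption",
                                          "lognormal", "zipf", "mandelbrot"),
                           j_cap = 20000L) {
  ra <- as_rank_abundance(ra)
  fits <- list()
  for (mdl in models) {
    fits[[mdl]] <- tryCatch(
      if (mdl == "zsm") fit_zsm(ra, j_cap) else fit_rad(ra, mdl),
      error = function(e) {
        log_msg("model ", mdl, " failed: ", conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  fits <- fits[ok]
  if (!length(fits)) stop("all model fits failed")
  tab <- data.frame(model = names(fits),
                    npar = vapply(fits, `[[`, integer(1), "npar"),
                    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
                    aic = vapply(fits, `[[`, numeric(1), "aic"),
                    converged = vapply(fits, `[[`, logical(1), "converged"),
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(tab$aic, tab$npar)
  tab <- tab[ord, ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Sample a local community under neutral dynamics
#'
#' Exact sequential construction of a dispersal-limited neutral sample: each
#' new individual is an immigrant with probability `I / (I + j - 1)`
#' (`I = m (J-1)/(1-m)`); immigrants take species according to an Ewens urn
#' with parameter `theta` over immigration events, and non-immigrants copy
#' a uniformly chosen earlier local individual. The resulting abundance
#' configuration follows the zero-sum multinomial, making this the
#' generating counterpart of [fit_zsm()].
#'
#' @param J community size.
#' @param theta fundamental biodiversity number.
#' @param m immigration probability in (0, 1].
#' @param seed integer seed.
#' @return integer abundance vector (one entry per species, unordered).
#' @export
rzsm <- function(J, theta, m, seed = 1L) {
  set.seed(as.integer(seed))
  I <- if (m >= 1) Inf else m * (J - 1) / (1 - m)
  species <- integer(J)     # species id per local individual
  imm_species <- integer(0) # species id per immigration event
  n_species <- 0L
  for (j in seq_len(J)) {
    immigrant <- j == 1L || is.infinite(I) || runif(1) < I / (I + j - 1)
    if (immigrant) {
      k <- length(imm_species) + 1L
      if (k == 1L || runif(1) < theta / (theta + k - 1)) {
        n_species <- n_species + 1L
        sp <- n_species
      } else {
        sp <- imm_species[sample.int(k - 1L, 1L)]
      }
      imm_species <- c(imm_species, sp)
    } else {
      sp <- species[sample.int(j - 1L, 1L)]
    }
    species[j] <- sp
  }
  tabulate(species, nbins = n_species)
}
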