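# Skew-t distribution (Azzalini parameterization) and finite mixtures.
#
# Fate probabilities for a lineage span orders of magnitude and are strongly
# skewed on the log scale; a two- or three-component skew-t mixture on
# log10 fates separates the "on-trajectory" cells (the component with the
# largest location) from background.

#' Skew-t density and random deviates
#'
#' Azzalini-type skew-t: location `xi`, scale `omega`, slant `alpha`,
#' degrees of freedom `nu`. `alpha = 0` recovers the scaled/shifted Student
#' t; `nu = Inf` the skew-normal.
#'
#' @param x Numeric vector of quantiles.
#' @param xi,omega,alpha,nu Location, scale (>0), slant, df (>0).
#' @param log Return log-density?
#' @return `dskewt`: density values; `rskewt`: random deviates.
#' @export
dskewt <- function(x, xi = 0, omega = 1, alpha = 0, nu = 10, log = FALSE) {
  z <- (x - xi) / omega
  w <- alpha * z * sqrt((nu + 1) / (nu + z^2))
  lf <- log(2) - log(omega) + dt(z, nu, log = TRUE) +
    pt(w, nu + 1, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dskewt
#' @param n Number of deviates.
#' @export
rskewt <- function(n, xi = 0, omega = 1, alpha = 0, nu = 10) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  sn <- delta * abs(u0) + sqrt(1 - delta^2) * u1
  v <- rchisq(n, nu) / nu
  xi + omega * sn / sqrt(v)
}

# Parameter packing: theta = (logit-weights[2..K], then per component
# xi, log omega, alpha, eta) with nu = 2 + 98 * plogis(eta), bounding the
# df in (2, 100).
#' @noRd
st_unpack <- function(par, K) {
  lw <- c(0, par[seq_len(K - 1)])
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  comp <- matrix(par[K:length(par)], nrow = 4)
  list(w = w, xi = comp[1, ], s = comp[2, ], omega = exp(comp[2, ]),
       alpha = comp[3, ], eta = comp[4, ], nu = 2 + 98 * plogis(comp[4, ]))
}

# Negative log-likelihood and analytic gradient (df direction by finite
# difference). Returns nll with gradient attribute.
#' @noRd
st_mix_nll_grad <- function(par, x, K, grad = TRUE) {
  th <- st_unpack(par, K)
  n <- length(x)
  lcomp <- matrix(0, n, K)
  zs <- gs <- Bs <- vector("list", K)
  for (k in seq_len(K)) {
    z <- (x - th$xi[k]) / th$omega[k]
    nu <- th$nu[k]
    g <- sqrt((nu + 1) / (nu + z^2))
    q <- th$alpha[k] * z * g
    ldt <- dt(z, nu, log = TRUE)
    lpt <- pt(q, nu + 1, log.p = TRUE)
    lcomp[, k] <- log(th$w[k]) + log(2) - log(th$omega[k]) + ldt + lpt
    if (grad) {
      zs[[k]] <- z
      gs[[k]] <- g
      Bs[[k]] <- exp(dt(q, nu + 1, log = TRUE) - lpt)
    }
  }
  mx <- lcomp[cbind(seq_len(n), max.col(lcomp, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(lcomp - mx)))
  nll <- -sum(lse)
  if (!grad) return(nll)

  r <- exp(lcomp - lse)                      # responsibilities n x K
  gr <- numeric(length(par))
  if (K > 1) gr[seq_len(K - 1)] <- -(colSums(r)[-1] - n * th$w[-1])
  h <- 1e-4
  for (k in seq_len(K)) {
    z <- zs[[k]]; g <- gs[[k]]; B <- Bs[[k]]
    nu <- th$nu[k]; a <- th$alpha[k]; om <- th$omega[k]
    A <- -(nu + 1) * z / (nu + z^2)
    dq_dz <- a * sqrt(nu + 1) * nu * (nu + z^2)^(-1.5)
    dlf_dz <- A + B * dq_dz
    rk <- r[, k]
    base <- (K - 1) + 4 * (k - 1)
    gr[base + 1] <- -sum(rk * dlf_dz * (-1 / om))          # xi
    gr[base + 2] <- -sum(rk * (-1 - z * dlf_dz))           # log omega
    gr[base + 3] <- -sum(rk * B * z * g)                   # alpha
    # df (via eta), forward difference on the component log-density
    lf0 <- lcomp[, k] - log(th$w[k])
    lf_p <- dskewt(x, th$xi[k], om, a, 2 + 98 * plogis(th$eta[k] + h),
                   log = TRUE)
    gr[base + 4] <- -sum(rk * (lf_p - lf0) / h)
  }
  attr(nll, "gradient") <- gr
  nll
}

#' Fit a K-component skew-t mixture by maximum likelihood
#'
#' Direct numerical maximization of the mixture log-likelihood (quasi-Newton
#' with an analytic gradient; the df coordinate uses a finite difference),
#' with `n_restarts` randomized starting points. Restart passes run a few
#' iterations on a subsample; the best start is then polished on the full
#' data. Degrees of freedom are bounded in (2, 100). If every start fails, a
#' two-component Gaussian mixture (mclust) is fitted instead and flagged via
#' `downgraded = TRUE`.
#'
#' @param x Numeric data vector.
#' @param K Number of components (2 or 3 in normal use).
#' @param n_restarts Randomized starts.
#' @param seed Integer seed for the starts.
#' @return List: `weights`, `xi`, `omega`, `alpha`, `nu`, `loglik`, `bic`,
#'   `posterior` (n x K responsibilities), `cluster` (max-posterior
#'   assignment), `top_component` (index with largest `xi`), `converged`,
#'   `downgraded`.
#' @export
fit_skewt_mixture <- function(x, K, n_restarts = 10, seed = 1) {
  n <- length(x)
  if (n < 5 * K)
    stop_cosicc("too few observations for the requested mixture", "design")
  qs <- quantile(x, probs = seq_len(K) / (K + 1), names = FALSE)
  sx <- sd(x)
  xs <- if (n > 500) with_seed(substream_seed(seed, 999L),
                               x[sample.int(n, 500)]) else x
  starts <- with_seed(seed, lapply(seq_len(n_restarts), function(r) {
    xi0 <- qs + rnorm(K, 0, sx / 4)
    c(rep(0, K - 1),
      rbind(xi0,
            log(sx / K) + rnorm(K, 0, 0.3),
            rnorm(K, 0, 1.5),
            qlogis(0.06) + rnorm(K, 0, 0.7)))
  }))
  # objective and gradient share one evaluation when called at the same point
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par, data) {
    key <- if (identical(data, x)) "full" else "sub"
    if (!identical(cache[[paste0("par_", key)]], par)) {
      cache[[paste0("val_", key)]] <- st_mix_nll_grad(par, data, K,
                                                      grad = TRUE)
      cache[[paste0("par_", key)]] <- par
    }
    cache[[paste0("val_", key)]]
  }
  objective <- function(par, data) as.numeric(eval_at(par, data))
  gradient <- function(par, data) attr(eval_at(par, data), "gradient")
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      nlminb(st, objective, gradient, data = xs,
             control = list(iter.max = 20, trace = 0)),
      error = function(e) NULL)
    if (!is.null(o) && is.finite(o$objective) &&
        (is.null(best) || o$objective / length(xs) <
           best$objective / length(xs)))
      best <- o
  }
  if (is.null(best)) return(gaussian_fallback(x, seed))
  o <- tryCatch(
    nlminb(best$par, objective, gradient, data = x,
           control = list(iter.max = 400, trace = 0)),
    error = function(e) NULL)
  if (is.null(o) || !is.finite(o$objective))
    return(gaussian_fallback(x, seed))

  th <- st_unpack(o$par, K)
  lcomp <- vapply(seq_len(K), function(k)
    log(th$w[k]) + dskewt(x, th$xi[k], th$omega[k], th$alpha[k], th$nu[k],
                          log = TRUE), numeric(n))
  mx <- lcomp[cbind(seq_len(n), max.col(lcomp, ties.method = "first"))]
  lse <- mx + log(rowSums(exp(lcomp - mx)))
  post <- exp(lcomp - lse)
  npar <- 5 * K - 1
  list(weights = th$w, xi = th$xi, omega = th$omega, alpha = th$alpha,
       nu = th$nu, loglik = -o$objective,
       bic = 2 * o$objective + npar * log(n),
       posterior = post, cluster = max.col(post),
       top_component = which.max(th$xi),
       converged = o$convergence == 0 || o$iterations >= 1,
       downgraded = FALSE)
}

#' @noRd
gaussian_fallback <- function(x, seed) {
  fit <- with_seed(seed, mclust::Mclust(x, G = 2, modelNames = "V",
                                        verbose = FALSE))
  post <- fit$z
  mu <- fit$parameters$mean
  list(weights = fit$parameters$pro, xi = as.numeric(mu),
       omega = sqrt(as.numeric(fit$parameters$variance$sigmasq)),
       alpha = rep(0, 2), nu = rep(Inf, 2), loglik = fit$loglik,
       bic = -fit$bic, posterior = post, cluster = max.col(post),
       top_component = which.max(mu), converged = TRUE, downgraded = TRUE)
}

#' Choose between 2- and 3-component skew-t mixtures by BIC
#'
#' @inheritParams fit_skewt_mixture
#' @param Ks Candidate component counts.
#' @return The winning [fit_skewt_mixture()] fit, with `K` and `bic_all`
#'   fields added.
#' @export
select_skewt_mixture <- function(x, Ks = c(2, 3), n_restarts = 10, seed = 1) {
  fits <- lapply(seq_along(Ks), function(i)
    fit_skewt_mixture(x, Ks[i], n_restarts = n_restarts,
                      seed = substream_seed(seed, i)))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  best <- which.min(bics)
  out <- fits[[best]]
  out$K <- Ks[best]
  out$bic_all <- setNames(bics, paste0("K", Ks))
  out
}
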