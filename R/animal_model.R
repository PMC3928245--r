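#' Fit the weighted animal model by REML
#'
#' First step of the two-step association analysis: fit
#' \deqn{y = 1\mu + u + e, \qquad
#'       \mathrm{var}(u) = G\sigma^2_a, \quad
#'       \mathrm{var}(e) = D\sigma^2_e, \quad D = \mathrm{diag}(1/w_i)}
#' to the pseudo-phenotypes `y` (typically deregressed EBVs) with `G`
#' a genomic relationship matrix and `w` the deregression information
#' weights, by restricted maximum likelihood. The likelihood is
#' profiled over the single ratio \eqn{\delta = \sigma^2_e/\sigma^2_a}
#' after simultaneous diagonalization of `(G, D)`: with
#' \eqn{D^{-1/2} G D^{-1/2} = U \Lambda U^\top} and the rotation
#' \eqn{T = U^\top D^{-1/2}}, the transformed data have diagonal
#' covariance \eqn{\sigma^2_a(\Lambda + \delta I)}, so each likelihood
#' evaluation is O(n) and the optimum is found by a one-dimensional
#' search on \eqn{\log\delta}.
#'
#' A non-positive-semidefinite `G` is repaired by a `1e-6` ridge with a
#' warning. If all transformed eigenvalues are (numerically) equal the
#' two variance components are not separately identifiable (e.g.
#' `G = I` with equal weights); only their sum is, and the fit carries
#' `identifiable = FALSE` with a warning. An optimum at the edge of
#' the search interval is reported as a boundary fit
#' (\eqn{\hat h^2 \in \{0, 1\}}) with a warning.
#'
#' @param y numeric vector of pseudo-phenotypes.
#' @param G n x n relationship matrix.
#' @param weights positive information weights (length n or scalar);
#'   residual variances are \eqn{\sigma^2_e / w_i}.
#' @param ids optional individual ids (defaults to `rownames(G)`).
#' @param fixed optional `c(sigma2_a =, sigma2_e =)` to skip REML and
#'   build the model object at fixed variance components.
#' @param interval search interval for \eqn{\log\delta}.
#' @return An object of class `"animal_model"`: variance components
#'   `sigma2_a`, `sigma2_e`, heritability `h2`, intercept `mu`,
#'   restricted log-likelihood `loglik`, plus the spectral transform
#'   reused by [snp_scan()].
#' @seealso [snp_scan()], [compute_grm()], [deregress()]
#' @export
fit_animal_model <- function(y, G, weights = 1, ids = NULL, fixed = NULL,
                             interval = c(-25, 25)) {
  n <- length(y)
  if (!is.matrix(G) || nrow(G) != n || ncol(G) != n)
    stop("G must be an n x n matrix matching length(y)")
  weights <- rep_len(weights, n)
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive and finite")
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("ind", seq_len(n))

  d <- sqrt(weights)                      # D^{-1/2} = diag(sqrt(w))
  Gs <- d * t(d * G)                      # diag(d) G diag(d)
  Gs <- (Gs + t(Gs)) / 2
  eig <- eigen(Gs, symmetric = TRUE)
  lam <- eig$values
  if (min(lam) < -1e-8 * max(abs(lam))) {
    warning("G is not positive semidefinite; adding a 1e-6 ridge")
    lam <- lam + 1e-6
  }
  lam <- pmax(lam, 0)
  identifiable <- (max(lam) - min(lam)) > 1e-8 * max(1, max(lam))
  if (!identifiable)
    warning("variance components not separately identifiable: ",
            "the transformed relationship matrix is a multiple of the ",
            "identity, so only sigma2_a + sigma2_e is estimable")

  Tm <- t(eig$vectors) * rep(d, each = n)  # U' diag(d)
  ty <- drop(Tm %*% y)
  tones <- drop(Tm %*% rep(1, n))

  reml_pieces <- function(logdelta) {
    h <- lam + exp(logdelta)
    wi <- 1 / h
    sxx <- sum(wi * tones^2)
    mu <- sum(wi * tones * ty) / sxx
    r <- ty - tones * mu
    q <- sum(wi * r^2)
    s2a <- q / (n - 1)
    ll <- -0.5 * ((n - 1) * (log(2 * pi * s2a) + 1) + sum(log(h)) + log(sxx))
    list(ll = ll, mu = mu, s2a = s2a, sxx = sxx)
  }

  boundary <- FALSE
  if (!is.null(fixed)) {
    s2a <- unname(fixed[["sigma2_a"]]); s2e <- unname(fixed[["sigma2_e"]])
    if (s2a <= 0) s2a <- 1e-12
    logdelta <- log(s2e / s2a)
    pc <- reml_pieces(logdelta)
    mu <- pc$mu; loglik <- pc$ll
  } else {
    opt <- stats::optimize(function(ld) reml_pieces(ld)$ll,
                           interval = interval, maximum = TRUE, tol = 1e-9)
    logdelta <- opt$maximum
    if (min(abs(logdelta - interval)) < 1e-3) {
      boundary <- TRUE
      warning("REML optimum at the boundary: h2 estimated at ",
              if (logdelta > 0) "0" else "1")
    }
    pc <- reml_pieces(logdelta)
    s2a <- pc$s2a
    s2e <- s2a * exp(logdelta)
    mu <- pc$mu
    loglik <- pc$ll
  }

  structure(list(sigma2_a = s2a, sigma2_e = s2e,
                 h2 = s2a / (s2a + s2e), mu = mu, loglik = loglik,
                 n = n, ids = ids, weights = weights,
                 eigenvalues = lam, transform = Tm, ty = ty, tones = tones,
                 y = y, G = G, var_y = stats::var(y),
                 identifiable = identifiable, boundary = boundary,
                 fixed = !is.null(fixed)),
            class = "animal_model")
}

# diagonal covariance of the transformed data, in trait units^2
model_tvar <- function(object)
  object$sigma2_a * object$eigenvalues + object$sigma2_e

#' @export
print.animal_model <- function(x, ...) {
  cat("Weighted animal model (REML",
      if (x$fixed) ", fixed components" else "", ")\n", sep = "")
  cat(sprintf("  n = %d individuals\n", x$n))
  cat(sprintf("  sigma2_a = %.4g   sigma2_e = %.4g   h2 = %.3f\n",
              x$sigma2_a, x$sigma2_e, x$h2))
  cat(sprintf("  intercept mu = %.4g   restricted logLik = %.2f\n",
              x$mu, x$loglik))
  if (!x$identifiable)
    cat("  NOTE: variance components not separately identifiable\n")
  if (x$boundary) cat("  NOTE: estimate at the parameter boundary\n")
  invisible(x)
}

#' @export
summary.animal_model <- function(object, ...) {
  v <- model_tvar(object)
  sxx <- sum(object$tones^2 / v)
  out <- list(model = object, mu_se = sqrt(1 / sxx))
  class(out) <- "summary.animal_model"
  out
}

#' @export
print.summary.animal_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  s.e.(mu) = %.4g\n", x$mu_se))
  invisible(x)
}

#' @export
coef.animal_model <- function(object, ...)
  c(mu = object$mu)

#' @export
logLik.animal_model <- function(object, ...) {
  val <- object$loglik
  attr(val, "df") <- 3  # mu, sigma2_a, sigma2_e
  attr(val, "nobs") <- object$n
  class(val) <- "logLik"
  val
}

#' @export
vcov.animal_model <- function(object, ...) {
  v <- model_tvar(object)
  matrix(1 / sum(object$tones^2 / v), 1, 1,
         dimnames = list("mu", "mu"))
}

#' Best linear unbiased predictions of the additive values
#'
#' @param object a fitted `"animal_model"`.
#' @param ... unused.
#' @return numeric vector of BLUPs, one per individual.
#' @export
ranef_animal_model <- function(object, ...) {
  v <- model_tvar(object)
  r <- object$ty - object$tones * object$mu
  # u_hat = s2a G V^{-1} (y - mu) = s2a G diag(d) U (r_t / v_t)
  d <- sqrt(object$weights)
  back <- crossprod(object$transform, r / v)  # diag(d) U (r/v)
  drop(object$sigma2_a * object$G %*% back)
}

#' @export
fitted.animal_model <- function(object, ...)
  object$mu + ranef_animal_model(object)

#' @export
residuals.animal_model <- function(object, ...)
  object$y - fitted(object)

#' @export
simulate.animal_model <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- model_tvar(object)
  # back-transform T^{-1} = D^{1/2} U applied to independent normals with
  # the transformed variances reproduces var(y) = sigma2_a G + sigma2_e D
  out <- replicate(nsim, {
    z <- stats::rnorm(object$n, 0, sqrt(v))
    object$mu + drop(crossprod(object$transform, z)) / object$weights
  }, simplify = FALSE)
  as.data.frame(stats::setNames(out, paste0("sim_", seq_len(nsim))))
}
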