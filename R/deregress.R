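#' Deregress EBVs without parent information
#'
#' Removes the shrinkage from an estimated breeding value by dividing
#' it by its reliability, and attaches the information weight used to
#' model the heterogeneous residual variance of deregressed proofs:
#' \deqn{w = \frac{1 - h^2}{(c + (1 - r^{*2})/r^{*2})\, h^2}}
#' where \eqn{r^{*2}} is the effective reliability of the deregressed
#' value (equal to the input reliability in this no-parent case) and
#' `c` the fraction of genetic variance not captured by the markers.
#'
#' Reliabilities of exactly 1 would make the weight unbounded; they
#' are capped at `1 - 1e-6` with a warning.
#'
#' @param ebv numeric vector of EBVs.
#' @param r2 reliabilities in (0, 1\]; values of 1 are capped.
#' @param h2 trait heritability in (0, 1\].
#' @param c fraction of genetic variance not accounted for by markers,
#'   in \[0, 1).
#' @return data.frame with columns `debv`, `weight`, `r2_star`.
#' @export
deregress_simple <- function(ebv, r2, h2, c = 0) {
  if (any(r2 <= 0 | r2 > 1)) stop("reliabilities must lie in (0, 1]")
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (c < 0 || c >= 1) stop("c must lie in [0, 1)")
  if (any(r2 >= 1)) {
    warning("reliabilities of 1 capped at 1 - 1e-6")
    r2 <- pmin(r2, 1 - 1e-6)
  }
  debv <- ebv / r2
  w <- (1 - h2) / ((c + (1 - r2) / r2) * h2)
  data.frame(debv = debv, weight = w, r2_star = r2)
}

#' Deregress EBVs removing the parent-average contribution
#'
#' Full two-equation deregression for an animal with parent (average)
#' information. The method reconstructs the 2x2 mixed-model-equation
#' system in the unknowns (parent average, individual) implied by the
#' stated reliabilities and the variance ratio
#' \eqn{\lambda = (1-h^2)/h^2}: with
#' \eqn{\alpha = 1/(0.5 - r^2_{PA})} and
#' \eqn{\delta = (0.5 - r^2_{PA})/(1 - r^2_i)}, the individual's
#' information content is
#' \deqn{Z'Z_{PA} = \lambda(0.5\alpha - 4) + 0.5\lambda
#'       \sqrt{\alpha^2 + 16/\delta}, \quad
#'       Z'Z_i = \delta Z'Z_{PA} + 2\lambda(2\delta - 1).}
#' The right-hand side for the individual is recovered from the known
#' solutions, the deregressed proof is that right-hand side divided by
#' \eqn{Z'Z_i}, the effective reliability is
#' \eqn{r^{*2} = 1 - \lambda/(Z'Z_i + \lambda)}, and the weight follows
#' the same formula as [deregress_simple()].
#'
#' When the parent-average reliability is zero the parents are
#' effectively unknown and the parent-average equation drops from the
#' system; the remaining 1x1 system reduces exactly to
#' [deregress_simple()], which is what this function then returns. A
#' degenerate system (non-finite or non-positive \eqn{Z'Z_i} or
#' \eqn{r^{*2}}) also falls back to [deregress_simple()] with a
#' warning.
#'
#' @param ebv numeric vector of individual EBVs.
#' @param r2 individual reliabilities in (0, 1).
#' @param pa_ebv parent-average EBVs (e.g. `(sire + dam)/2`).
#' @param r2_pa parent-average reliabilities in \[0, 0.5); the usual
#'   construction is `(r2_sire + r2_dam)/4`.
#' @param h2,c as in [deregress_simple()].
#' @return data.frame with columns `debv`, `weight`, `r2_star`.
#' @export
deregress_garrick <- function(ebv, r2, pa_ebv = 0, r2_pa = 0, h2, c = 0) {
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (c < 0 || c >= 1) stop("c must lie in [0, 1)")
  k <- max(length(ebv), length(r2), length(pa_ebv), length(r2_pa))
  ebv <- rep_len(ebv, k); r2 <- rep_len(r2, k)
  pa_ebv <- rep_len(pa_ebv, k); r2_pa <- rep_len(r2_pa, k)
  if (any(r2 <= 0 | r2 >= 1)) stop("individual reliabilities must lie in (0, 1)")
  if (any(r2_pa < 0 | r2_pa >= 0.5))
    stop("parent-average reliabilities must lie in [0, 0.5)")
  if (any(r2_pa >= r2))
    stop("individual reliability must exceed the parent-average reliability")
  lambda <- (1 - h2) / h2
  if (lambda == 0) lambda <- 1e-8  # h2 = 1: no shrinkage to undo
  alpha <- 1 / (0.5 - r2_pa)
  delta <- (0.5 - r2_pa) / (1 - r2)
  zz_pa <- lambda * (0.5 * alpha - 4) + 0.5 * lambda * sqrt(alpha^2 + 16 / delta)
  zz_i <- delta * zz_pa + 2 * lambda * (2 * delta - 1)
  rhs_i <- -2 * lambda * pa_ebv + (zz_i + 2 * lambda) * ebv
  debv <- rhs_i / zz_i
  r2_star <- 1 - lambda / (zz_i + lambda)

  bad <- !is.finite(zz_i) | zz_i <= 0 | !is.finite(r2_star) | r2_star <= 0
  no_pa <- r2_pa <= 0
  if (any(bad & !no_pa))
    warning(sum(bad & !no_pa),
            " record(s) with a degenerate deregression system; ",
            "falling back to simple deregression")
  use_simple <- bad | no_pa
  out <- data.frame(debv = debv, weight = NA_real_, r2_star = r2_star)
  if (any(use_simple)) {
    simple <- deregress_simple(ebv[use_simple], r2[use_simple], h2, c)
    out$debv[use_simple] <- simple$debv
    out$r2_star[use_simple] <- simple$r2_star
    out$weight[use_simple] <- simple$weight
  }
  full <- !use_simple
  if (any(full))
    out$weight[full] <- (1 - h2) /
      ((c + (1 - out$r2_star[full]) / out$r2_star[full]) * h2)
  out
}

#' Deregress an EBV table into pseudo-phenotypes
#'
#' Applies [deregress_garrick()] when the table carries sire/dam EBV
#' information (`sire_ebv`/`sire_r2`, optionally `dam_ebv`/`dam_r2`),
#' and [deregress_simple()] otherwise.
#'
#' @param ebv data.frame with columns `id`, `ebv`, `reliability` and
#'   optional parent columns.
#' @param h2 trait heritability used for the variance ratio and weights.
#' @param c fraction of genetic variance not captured by markers.
#' @return data.frame `id`, `debv`, `weight`, `r2_star`.
#' @export
deregress <- function(ebv, h2, c = 0) {
  stopifnot(all(c("id", "ebv", "reliability") %in% names(ebv)))
  if (all(c("sire_ebv", "sire_r2") %in% names(ebv))) {
    dam_ebv <- if ("dam_ebv" %in% names(ebv)) ebv$dam_ebv else 0
    dam_r2 <- if ("dam_r2" %in% names(ebv)) ebv$dam_r2 else 0
    pa_ebv <- (ebv$sire_ebv + dam_ebv) / 2
    r2_pa <- (ebv$sire_r2 + dam_r2) / 4
    res <- deregress_garrick(ebv$ebv, ebv$reliability, pa_ebv, r2_pa, h2, c)
  } else {
    res <- deregress_simple(ebv$ebv, ebv$reliability, h2, c)
  }
  cbind(data.frame(id = ebv$id), res)
}
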