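#' Brute-force constrained maximum-entropy oracle
#'
#' Directly maximizes the noise entropy `sum_x P(x) H2(p_x)` over the
#' per-state conditional spike probabilities `p_x`, subject to the moment
#' constraints `sum_x P(x) p_x f(x) = <y f(x)>`, using a generic augmented
#' Lagrangian optimizer on per-state logits. No logistic-in-features
#' parameterization is involved, so the result is an independent check that
#' the logistic MNE form attains the constrained maximum: on any enumerable
#' ensemble the oracle table and a converged [fit_mne()] model must agree
#' per state.
#'
#' @param moments an `mne_moments` tibble (from [empirical_moments()]); its
#'   attached feature map defines the constraint set.
#' @param ensemble an [input_ensemble()] (or data frame; uniform weights
#'   assumed). Duplicate states are aggregated. At most 4096 distinct states.
#' @param tol constraint-residual threshold below which the solution is
#'   accepted; residuals above `infeasible_tol` raise an infeasibility error
#'   naming the worst-violated constraint.
#' @param infeasible_tol see `tol`.
#' @return a tibble of class `maxent_table`: distinct input states with
#'   columns `.weight` and `p` (the entropy-maximizing conditional
#'   probability of output 1), with the final constraint residuals in
#'   attribute `residuals`.
#' @export
#' @examples
#' xor <- gate_dataset(named_gate("XOR"))
#' m <- empirical_moments(xor, feature_map(2, 1, binary_inputs = TRUE))
#' maxent_oracle(m, xor)  # all conditionals 1/2
maxent_oracle <- function(moments, ensemble, tol = 1e-10,
                          infeasible_tol = 1e-8) {
  fm <- moments_fm(moments)
  X <- ens_inputs(ensemble, fm$n_inputs)
  w <- ens_weights(ensemble)
  key <- apply(X, 1L, paste, collapse = "\r")
  agg <- rowsum(w, key, reorder = FALSE)
  Xs <- X[!duplicated(key), , drop = FALSE]
  Ps <- as.numeric(agg[match(key[!duplicated(key)], rownames(agg))])
  S <- nrow(Xs)
  if (S > 4096L) abort("too many distinct states to enumerate (> 4096)")

  Fmat <- feature_matrix(fm, Xs)          # S x M
  m_target <- moments$value
  PF <- Fmat * Ps                         # rows scaled by state probability

  residual <- function(p) drop(crossprod(PF, p)) - m_target
  u <- rep(0, S)
  lambda <- rep(0, length(m_target))
  rho <- 10
  res <- residual(stats::plogis(u))
  for (outer in 1:60) {
    obj <- function(u) {
      p <- stats::plogis(u)
      g <- residual(p)
      # negative noise entropy (nats) + augmented Lagrangian terms
      ent <- sum(Ps * ent_nats(p))
      -ent + sum(lambda * g) + 0.5 * rho * sum(g^2)
    }
    grd <- function(u) {
      p <- stats::plogis(u)
      g <- residual(p)
      dl_dp <- -Ps * dent_nats(p) + drop(PF %*% (lambda + rho * g))
      dl_dp * p * (1 - p)
    }
    opt <- optim(u, obj, grd, method = "BFGS",
                 control = list(maxit = 1000, reltol = 1e-15))
    u <- opt$par
    res <- residual(stats::plogis(u))
    if (max(abs(res)) < tol) break
    lambda <- lambda + rho * res
    rho <- min(rho * 8, 1e12)
  }
  if (max(abs(res)) > infeasible_tol) {
    worst <- which.max(abs(res))
    abort(sprintf(
      "constraints appear infeasible: `%s` violated by %.3g",
      moments$term[worst], abs(res[worst])))
  }
  # polish: the constraints are linear in p, so ascend the entropy inside
  # their null space with damped Newton steps (the augmented Lagrangian can
  # leave flat feasible directions slightly unconverged)
  p <- stats::plogis(u)
  dec <- svd(PF, nu = S)
  rank <- sum(dec$d > max(dec$d) * 1e-12)
  if (rank < S) {
    Z <- dec$u[, (rank + 1L):S, drop = FALSE]
    for (it in 1:100) {
      grad <- drop(crossprod(Z, Ps * dent_nats(p)))
      if (max(abs(grad)) < 1e-12) break
      curv <- crossprod(Z, Z * (-Ps / pmax(p * (1 - p), PROB_EPS)))
      dv <- drop(solve(curv, -grad))
      step <- drop(Z %*% dv)
      alpha <- 1
      ent0 <- sum(Ps * ent_nats(p))
      repeat {
        p_new <- p + alpha * step
        if (all(p_new > 0 & p_new < 1) &&
            sum(Ps * ent_nats(p_new)) >= ent0) break
        alpha <- alpha / 2
        if (alpha < 1e-12) { p_new <- p; break }
      }
      if (identical(p_new, p)) break
      p <- p_new
    }
    res <- residual(p)
  }
  u <- stats::qlogis(pmin(pmax(p, PROB_EPS), 1 - PROB_EPS))
  out <- as_tibble(as.data.frame(Xs))
  out$.weight <- Ps
  out$p <- stats::plogis(u)
  attr(out, "residuals") <- setNames(res, moments$term)
  class(out) <- c("maxent_table", class(out))
  out
}

# binary entropy and its derivative in nats, safe at the boundary
ent_nats <- function(p) {
  p <- clamp01(p)
  -p * log(p) - (1 - p) * log(1 - p)
}
dent_nats <- function(p) {
  p <- clamp01(p)
  log((1 - p) / p)
}
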