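# Limited-memory quasi-Newton steppers.
#
# L-BFGS (positive-definite, for constrained minimization) and L-SR1
# (indefinite-capable, for saddle-point search), both seeded with the signed
# inverse-diagonal Hessian preconditioner and capped by a max-norm trust step.
# No line search: a fixed maximum step size plays the role of a trust region.

#' Signed inverse-diagonal preconditioner
#'
#' Inverts a diagonal curvature model elementwise, flooring the magnitude at
#' \code{floor} while preserving the sign.  Negative elements make the
#' quasi-Newton step go uphill along those directions, which is what drives a
#' saddle search.
#'
#' @param d diagonal Hessian vector (Ha).
#' @param floor smallest magnitude retained before inversion (Ha).
#' @return vector of signed inverse elements.
#' @export
make_preconditioner <- function(d, floor = 1e-3) {
  s <- ifelse(d < 0, -1, 1)
  s / pmax(abs(d), floor)
}

#' Cap a step at a maximum-norm trust radius
#'
#' If the max-norm of the step exceeds \code{max_step} the whole step is
#' rescaled uniformly (direction preserved); otherwise it is unchanged.
#'
#' @param step numeric step vector.
#' @param max_step positive cap on the max-norm.
#' @return the (possibly rescaled) step.
#' @export
clip_step <- function(step, max_step) {
  if (max_step <= 0) stop("max_step must be positive")
  m <- max(abs(step))
  if (m > max_step) step * (max_step / m) else step
}

#' Create a limited-memory quasi-Newton state
#'
#' @param precond signed inverse-diagonal initial Hessian (from
#'   \code{\link{make_preconditioner}}).
#' @param max_step max-norm step cap.
#' @param memory number of curvature pairs retained.
#' @param skip_tol relative tolerance of the SR1 skip rule.
#' @return an object of class \code{qn_state}.
#' @export
qn_state <- function(precond, max_step, memory = 20L, skip_tol = 1e-8) {
  stopifnot(max_step > 0, memory >= 1)
  structure(list(precond = precond, max_step = max_step,
                 memory = as.integer(memory), skip_tol = skip_tol,
                 S = list(), Y = list(), iteration = 0L),
            class = "qn_state")
}

#' Record a curvature pair
#'
#' Appends the step \code{s} and gradient difference \code{y} to the memory,
#' dropping the oldest pair beyond the memory length.  For L-BFGS, pairs
#' violating the positive-curvature condition are discarded at application
#' time; for L-SR1 the standard denominator skip rule is applied when the
#' inverse-Hessian operator is formed.
#'
#' @param qn a \code{qn_state}.
#' @param s step vector taken.
#' @param y gradient difference across the step.
#' @return the updated \code{qn_state}.
#' @export
qn_update <- function(qn, s, y) {
  qn$S <- c(qn$S, list(s))
  qn$Y <- c(qn$Y, list(y))
  if (length(qn$S) > qn$memory) {
    qn$S <- qn$S[-1]
    qn$Y <- qn$Y[-1]
  }
  qn$iteration <- qn$iteration + 1L
  qn
}

#' L-BFGS quasi-Newton step
#'
#' Two-loop recursion with the absolute value of the preconditioner as
#' initial inverse Hessian (minimization must not follow negative curvature),
#' returning the capped step \eqn{-H g}.
#'
#' @param qn a \code{qn_state}.
#' @param g gradient vector.
#' @return step vector.
#' @export
lbfgs_step <- function(qn, g) {
  p0 <- abs(qn$precond)
  n <- length(qn$S)
  q <- g
  alpha <- numeric(n)
  rho <- numeric(n)
  keep <- logical(n)
  if (n > 0) {
    for (k in n:1) {
      sy <- sum(qn$S[[k]] * qn$Y[[k]])
      keep[k] <- sy > 1e-12 * sqrt(sum(qn$S[[k]]^2) * sum(qn$Y[[k]]^2))
      if (!keep[k]) next
      rho[k] <- 1 / sy
      alpha[k] <- rho[k] * sum(qn$S[[k]] * q)
      q <- q - alpha[k] * qn$Y[[k]]
    }
  }
  r <- p0 * q
  if (n > 0) {
    for (k in seq_len(n)) {
      if (!keep[k]) next
      beta <- rho[k] * sum(qn$Y[[k]] * r)
      r <- r + qn$S[[k]] * (alpha[k] - beta)
    }
  }
  clip_step(-r, qn$max_step)
}

# build the limited-memory SR1 inverse-Hessian operator as a closure
lsr1_operator <- function(qn) {
  p0 <- qn$precond
  us <- list(); ds <- numeric(0)
  apply_H <- function(v) {
    r <- p0 * v
    if (length(us)) for (k in seq_along(us))
      r <- r + us[[k]] * (sum(us[[k]] * v) / ds[k])
    r
  }
  for (k in seq_along(qn$S)) {
    y <- qn$Y[[k]]
    u <- qn$S[[k]] - apply_H(y)
    d <- sum(u * y)
    if (abs(d) >= qn$skip_tol * sqrt(sum(u^2) * sum(y^2))) {
      us[[length(us) + 1]] <- u
      ds <- c(ds, d)
    }
  }
  apply_H
}

#' L-SR1 quasi-Newton step
#'
#' Symmetric rank-1 update of the inverse Hessian, seeded with the signed
#' preconditioner; the approximation can be indefinite, so steps go uphill
#' along negative-curvature directions as required to converge on saddle
#' points.  Updates whose denominator is nearly singular are skipped.
#'
#' @param qn a \code{qn_state}.
#' @param g gradient vector.
#' @return step vector (capped).
#' @export
lsr1_step <- function(qn, g) {
  H <- lsr1_operator(qn)
  clip_step(-H(g), qn$max_step)
}
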