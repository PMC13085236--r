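# S3 methods for fitted solutions.

#' @export
print.frdo_solution <- function(x, ...) {
  lab <- switch(x$method, ground = "Ground-state direct minimization",
                frdo = "Freeze-and-release direct optimization",
                domom = "Direct optimization with maximum-overlap control")
  cat(lab, "\n")
  cat(sprintf("  total energy: %.8f Ha\n", x$energy))
  if (!is.null(x$excitation_eV) && x$method != "ground")
    cat(sprintf("  excitation energy: %.4f eV\n", x$excitation_eV))
  cat(sprintf("  residual: %.3g eV^2/electron (%s)\n", x$residual,
              if (x$converged) "converged" else "NOT converged"))
  it <- x$iterations
  if (!is.null(it$constrained))
    cat(sprintf("  iterations: %d constrained + %d released = %d\n",
                it$constrained, it$released, it$total))
  else cat(sprintf("  iterations: %d\n", it$total))
  if (!is.null(x$diagnostics) && !is.null(x$diagnostics$d_CT))
    cat(sprintf("  d_CT = %.3f Bohr, q_CT = %.3f e, spin contamination = %.3f e\n",
                x$diagnostics$d_CT, x$diagnostics$q_CT,
                x$diagnostics$spin_contamination))
  invisible(x)
}

#' @export
summary.frdo_solution <- function(object, ...) {
  print(object)
  cat("\nOrbital energies (Ha):\n")
  tab <- data.frame(orbital = seq_len(object$state$M),
                    eps_up = object$eps_up, f_up = object$f_up,
                    eps_dn = object$eps_dn, f_dn = object$f_dn)
  print(tab, row.names = FALSE, digits = 6)
  invisible(object)
}

#' Orbital coefficients of a fitted solution
#'
#' @param object a \code{frdo_solution}.
#' @param ... unused.
#' @return list with coefficient matrices \code{C_up}, \code{C_dn}.
#' @export
coef.frdo_solution <- function(object, ...) {
  list(C_up = object$state$C_up, C_dn = object$state$C_dn)
}

#' Per-iteration residuals of the optimization trace
#'
#' @param object a \code{frdo_solution}.
#' @param ... unused.
#' @return numeric vector of squared residuals (eV^2/electron) per
#'   iteration.
#' @export
residuals.frdo_solution <- function(object, ...) {
  object$trace$residual
}

#' Convergence plot of a fitted solution
#'
#' Plots energy and squared residual against iteration, with the phase
#' boundary (constrained vs released) marked for freeze-and-release runs.
#'
#' @param x a \code{frdo_solution}.
#' @param ... passed to \code{plot}.
#' @export
plot.frdo_solution <- function(x, ...) {
  tr <- x$trace
  it <- seq_len(nrow(tr))
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  plot(it, tr$energy, type = "b", xlab = "iteration", ylab = "energy (Ha)",
       main = x$method, ...)
  nb <- sum(tr$phase == tr$phase[1])
  if (length(unique(tr$phase)) > 1)
    graphics::abline(v = nb + 0.5, lty = 2, col = "grey40")
  plot(it, pmax(tr$residual, 1e-16), type = "b", log = "y",
       xlab = "iteration", ylab = "residual (eV^2/e)", ...)
  if (length(unique(tr$phase)) > 1)
    graphics::abline(v = nb + 0.5, lty = 2, col = "grey40")
  invisible(x)
}
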