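# Powell's conjugate-direction minimizer (derivative-free).
#
# Classic scheme: sweep line minimizations along a direction set, replace
# the direction of largest decrease by the net sweep displacement. Line
# minimization uses stats::optimize() on an adaptively expanded bracket.
# For the convex least-squares objectives fitted here it converges to the
# unique optimum in a few sweeps; the closed-form solution serves as an
# independent cross-check in the fitting code.

.line_min <- function(f, x, u, span0 = 1) {
  g <- function(t) f(x + t * u)
  span <- span0
  for (i in 1:60) {
    opt <- stats::optimize(g, c(-span, span), tol = 1e-12 * max(1, span))
    if (abs(opt$minimum) < 0.9 * span) return(opt)
    span <- span * 4
  }
  opt
}

powell_minimize <- function(f, x0, tol = 1e-12, maxit = 200) {
  n <- length(x0)
  dirs <- diag(n)
  x <- x0
  fx <- f(x)
  for (it in seq_len(maxit)) {
    x_start <- x
    f_start <- fx
    biggest <- 0
    ibig <- 1
    for (i in seq_len(n)) {
      ls <- .line_min(f, x, dirs[, i])
      dec <- fx - ls$objective
      if (dec > biggest) { biggest <- dec; ibig <- i }
      x <- x + ls$minimum * dirs[, i]
      fx <- ls$objective
    }
    if (2 * (f_start - fx) <= tol * (abs(f_start) + abs(fx) + 1e-300))
      break
    # replace the best-decrease direction with the sweep displacement
    u <- x - x_start
    if (sqrt(sum(u^2)) > 0) {
      dirs[, ibig] <- dirs[, n]
      dirs[, n] <- u / sqrt(sum(u^2))
      ls <- .line_min(f, x, dirs[, n])
      x <- x + ls$minimum * dirs[, n]
      fx <- ls$objective
    }
  }
  list(par = x, value = fx, iterations = it)
}
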