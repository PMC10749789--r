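# Finite-difference gradient checking for the autodiff core.
#
# build: function(tape, params) -> scalar loss node, where params is a named
# list of numeric arrays wrapped with ag_param inside build.
num_grad <- function(build, params, eps = 1e-5) {
  out <- lapply(params, function(p) array(0, dim(p)))
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      fu <- histoexpr:::ag_val(build(histoexpr:::ag_tape(), up))[1]
      fd <- histoexpr:::ag_val(build(histoexpr:::ag_tape(), dn))[1]
      out[[nm]][i] <- (fu - fd) / (2 * eps)
    }
  }
  out
}

analytic_grad <- function(build, params) {
  tp <- histoexpr:::ag_tape()
  loss <- build(tp, params)
  grads <- histoexpr:::ag_backward(tp, loss)
  histoexpr:::ag_param_grads(tp, grads)
}

expect_grads_match <- function(build, params, tol = 1e-6) {
  ga <- analytic_grad(build, params)
  gn <- num_grad(build, params)
  for (nm in names(params)) {
    expect_equal(as.vector(ga[[nm]]), as.vector(gn[[nm]]),
                 tolerance = tol, label = paste("grad of", nm))
  }
}
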