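# Session-cached coupled desk-scale runs shared by the acceptance tests.
# The expensive FSI simulations are executed once, on first use.

acceptance_cache <- new.env(parent = emptyenv())

healthy_estimation <- function() {
  if (!is.null(acceptance_cache$healthy)) return(acceptance_cache$healthy)
  set.seed(42)
  bm <- build_model(default_config("desk-healthy"))
  ed <- run_diastole(bm$model, bm$protocol)
  target_esv <- 0.70 * ed$volume
  # runner caching the final state of each candidate so the estimation
  # run also provides the end-systolic fields
  states <- list()
  runner <- function(ts) {
    m <- bm$model
    m$T_scale <- ts
    st <- run_systole(m, ed, bm$protocol)
    states[[sprintf("%.8g", ts)]] <<- st
    st$volume
  }
  fit <- bisect_parameter(runner, target_esv, lower = 1, upper = 8,
                          tol = 0.05, max_iter = 20)
  es <- states[[sprintf("%.8g", fit$par)]]
  acceptance_cache$healthy <- list(model = bm$model, protocol = bm$protocol,
                                   ed = ed, es = es, fit = fit,
                                   target_esv = target_esv)
  acceptance_cache$healthy
}

mi_contraction <- function() {
  if (!is.null(acceptance_cache$mi)) return(acceptance_cache$mi)
  set.seed(43)
  bm <- build_model(default_config("desk-mi"))
  ed <- run_diastole(bm$model, bm$protocol)
  es <- run_systole(bm$model, ed, bm$protocol)
  acceptance_cache$mi <- list(model = bm$model, protocol = bm$protocol,
                              ed = ed, es = es)
  acceptance_cache$mi
}
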