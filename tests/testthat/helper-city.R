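# Build a city_state with an arbitrary composition, bypassing the entry
# process, so metric formulas can be checked on hand-constructed cities.
make_state <- function(res_count, mig_count) {
  stopifnot(length(res_count) == length(mig_count))
  M <- length(res_count)
  st <- new.env(parent = emptyenv())
  st$M <- M
  st$n_res <- sum(res_count)
  st$P0 <- sum(res_count)
  st$res_cell <- rep(seq_len(M), res_count)
  st$res_count <- as.integer(res_count)
  st$mig_cell <- rep(seq_len(M), mig_count)
  st$mig_count <- as.integer(mig_count)
  st$ever_breached <- logical(st$n_res)
  st$first_breach <- rep(NA_integer_, st$n_res)
  st$t <- 0L
  st$entry_log <- list()
  class(st) <- "city_state"
  st
}

# Small, fast scenario used across engine tests.
small_params <- function(...) {
  args <- utils::modifyList(
    list(g = 0.05, M = 4L, n_residents = 40L, n_iterations = 20L),
    list(...))
  do.call(model_params, args)
}
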