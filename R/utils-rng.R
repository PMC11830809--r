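# Local, restorable RNG scoping so generators and seeded subsampling never
# perturb the caller's random stream.

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Deterministic per-reactor seed stream
#'
#' Derives a 32-bit seed from a master seed and a reactor label so that
#' generated datasets are reproducible and independent of reactor order.
#'
#' @param master_seed integer master seed.
#' @param reactor_id reactor label.
#' @param offset small integer separating the substreams (trace, chemistry,
#'   biology) of one reactor.
#' @return Integer seed in \[0, 2^31 - 1).
#' @export
reactor_seed <- function(master_seed, reactor_id, offset = 0) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(as.character(reactor_id))) h <- (h * 31 + c) %% m
  as.integer((h * 31 + (master_seed %% m) * 7919 + offset) %% m)
}
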