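#' Derive a child seed from a master seed
#'
#' Counter-based seed splitting: every randomized stage of the pipeline draws
#' its own seed as `derive_seed(master_seed, index)` with a distinct integer
#' index, so records and training runs are mutually independent yet fully
#' reproducible from one master seed. The result is always in
#' `[1, 2^31 - 2]`, safe for `set.seed()`.
#'
#' @param master_seed integer master seed.
#' @param index non-negative integer counter.
#' @return a single integer seed.
#' @export
derive_seed <- function(master_seed, index) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (as.double(master_seed) %% m) + as.double(index) * 2654435761
  x <- x %% m
  x <- (x * 48271 + 3) %% m
  x <- (x * 16807 + 11) %% m
  s <- as.integer(x)
  if (s < 1L) s <- s + 2147483645L
  s
}
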