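#' Derive a reproducible sub-seed
#'
#' Counter-based seed splitter: maps a master seed and a stream counter to an
#' integer seed in `[1, 2^31 - 2]`. Every stochastic operation in the package
#' draws its seed through this function, so runs are independent of execution
#' order and a whole experiment is reproducible from one master seed.
#'
#' @param master integer master seed.
#' @param counter non-negative integer stream index.
#' @return a single integer seed.
#' @export
split_seed <- function(master, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647  # 2^31 - 1, prime
  # Lehmer-style mixing; all intermediates stay below 2^53 so doubles are exact
  x <- (abs(master) %% m)
  x <- (x * 48271 + 11) %% m
  x <- (x + (counter %% m) * 69621) %% m
  x <- (x * 16807 + 33) %% m
  as.integer(x %% (m - 2) + 1)
}
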