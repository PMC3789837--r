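#' Mean microtubule length from a serial-section reconstruction
#'
#' Estimates the mean microtubule (MT) length from serial-section
#' electron-microscopy reconstructions as `L = 2 * N * a / T`, where `N`
#' is the average number of MTs per section (dimensionless), `a` the total
#' reconstructed length (micrometres) and `T` the number of MT endpoints
#' observed. Each observed endpoint terminates one MT at one end, and each
#' MT has two ends; hence the factor 2.
#'
#' @param N Mean MT count per section (`>= 0`).
#' @param a Total reconstructed length in micrometres (`> 0`).
#' @param T Number of MT endpoints observed (`> 0`; with no endpoint the
#'   length is undefined and a hard error is raised).
#' @return Mean MT length in micrometres. Vectorised.
#' @export
#' @examples
#' mt_mean_length(10, 5, 20) # 5
mt_mean_length <- function(N, a, T) {
  if (any(is.na(N)) || any(N < 0)) abort("N must be non-negative.")
  if (any(is.na(a)) || any(a <= 0)) abort("a must be positive (micrometres).")
  if (any(is.na(T)) || any(T < 0)) abort("T must be non-negative.")
  if (any(T == 0)) {
    abort("T == 0: no microtubule endpoints observed; mean length undefined.")
  }
  2 * N * a / T
}

#' Append mean MT lengths to a reconstruction table
#'
#' @param df Data frame with columns `N` (mean MTs/section), `a`
#'   (reconstructed length, micrometres) and `T` (endpoints observed).
#' @return The input as a tibble with an added `L` column (micrometres).
#' @export
mt_length_table <- function(df) {
  check_columns(df, c("N", "a", "T"))
  out <- as_tibble(df)
  out$L <- mt_mean_length(out$N, out$a, out$T)
  out
}
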