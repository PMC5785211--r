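#' Hill activation function
#'
#' Fractional promoter activity contributed by an activating regulator at
#' normalized level `u`: `f = (u/K)^H / (1 + (u/K)^H)`, where `K` is the
#' coefficient of activation (the regulator level at half-maximal activity)
#' and `H` the Hill coefficient (steepness).
#'
#' Degenerate cases are resolved by the limits that keep the fitting
#' objective continuous on the parameter box: `H = 0` gives `f = 0.5`
#' everywhere (via the `0^0 = 1` convention); `K = 0` with `u > 0` gives
#' `f = 1`; `u = K = 0` gives `f = 0.5`.
#'
#' @param u nonnegative regulator level (normalized expression units);
#'   vectorized.
#' @param K coefficient of activation, in `[0, 1]`.
#' @param H Hill coefficient, in `[0, 7]`.
#' @return numeric vector of activities in `[0, 1]`.
#' @seealso [hill_repression()]
#' @examples
#' hill_activation(0.5, K = 0.5, H = 2)  # 0.5 at the half-activation point
#' hill_activation(1.0, K = 0.5, H = 1)  # 2/3
#' @export
hill_activation <- function(u, K, H) {
  check_hill_args(u, K, H)
  if (H == 0) return(rep(0.5, length(u)))
  f <- numeric(length(u))
  if (K == 0) {
    # limit K -> 0+: full activation wherever regulator is present
    f[u > 0] <- 1
    f[u == 0] <- 0.5   # u = K = 0 limit
    return(f)
  }
  r <- (u / K)^H
  ifelse(is.infinite(r), 1, r / (1 + r))
}

#' Hill repression function
#'
#' Fractional promoter activity under a repressing regulator:
#' `f = 1 / (1 + (u/K)^H)`, with `K` the coefficient of repression.
#' Degenerate conventions mirror [hill_activation()] so that
#' `hill_activation(u, K, H) + hill_repression(u, K, H) == 1`.
#'
#' @inheritParams hill_activation
#' @return numeric vector of activities in `[0, 1]`.
#' @export
hill_repression <- function(u, K, H) {
  check_hill_args(u, K, H)
  1 - hill_activation(u, K, H)
}

check_hill_args <- function(u, K, H) {
  if (any(!is.finite(u)) || any(u < 0))
    stop("regulator level 'u' must be finite and nonnegative", call. = FALSE)
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K > 1)
    stop("'K' must be a single value in [0, 1]", call. = FALSE)
  if (!is.numeric(H) || length(H) != 1L || H < 0 || H > 7)
    stop("'H' must be a single value in [0, 7]", call. = FALSE)
  invisible(TRUE)
}
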