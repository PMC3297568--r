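#' Hill activation functions
#'
#' `hill()` is the plain Hill function `x^n / (x^n + K^n)` used for
#' concentration-valued regulators (bacteria, neutrophil pools). `hill_norm()`
#' is the normalized HillCube variant, rescaled so that a unit-interval
#' regulator at its maximal value 1 yields exactly 1:
#' `hill(x) / hill(1) = x^n (1 + K^n) / (x^n + K^n)`. Using the normalized
#' form for unit-interval regulators keeps the PI/AI/damage states closed in
#' \[0, 1\] under the dynamics.
#'
#' @param x Regulator level, `x >= 0` (clamped at 0 for tiny negative solver
#'   undershoot; for `hill_norm` also clamped at 1).
#' @param K Half-maximal constant, `K > 0`.
#' @param n Hill coefficient, `n >= 1` (the model fixes `n = 3` everywhere).
#' @return Value in `[0, 1)` for `hill`, `[0, 1]` for `hill_norm`; monotone
#'   increasing in `x`.
#' @examples
#' hill(0, 0.5)        # 0
#' hill(0.5, 0.5)      # 0.5 (half-maximal by construction)
#' hill_norm(1, 0.5)   # 1 (normalized at regulator value 1)
#' @export
hill <- function(x, K, n = 3) {
  if (any(K <= 0)) stop("hill: K must be positive", call. = FALSE)
  if (n < 1) stop("hill: Hill coefficient must be >= 1", call. = FALSE)
  if (any(x < -1e-8)) stop("hill: negative regulator level", call. = FALSE)
  x <- pmax(x, 0)
  xn <- x^n
  xn / (xn + K^n)
}

#' @rdname hill
#' @export
hill_norm <- function(x, K, n = 3) {
  if (any(K <= 0)) stop("hill_norm: K must be positive", call. = FALSE)
  if (any(x < -1e-8)) stop("hill_norm: negative regulator level", call. = FALSE)
  x <- pmin(pmax(x, 0), 1)
  xn <- x^n
  Kn <- K^n
  xn * (1 + Kn) / (xn + Kn)
}
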