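#' Safeguarded Newton root finding on a bracket
#'
#' Finds the root of a monotone scalar function on `[lo, hi]` using Newton's
#' method with bisection as fallback: any Newton step that leaves the current
#' bracket, or that is attempted where the derivative magnitude falls below
#' `deriv_floor`, is replaced by a bisection step, so convergence is
#' guaranteed for monotone `f`. This is the solver used for the cubic
#' equations of the two competition models.
#'
#' @param f function of one numeric argument.
#' @param lo,hi bracket endpoints with `f(lo)` and `f(hi)` of opposite sign
#'   (either endpoint may itself be a root).
#' @param df optional derivative function; when `NULL` a central finite
#'   difference is used.
#' @param rel_tol relative tolerance on the root variable (default 1e-12).
#' @param max_iter iteration cap (default 200); exceeding it is an error,
#'   never a silent return.
#' @param deriv_floor derivative magnitudes below this trigger a bisection
#'   step instead of a Newton step.
#' @return The root, a single number within the bracket.
#' @examples
#' solve_bracketed_root(function(x) x^3 - 2 * x - 5, 2, 3)
#' @export
solve_bracketed_root <- function(f, lo, hi, df = NULL, rel_tol = 1e-12,
                                 max_iter = 200L, deriv_floor = 1e-300) {
  stopifnot(is.function(f), is.finite(lo), is.finite(hi), lo < hi)
  flo <- f(lo)
  fhi <- f(hi)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) {
    abort("f(lo) and f(hi) must have opposite signs (no sign change on bracket).",
          class = "bindsim_error_bracket")
  }
  # orient so that f(lo) < 0 < f(hi) conceptually via the sign of flo
  s <- sign(fhi)                      # +1 if increasing across bracket
  if (is.null(df)) {
    df <- function(x) {
      h <- max(abs(x), 1) * 1e-7
      (f(x + h) - f(x - h)) / (2 * h)
    }
  }
  x <- (lo + hi) / 2
  for (iter in seq_len(max_iter)) {
    fx <- f(x)
    if (fx == 0) return(x)
    if (s * fx > 0) hi <- x else lo <- x
    d <- df(x)
    x_new <- if (is.finite(d) && abs(d) > deriv_floor) x - fx / d else NA_real_
    if (!is.finite(x_new) || x_new <= lo || x_new >= hi) {
      x_new <- (lo + hi) / 2          # bisection fallback
    }
    if (abs(x_new - x) <= rel_tol * max(abs(x_new), .Machine$double.xmin)) {
      return(x_new)
    }
    x <- x_new
  }
  abort(sprintf("root search did not converge within %d iterations.", max_iter),
        class = "bindsim_error_numerical_failure")
}

# Vectorized safeguarded Newton for the cubic free-species equations.
# Solves, elementwise, root of  x * (1 + ca/(Ka+x) + cb/(Kb+x)) - total = 0
# on (0, total]; used by sweeps and fitting where many points are solved at
# once. Same tolerances as solve_bracketed_root.
free_root_vec <- function(total, ca, Ka, cb, Kb, rel_tol = 1e-12,
                          max_iter = 200L) {
  n <- length(total)
  ca <- rep_len(ca, n); Ka <- rep_len(Ka, n)
  cb <- rep_len(cb, n); Kb <- rep_len(Kb, n)
  out <- numeric(n)
  live <- total > 0
  if (!any(live)) return(out)
  lo <- numeric(n)
  hi <- total
  x <- total / 2
  done <- !live
  for (iter in seq_len(max_iter)) {
    idx <- which(!done)
    if (length(idx) == 0L) break
    xi <- x[idx]
    fa <- ca[idx] / (Ka[idx] + xi)
    fb <- cb[idx] / (Kb[idx] + xi)
    fx <- xi * (1 + fa + fb) - total[idx]
    up <- fx > 0
    hi[idx][up] <- xi[up]
    lo[idx][!up] <- xi[!up]
    d <- 1 + fa * Ka[idx] / (Ka[idx] + xi) + fb * Kb[idx] / (Kb[idx] + xi)
    xn <- xi - fx / d
    bad <- !is.finite(xn) | xn < lo[idx] | xn > hi[idx]
    xn[bad] <- (lo[idx][bad] + hi[idx][bad]) / 2
    # an exact root stays put; otherwise converge on the step size
    xn[fx == 0] <- xi[fx == 0]
    conv <- fx == 0 |
      abs(xn - xi) <= rel_tol * pmax(abs(xn), .Machine$double.xmin)
    x[idx] <- xn
    done[idx] <- conv
  }
  if (!all(done)) {
    abort("cubic solver did not converge within the iteration cap.",
          class = "bindsim_error_numerical_failure")
  }
  out[live] <- x[live]
  out
}
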