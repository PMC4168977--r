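#' Dynamic-programming model of optimal cluster division
#'
#' Settling selection happens after `T` division-plus-growth steps. A
#' cluster of `n` cells that reaches selection survives with probability
#' `s(n)` (non-decreasing: larger clusters sink faster). Each step a
#' cluster of size `n` first splits into parts `a` and `n - a`
#' (`a = 0` means no division), then each part grows by the map `g`
#' (default doubling, clipped at `n_max`). Maximal reproductive output
#' `V(n, t)` counts either surviving clusters (`fitness_mode = "clusters"`,
#' terminal value `s(n)`) or surviving cells (`"cells"`, terminal value
#' `n * s(n)`).
#'
#' @param s Survival function of cluster size; values in `[0, 1]`,
#'   non-decreasing over `1..n_max`.
#' @param g Growth map; must satisfy `g(n) >= n`. Default `2 * n`.
#' @param T Horizon: number of division+growth steps before selection.
#' @param n_max Largest tabulated size; `g` is clipped here (a boundary
#'   artifact, so keep the sizes of interest well below it).
#' @param fitness_mode `"clusters"` or `"cells"`.
#' @return An object of class `dp_model`.
#' @export
dp_model <- function(s, g = function(n) 2 * n, T = 5, n_max = 256,
                     fitness_mode = c("clusters", "cells")) {
  fitness_mode <- match.arg(fitness_mode)
  stopifnot(T >= 1, n_max >= 2)
  sv <- s(1:n_max)
  if (any(!is.finite(sv)) || any(sv < 0) || any(sv > 1)) {
    stop("survival function must take values in [0, 1] over 1..n_max")
  }
  if (any(diff(sv) < -1e-12)) stop("survival function must be non-decreasing")
  gv <- g(1:n_max)
  if (any(gv < 1:n_max)) stop("growth map must satisfy g(n) >= n")
  structure(list(s = s, g = g, T = as.integer(T), n_max = as.integer(n_max),
                 fitness_mode = fitness_mode,
                 s_tab = sv, g_tab = pmin(as.integer(round(gv)), n_max)),
            class = "dp_model")
}

#' Solve the division model by backward recursion
#'
#' Tabulates `V(n, t)` for all `1 <= n <= n_max`, `0 <= t <= T` using the
#' recursion `V(n, t) = max_a [ V(g(a), t+1) + V(g(n-a), t+1) ]` over
#' `a in {0, 1, ..., floor(n/2)}`, with the `a = 0` term reducing to the
#' undivided lineage `V(g(n), t+1)`. Ties are broken toward the smallest
#' part `a`, so "no division" wins over an equivalent split.
#'
#' @param model A [dp_model()].
#' @return An object of class `division_policy`: value matrix `V`
#'   (`n_max` rows, `T + 1` columns for `t = 0..T`), integer matrix `split`
#'   of the optimal smaller parts, and `smaller_fraction = split / n`.
#' @examples
#' m <- dp_model(function(n) pmin(1, sqrt(n / 10)), T = 1, n_max = 16)
#' solve_policy(m)$split[4, "t0"] # 2: halving beats growing undivided
#' @export
solve_policy <- function(model) {
  stopifnot(inherits(model, "dp_model"))
  n_max <- model$n_max; T <- model$T
  g <- model$g_tab
  V <- matrix(0, nrow = n_max, ncol = T + 1,
              dimnames = list(NULL, paste0("t", 0:T)))
  split <- matrix(0L, nrow = n_max, ncol = T + 1,
                  dimnames = list(NULL, paste0("t", 0:T)))
  V[, T + 1] <- if (model$fitness_mode == "clusters") model$s_tab
                else (1:n_max) * model$s_tab
  for (tt in T:1) {
    Vnext <- V[, tt + 1]
    for (n in 1:n_max) {
      a <- 0:(n %/% 2)
      val <- ifelse(a == 0, Vnext[g[n]], Vnext[g[pmax(a, 1)]] + Vnext[g[n - a]])
      best <- which(val > val[which.max(val)] - 1e-12)[1] # smallest tied a
      V[n, tt] <- val[best]
      split[n, tt] <- a[best]
    }
  }
  structure(list(V = V, split = split,
                 smaller_fraction = split / (1:model$n_max),
                 model = model),
            class = "division_policy")
}

#' @export
print.division_policy <- function(x, ...) {
  cat(sprintf("<division_policy> n_max = %d, T = %d, fitness = %s\n",
              x$model$n_max, x$model$T, x$model$fitness_mode))
  invisible(x)
}

#' Standard families of settling-survival functions
#'
#' Convenience constructors for non-decreasing survival probabilities
#' `s(n)`:
#' \describe{
#'   \item{power}{`s(n) = min(1, (n / K)^beta)`; concave on `n >= 1` for
#'     `beta <= 1`.}
#'   \item{linear_capped}{`s(n) = min(1, n / K)`.}
#'   \item{hill}{`s(n) = n^h / (n^h + K^h)`; convex below the inflection
#'     for `h > 1`, concave above it.}
#'   \item{step}{0 below `n_star`, 1 at or above it.}
#' }
#'
#' @param name Family name.
#' @param beta,K,h,n_star Family parameters (see descriptions).
#' @return A function of `n`, with attribute `"family"`.
#' @export
survival_families <- function(name = c("power", "linear_capped", "hill", "step"),
                              beta = 0.5, K = 10, h = 4, n_star = 8) {
  name <- match.arg(name)
  if (K <= 0) stop("K must be positive")
  f <- switch(name,
    power = { if (beta <= 0) stop("beta must be positive")
              function(n) pmin(1, (n / K)^beta) },
    linear_capped = function(n) pmin(1, n / K),
    hill = { if (h <= 0) stop("h must be positive")
             function(n) n^h / (n^h + K^h) },
    step = function(n) as.numeric(n >= n_star))
  attr(f, "family") <- name
  f
}

#' Concavity report for a survival function
#'
#' Second-difference check of `s` over `1..n_max`: reports whether the
#' tabulated function is concave, convex, or mixed over the range.
#'
#' @param s Survival function.
#' @param n_max Upper end of the tabulated range.
#' @return One of `"concave"`, `"convex"`, `"mixed"`, `"linear"`.
#' @export
concavity <- function(s, n_max = 256) {
  d2 <- diff(s(1:n_max), differences = 2)
  tol <- 1e-10
  if (all(d2 <= tol) && any(d2 < -tol)) "concave"
  else if (all(d2 >= -tol) && any(d2 > tol)) "convex"
  else if (all(abs(d2) <= tol)) "linear"
  else "mixed"
}

#' Classify each policy state by its division regime
#'
#' Labels every `(n, t)` state of a solved policy as `"no_split"`
#' (`a = 0`), `"halve"` (`a = floor(n/2)`, the most even split possible),
#' or `"asymmetric"` (anything in between). Size-1 clusters cannot divide
#' and are labelled `"no_split"`.
#'
#' @param policy A solved [solve_policy()] object.
#' @return A character matrix shaped like `policy$split`.
#' @export
policy_regimes <- function(policy) {
  stopifnot(inherits(policy, "division_policy"))
  n <- seq_len(nrow(policy$split))
  out <- policy$split
  lab <- matrix("asymmetric", nrow(out), ncol(out), dimnames = dimnames(out))
  lab[policy$split == 0] <- "no_split"
  lab[sweep(policy$split, 1, n %/% 2, "==") & n > 1] <- "halve"
  lab[n == 1, ] <- "no_split"
  lab
}
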