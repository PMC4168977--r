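#' Volume capacity of a concentric shell
#'
#' Cells of a snowflake cluster occupy concentric shells around the founder
#' cell: shell `k` holds the cells `k` links away from the root. Treating
#' every cell as a sphere of radius `r` (with edge lengths effectively zero),
#' the volume enclosed by shell `k` is that of a sphere of radius `(2k+1)r`,
#' which can hold at most `(2k+1)^3` cell volumes, ignoring sphere-packing
#' corrections. The cell radius cancels, so capacities are pure counts.
#'
#' @param k Non-negative integer shell index (vectorized).
#' @return Integer-valued capacity `(2k+1)^3` for each `k`.
#' @examples
#' shell_capacity(0:4) # 1 27 125 343 729
#' @export
shell_capacity <- function(k) {
  if (any(k < 0)) stop("shell index `k` must be >= 0")
  (2 * k + 1)^3
}

#' Branch-size series under a degree cap
#'
#' Number of cells in a single branch of age `a` (a branch starts as one
#' cell). Without a degree cap every cell buds every generation, so the
#' branch doubles: `f(a) = 2^a`. With a degree cap `d`, a cell can hold at
#' most `d` attachments (parent link plus children; severed attachment sites
#' still count), so a non-root cell buds only in the `d - 1` generations
#' after its birth. New births in the branch then follow the order-(d-1)
#' generalized Fibonacci recursion `b(a) = b(a-1) + ... + b(a-(d-1))` with
#' `b(0) = 1`, and the branch size is the cumulative sum. A cap of 3 gives
#' ordinary Fibonacci growth (`f(a) = Fib(a+3) - 1`), a cap of 4 tribonacci
#' growth, and the uncapped tree is the Fibonacci sequence of infinite order.
#'
#' @param degree_cap Integer degree cap `>= 2`, or `NULL` for no cap.
#' @param max_age Largest branch age to tabulate.
#' @return Numeric vector `f(0), f(1), ..., f(max_age)`.
#' @examples
#' branch_series(3, 6) # 1 2 4 7 12 20 33
#' branch_series(4, 7) # 1 2 4 8 15 28 52 96
#' @export
branch_series <- function(degree_cap, max_age) {
  stopifnot(max_age >= 0)
  if (is.null(degree_cap)) return(2^(0:max_age))
  if (degree_cap < 2) stop("`degree_cap` must be >= 2 (or NULL for no cap)")
  births <- numeric(max_age + 1)
  births[1] <- 1
  for (a in seq_len(max_age)) {
    i <- a - seq_len(degree_cap - 1) # ages a-1, ..., a-(d-1)
    births[a + 1] <- sum(births[i[i >= 0] + 1])
  }
  cumsum(births)
}

#' Total tree size at a given generation
#'
#' For a degree-capped tree grown without volume limits, the root buds in
#' generations `1..d`, so once all root links are used (`t >= d`) the whole
#' tree is exactly twice its largest (oldest) branch: `2 * f_d(t-1)`. For
#' `t < d` the size is the direct sum `1 + sum_i f_d(t - i)` over the
#' branches created so far.
#'
#' @param degree_cap Integer degree cap `>= 2`, or `NULL` (uncapped, `2^t`).
#' @param t Generation (number of completed reproduction rounds), `>= 0`.
#' @return Number of cells in the unconstrained tree after `t` rounds.
#' @examples
#' total_size(3, 4)  # 14
#' total_size(4, 14) # 7472
#' @export
total_size <- function(degree_cap, t) {
  stopifnot(t >= 0)
  if (is.null(degree_cap)) return(2^t)
  if (t == 0) return(1)
  f <- branch_series(degree_cap, t)
  if (t >= degree_cap) {
    2 * f[t] # 2 * f_d(t - 1)
  } else {
    1 + sum(f[t - seq_len(t) + 1]) # root + branches of ages t-1, ..., 0
  }
}

#' Shell-resolved birth counts for unconstrained growth
#'
#' Internal: matrix `m[j+1, t+1]` = number of cells born into shell `j` at
#' generation `t` for a tree growing without volume limits. The root sits in
#' shell 0 at t = 0 and buds into shell 1 in generations `1..d` (all
#' generations if uncapped); every other cell buds into the next shell in
#' each of the `d - 1` generations after its birth.
#'
#' @noRd
shell_births <- function(degree_cap, t_max) {
  m <- matrix(0, nrow = t_max + 2, ncol = t_max + 1)
  m[1, 1] <- 1
  if (t_max >= 1) {
    root_gens <- if (is.null(degree_cap)) 1:t_max else seq_len(min(degree_cap, t_max))
    m[2, root_gens + 1] <- 1
    if (t_max >= 2) {
      for (j in 2:t_max) {
        for (tt in j:t_max) {
          lags <- if (is.null(degree_cap)) seq_len(tt - 1) else seq_len(degree_cap - 1)
          i <- tt - lags
          i <- i[i >= 1]
          m[j + 1, tt + 1] <- sum(m[j, i + 1])
        }
      }
    }
  }
  m
}

#' Cumulative shell occupancy of the unconstrained tree
#'
#' Number of cells within the volume enclosed by shell `k` (i.e. in shells
#' `0..k`) after `t` rounds of reproduction, for a tree growing with the
#' given degree cap but no volume constraint. Uncapped this is the binomial
#' partial sum `sum_{j <= k} C(t, j)`; capped it follows the shell-resolved
#' recursion `m(j, t) = sum_{i=1}^{d-1} m(j-1, t-i)` with root births in
#' generations `1..d`.
#'
#' @param degree_cap Integer degree cap `>= 2`, or `NULL` for no cap.
#' @param k Shell index `>= 0`.
#' @param t Generations `>= 0`.
#' @return Cumulative cell count in shells `0..k` at generation `t`.
#' @examples
#' shell_occupancy(NULL, 4, 12) # 794, exceeding shell_capacity(4) = 729
#' @export
shell_occupancy <- function(degree_cap, k, t) {
  stopifnot(k >= 0, t >= 0)
  if (is.null(degree_cap)) {
    return(sum(choose(t, 0:min(k, t))))
  }
  m <- shell_births(degree_cap, t)
  sum(m[seq_len(min(k + 1, nrow(m))), , drop = FALSE])
}

#' First generation at which shell volumes overflow
#'
#' Scans the unconstrained growth trajectory for the smallest generation `t`
#' at which the cumulative occupancy of some shell exceeds its enclosed
#' volume capacity `(2k+1)^3`, and reports which shells are exceeded at that
#' generation. Degree-cap-2 trees are filaments (one cell per shell) and
#' never overflow.
#'
#' @param degree_cap Integer degree cap `>= 2`, or `NULL` for no cap.
#' @param t_max Largest generation scanned (safety bound).
#' @return A list with elements `generation` (first overflow generation, or
#'   `NA` if none within `t_max`), `shells` (integer vector of shell indices
#'   exceeded at that generation), `overflows` (logical, `FALSE` for
#'   filaments and non-overflowing scans), and `occupancy`/`capacity` for the
#'   exceeded shells.
#' @examples
#' first_overflow(NULL)$generation # 12
#' first_overflow(3)$shells        # 14 15
#' @export
first_overflow <- function(degree_cap, t_max = 60) {
  if (!is.null(degree_cap) && degree_cap < 2) stop("`degree_cap` must be >= 2 or NULL")
  if (!is.null(degree_cap) && degree_cap == 2) {
    return(list(generation = NA_integer_, shells = integer(0),
                overflows = FALSE, occupancy = integer(0), capacity = integer(0)))
  }
  m <- shell_births(degree_cap, t_max)
  ks <- 0:(nrow(m) - 1)
  caps <- shell_capacity(ks)
  for (t in 1:t_max) {
    occ <- cumsum(rowSums(m[, seq_len(t + 1), drop = FALSE]))
    exceeded <- which(occ > caps) - 1L
    if (length(exceeded)) {
      return(list(generation = t, shells = exceeded, overflows = TRUE,
                  occupancy = occ[exceeded + 1], capacity = caps[exceeded + 1]))
    }
  }
  list(generation = NA_integer_, shells = integer(0), overflows = FALSE,
       occupancy = integer(0), capacity = integer(0))
}

#' Occupancy-versus-capacity table
#'
#' Tabulates cumulative shell occupancy against shell capacity over a grid of
#' generations, for export or plotting.
#'
#' @param degree_cap Integer degree cap `>= 2`, or `NULL`.
#' @param t_max Largest generation.
#' @param k_max Largest shell index (default `t_max`).
#' @return A data frame with columns `t`, `shell`, `occupancy`, `capacity`,
#'   `exceeded`.
#' @export
occupancy_table <- function(degree_cap, t_max, k_max = t_max) {
  m <- shell_births(degree_cap, t_max)
  ks <- 0:min(k_max, nrow(m) - 1)
  out <- do.call(rbind, lapply(1:t_max, function(t) {
    occ <- cumsum(rowSums(m[, seq_len(t + 1), drop = FALSE]))[ks + 1]
    data.frame(t = t, shell = ks, occupancy = occ,
               capacity = shell_capacity(ks))
  }))
  out$exceeded <- out$occupancy > out$capacity
  rownames(out) <- NULL
  out
}
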