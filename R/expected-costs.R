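#' Expected cost of an intact cell in the well-mixed pool
#'
#' With `k` damaged cells in a pool of `n`, an intact cell's `n - 1`
#' potential interaction partners comprise `n - k - 1` intact and `k`
#' damaged cells, so its expected cost is
#' `F_k = c_ii * (n - k - 1) / (n - 1) + c_id * k / (n - 1)`,
#' a convex combination of `c_ii` and `c_id`. Requires at least one intact
#' cell (`k <= n - 1`).
#'
#' @param k number of damaged cells (vectorized); `0 <= k <= n - 1`.
#' @param n pool size, `n >= 2`.
#' @param cm a [cost_matrix()].
#' @return Numeric vector of expected costs `F_k`, same length as `k`.
#' @examples
#' expected_cost_intact(10, 20, cost_matrix(1, 1.5, 1.16, 0.8)) # 24/19
#' @export
expected_cost_intact <- function(k, n, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (any(k < 0 | k > n - 1)) {
    stop("k must satisfy 0 <= k <= n - 1 (an intact cell must exist)",
         call. = FALSE)
  }
  (cm[["c_ii"]] * (n - k - 1) + cm[["c_id"]] * k) / (n - 1)
}

#' Expected cost of a damaged cell in the well-mixed pool
#'
#' With `k` damaged cells in a pool of `n`, a damaged cell's partners
#' comprise `n - k` intact and `k - 1` other damaged cells, so its expected
#' cost is `G_k = c_di * (n - k) / (n - 1) + c_dd * (k - 1) / (n - 1)`.
#' Requires at least one damaged cell (`k >= 1`).
#'
#' @param k number of damaged cells (vectorized); `1 <= k <= n`.
#' @inheritParams expected_cost_intact
#' @return Numeric vector of expected costs `G_k`.
#' @examples
#' expected_cost_damaged(1, 20, cost_matrix(1, 1.5, 1.16, 0.8)) # c_di = 1.16
#' @export
expected_cost_damaged <- function(k, n, cm) {
  cm <- validate_cost_matrix(cm)
  check_pool_size(n)
  if (any(k < 1 | k > n)) {
    stop("k must satisfy 1 <= k <= n (a damaged cell must exist)",
         call. = FALSE)
  }
  (cm[["c_di"]] * (n - k) + cm[["c_dd"]] * (k - 1)) / (n - 1)
}

check_pool_size <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != round(n)) {
    stop("pool size n must be a single integer >= 2", call. = FALSE)
  }
  invisible(n)
}
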