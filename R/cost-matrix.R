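#' Interaction cost matrix for intact and damaged stem cells
#'
#' Pairwise interaction costs between the two cell types. `c_ii` is the cost
#' an intact cell incurs when interacting with another intact cell, `c_id`
#' the cost of an intact cell interacting with a damaged cell, `c_di` the
#' cost of a damaged cell interacting with an intact cell, and `c_dd` the
#' cost of a damaged cell interacting with another damaged cell. Costs act
#' as inverse fitness: cells with higher expected cost are more likely to be
#' eliminated from the pool.
#'
#' All entries must be strictly positive and finite. No normalization is
#' imposed; [normalize_cost_matrix()] rescales so that `c_ii = 1` (the
#' process law depends only on cost ratios, so this loses nothing).
#'
#' @param c_ii,c_id,c_di,c_dd positive finite interaction costs.
#' @return An object of class `cost_matrix`: a named numeric vector with
#'   elements `c_ii`, `c_id`, `c_di`, `c_dd`.
#' @examples
#' cost_matrix(1, 1.5, 1.16, 0.8)
#' @export
cost_matrix <- function(c_ii = 1, c_id = 1, c_di = 1, c_dd = 1) {
  cm <- structure(
    c(c_ii = as.numeric(c_ii), c_id = as.numeric(c_id),
      c_di = as.numeric(c_di), c_dd = as.numeric(c_dd)),
    class = "cost_matrix"
  )
  validate_cost_matrix(cm)
}

#' Validate a cost matrix
#'
#' Checks that all four entries are strictly positive, finite scalars.
#'
#' @param cm a [cost_matrix()] (or an object coercible to one: a numeric
#'   vector of length 4 in the order `c_ii`, `c_id`, `c_di`, `c_dd`).
#' @return The validated `cost_matrix`, invisibly unchanged.
#' @export
validate_cost_matrix <- function(cm) {
  cm <- as_cost_matrix(cm)
  for (field in c("c_ii", "c_id", "c_di", "c_dd")) {
    v <- cm[[field]]
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("cost matrix entry '", field,
           "' must be a strictly positive finite number (got ",
           format(v), ")", call. = FALSE)
    }
  }
  cm
}

#' @export
print.cost_matrix <- function(x, ...) {
  m <- matrix(unclass(x)[c("c_ii", "c_id", "c_di", "c_dd")],
              nrow = 2, byrow = TRUE,
              dimnames = list(c("intact", "damaged"),
                              c("vs intact", "vs damaged")))
  cat("Interaction cost matrix (row = focal cell, column = partner):\n")
  print(m, ...)
  cat("regime:", regime(x), "\n")
  invisible(x)
}

as_cost_matrix <- function(cm) {
  if (inherits(cm, "cost_matrix")) return(cm)
  if (is.numeric(cm) && length(cm) == 4L) {
    return(structure(c(c_ii = cm[[1]], c_id = cm[[2]],
                       c_di = cm[[3]], c_dd = cm[[4]]),
                     class = "cost_matrix"))
  }
  stop("expected a cost_matrix or a numeric vector of length 4", call. = FALSE)
}

#' Is the cost matrix frequency-independent?
#'
#' Costs are frequency-independent when each cell type's cost does not depend
#' on the mix of partners: `c_ii == c_id` and `c_di == c_dd`.
#'
#' @inheritParams validate_cost_matrix
#' @return Logical scalar.
#' @export
is_frequency_independent <- function(cm) {
  cm <- validate_cost_matrix(cm)
  cm[["c_ii"]] == cm[["c_id"]] && cm[["c_di"]] == cm[["c_dd"]]
}

#' Rescale a cost matrix so that the intact-intact cost is 1
#'
#' Divides all entries by `c_ii`. Because elimination probabilities are ratios
#' of costs, the rescaled matrix generates exactly the same process.
#'
#' @inheritParams validate_cost_matrix
#' @return A `cost_matrix` with `c_ii = 1`.
#' @export
normalize_cost_matrix <- function(cm) {
  cm <- validate_cost_matrix(cm)
  as_cost_matrix(unclass(cm) / cm[["c_ii"]])
}

#' Game-theoretic regime of a cost matrix
#'
#' Classifies the matrix by which cell type is cheaper against each partner
#' type (remember: lower cost = higher fitness):
#' * `neutral` - all four entries equal; the two types are indistinguishable.
#' * `intact_dominant` - intact cells are strictly cheaper against both
#'   partner types (`c_ii < c_di` and `c_id < c_dd`).
#' * `damaged_dominant` - damaged cells are strictly cheaper against both
#'   partner types (`c_ii > c_di` and `c_id > c_dd`).
#' * `positive_frequency_dependent` - each type is cheaper when interacting
#'   with its own type (`c_ii < c_di`, `c_id > c_dd`); a coordination game.
#' * `negative_frequency_dependent` - each type is cheaper when interacting
#'   with the other type (`c_ii > c_di`, `c_id < c_dd`); includes hawk-dove.
#' * `boundary` - any tie other than full neutrality. Ties are exactly the
#'   axes of the shape diagram, so they are reported loudly rather than
#'   folded into a neighboring region.
#'
#' @inheritParams validate_cost_matrix
#' @return Character scalar, one of the labels above.
#' @examples
#' regime(cost_matrix(1, 1, 0.8, 0.8))    # damaged_dominant
#' regime(cost_matrix(1, 0.25, 0.5, 0.75)) # negative_frequency_dependent
#' @export
regime <- function(cm) {
  cm <- validate_cost_matrix(cm)
  c_ii <- cm[["c_ii"]]; c_id <- cm[["c_id"]]
  c_di <- cm[["c_di"]]; c_dd <- cm[["c_dd"]]
  if (c_ii == c_id && c_id == c_di && c_di == c_dd) return("neutral")
  if (c_ii == c_di || c_id == c_dd) return("boundary")
  if (c_ii < c_di && c_id < c_dd) return("intact_dominant")
  if (c_ii > c_di && c_id > c_dd) return("damaged_dominant")
  if (c_ii < c_di && c_id > c_dd) return("positive_frequency_dependent")
  "negative_frequency_dependent"
}
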