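# Shared fixture cost matrices and a generator of random positive matrices.

cm_neutral <- cost_matrix(1, 1, 1, 1)
cm_damaged_adv <- cost_matrix(1, 1, 0.8, 0.8)       # damaged_dominant
cm_intact_adv <- cost_matrix(1, 1, 1.25, 1.25)      # intact_dominant
cm_green <- cost_matrix(1, 1.5, 1.16, 0.8)          # mixed, dose-sweep set
cm_negfreq <- cost_matrix(1, 0.25, 0.5, 0.75)       # negative_frequency_dependent
cm_posfreq <- cost_matrix(1, 1.5, 1.2, 0.5)         # positive_frequency_dependent
cm_posfreq_lattice <- cost_matrix(1, 1.75, 1.25, 0.5)

random_cost_matrix <- function(lo = 0.1, hi = 2) {
  cost_matrix(runif(1, lo, hi), runif(1, lo, hi),
              runif(1, lo, hi), runif(1, lo, hi))
}

# Mixed random lattice grid with at least one cell of each type.
random_grid <- function(side, p_damaged = 0.4) {
  g <- matrix(as.integer(runif(side^2) < p_damaged), side, side)
  g[1, 1] <- 0L
  g[side, side] <- 1L
  g
}
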