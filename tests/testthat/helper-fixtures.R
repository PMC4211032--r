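# Frozen printed values of the published two-way grid (rows: mobile effect
# 0.96, 0.94, 0.92, 0.90; columns: per-visit leisure cost 33.84, 56.98,
# 80.12). Reconstructed cells must agree within +/- $0.15 (the published
# table carries a constant ~$0.06 offset from sub-dollar rounding of its
# internal subtotals).
published_twoway <- function() {
  tibble::tibble(
    mobile_effect = rep(c(0.96, 0.94, 0.92, 0.90), each = 3),
    leisure_cost_per_visit = rep(c(33.84, 56.98, 80.12), times = 4),
    inb = c(198.75, 236.70, 274.65,
            110.77, 148.72, 186.67,
            22.80, 60.75, 98.70,
            -65.18, -27.23, 10.72)
  )
}

# Unrounded ledger sums used across tests.
ledger_sums <- function() {
  list(
    mobile_hs = 1.39 + 6.94 + 0.44 + 42.00 + 43.05 + 19.95 + 22.00,  # 135.77
    in_person_hs = 103.74 + 2.16 + 0.21 + 3.83 + 10.25 + 43.46 + 10.56,  # 174.21
    in_person_patient = 102.24 + 33.84 + 38.11 + 32.80  # 206.99
  )
}

# A comparison object with chosen increments, for unit tests of the
# decision rules without running the costing.
make_comparison <- function(delta_cost, delta_effect,
                            perspective = "societal") {
  comp <- incremental(
    breakdown = tibble::tibble(
      arm = c("mobile", "in_person"),
      health_system = c(0, delta_cost),
      patient = c(0, 0),
      external = c(0, 0),
      total = c(0, delta_cost)
    ),
    effects = c(mobile = 0.5 + delta_effect / 2,
                in_person = 0.5 - delta_effect / 2),
    perspective = perspective
  )
  comp
}
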