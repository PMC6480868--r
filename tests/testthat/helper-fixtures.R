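# Shared fixtures: the canonical parameter set, the study data, and a toy
# travel-time matrix small enough to check by hand.

params <- default_parameters()
study <- study_region()

toy_minutes <- function() {
  m <- matrix(c(10, 30,
                25, 5,
                20, 20), nrow = 3, byrow = TRUE,
              dimnames = list(c("m1", "m2", "m3"), c("h1", "h2")))
  m
}

# independent smallest-feasible-staffing search: try unit counts upward
brute_min_units <- function(cases, care_hours, capacity, minimum) {
  if (cases == 0) return(0L)
  u <- 0L
  repeat {
    if (u >= minimum && u * capacity >= cases * care_hours) return(u)
    u <- u + 1L
  }
}
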