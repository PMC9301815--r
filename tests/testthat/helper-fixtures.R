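# shared fixtures, built in code at test time

base_params <- function() default_parameters()

fixture_life_table <- function() default_life_table()

# flat-mortality life table for closed-form oracles
constant_life_table <- function(q = 0.1, ages = 35:100) {
  as_life_table(data.frame(age = ages, q_annual = q))
}

# hand-built mortality schedule of annual cycles with constant probability
annual_schedule <- function(q, n_cycles, start_age = 60) {
  sched <- data.frame(
    start = 365 * (seq_len(n_cycles) - 1),
    length = 365,
    p_death = q,
    age = start_age + (seq_len(n_cycles) - 1)
  )
  class(sched) <- c("txace_schedule", "data.frame")
  sched
}

no_utility <- list(base = 1, decrements = list(under65 = 0, age65_74 = 0, age75plus = 0))

# cache the deterministic base case across tests
base_case_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_model(base_params(), fixture_life_table())
    cache
  }
})
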