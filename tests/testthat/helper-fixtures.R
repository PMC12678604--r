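# Shared fixtures: all synthetic, regenerated from the bundled
# acceleration-model parameters at test time.

berlin_splits <- function(sex = "male", event = "100",
                          noise_sd = 0, seed = 1L) {
  p <- sprint_parameters()$table1[[sex]][[event]]
  make_split_table(fixture_spec(
    tau = p$tau, v_f = p$v_f,
    total_distance = as.numeric(event),
    finish_time = p$finish_time,
    split_interval = if (event == "100") 10 else 50,
    noise_sd = noise_sd, seed = seed
  ))
}

berlin_profile <- function(sex = "male", event = "100", dt = 0.01) {
  p <- sprint_parameters()$table1[[sex]][[event]]
  dur <- p$finish_time - 0.15
  # the modelled profile cannot exceed the pure-acceleration distance;
  # where the nominal distance is out of reach (women's 100 m, whose
  # modelled profile undershoots the line) target just below the cap
  d_max <- p$v_f * (dur - p$tau * (1 - exp(-dur / p$tau)))
  sprint_velocity_profile(
    v_f = p$v_f, tau = p$tau, duration = dur,
    distance = min(as.numeric(event), 0.995 * d_max), dt = dt
  )
}

# race durations net of the 0.15 s reaction time, per sex
berlin_durations <- function(sex = "male") {
  p <- sprint_parameters()$table1[[sex]]
  vapply(p, function(x) x$finish_time - 0.15, numeric(1))
}
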