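# Shared fixtures: small, fast configurations and signal builders.

# Short-session config for signal-level tests (claps at 3..5.8 s,
# vocalisations afterwards).
quick_cfg <- function(...) {
  args <- modifyList(list(n_infants = 1, timepoints = 6,
                          session_duration = 60, attrition = 0, p_gap = 0,
                          p_rate_drop = 0, p_artifact = 0), list(...))
  do.call(sim_config, args)
}

# Noise-free deterministic config: tone carrier, no random effects, no lag.
clean_cfg <- function(...) {
  args <- modifyList(list(carrier_type = "tone", sd_resid = 0,
                          sd_intercept = 0, sd_slope_limb = 0,
                          lag_audio_imu = 0), list(...))
  do.call(quick_cfg, args)
}

# A bare epoch object on the standard grid with given raw values.
make_epoch <- function(raw, event_id = 1L, limb = "arm", side = "left") {
  structure(list(event_id = event_id, onset = 0,
                 placement = placement("infant", limb, side),
                 t_rel = seq(-3.5, 5, by = 1 / 60), raw = raw,
                 baselined = NULL, envelope = NULL,
                 excluded = FALSE, reason = NA_character_),
            class = "epoch")
}

epoch_t <- seq(-3.5, 5, by = 1 / 60)

# Enveloped epoch whose envelope is set directly (for median/summary tests).
make_env_epoch <- function(env, event_id = 1L, limb = "arm", side = "left") {
  e <- make_epoch(env, event_id, limb, side)
  e$baselined <- env
  e$envelope <- env
  e
}
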