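# canonical parameter set used throughout the suite
base_params <- function(...) {
  defaults <- list(a = 75, mu_c = 0.5, zeta = 20, alpha = 2, tau = 50,
                   ter = 300, sr = 30)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(dmc_params, defaults)
}

# fast fitting settings for structural tests
tiny_fit_config <- function(...) {
  fit_config(n_sim = 500, max_iterations = 25, n_restarts = 2, ...)
}

# a deterministic session-like data.frame without simulation
manual_session <- function(congruency, correct, rt_ms,
                           participant = "s01", condition = "sham",
                           phase = "main") {
  n <- length(congruency)
  word <- ifelse(congruency == "congruent", "red", "red")
  font <- ifelse(congruency == "congruent", "red", "yellow")
  data.frame(participant = participant, condition = condition,
             trial_idx = seq_len(n) - 1L,
             phase = rep_len(phase, n), word = word, font_color = font,
             congruency = congruency, prev_congruency = NA_character_,
             response = 1L, correct = correct, rt_ms = rt_ms,
             isi_s = 0.5, stringsAsFactors = FALSE)
}
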