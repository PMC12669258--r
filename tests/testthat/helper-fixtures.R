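# shared fixtures: small layouts, templates, and Markov models built in code

tiny_layout <- function(n = 16) default_layout(n)

tiny_templates <- function(n_channels = 16, k = 5) {
  synth_templates(default_layout(n_channels), k = k)
}

# 5-state chain with 60 ms mean dwell at the given rate
tiny_model <- function(sfreq = 125, dwell = 0.06, k = 5, ...) {
  markov_model(transition_from_dwell(rep(dwell, k), sfreq), ...)
}

# render a known label sequence at zero noise (no polarity flips by default)
render_clean <- function(labels, templates, flips = FALSE, seed = 1) {
  render_eeg(labels, templates, gfp_mean = 15, gfp_cv = 0.3, noise_sigma = 0,
             polarity_flips = flips, seed = seed)
}

# recording whose consecutive 1 s epochs have prescribed target-state coverage
coverage_recording <- function(coverages, templates, target = 4L, other = 1L,
                               sfreq = 100) {
  lab <- unlist(lapply(coverages, function(p) {
    nd <- round(p * sfreq)
    c(rep(target, nd), rep(other, sfreq - nd))
  }))
  render_clean(ms_labels(lab, sfreq, n_states = n_states(templates)), templates)
}
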