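# Shared fixtures: small tubes and cached expensive runs.

adult <- subject_preset("healthy_adult")
child <- subject_preset("child_5y")
asthmatic <- subject_preset("severe_asthma")

# a small terminal-bronchiole-like tube used in microdosimetry tests
small_tube <- list(diam_um = 600, length_um = 1650, gel_um = 2, sol_um = 2.4)

uniform_depth_weights <- function(depths = c(10, 20)) {
  data.frame(depth_um = depths, weight = rep(1 / length(depths),
                                             length(depths)))
}

# cache: one deposition run per preset at moderate size, shared by tests
.run_cache <- new.env()
cached_deposition <- function(preset, n = 4000, seed = 11) {
  key <- paste(preset, n, seed)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- run_deposition(exposure_scenario(),
                                        subject_preset(preset),
                                        n_histories = n, seed = seed)
  .run_cache[[key]]
}
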