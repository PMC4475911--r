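# Synthetic population used by the redundancy and shuffle-control checks:
# one 300 s session with fully speed-driven delta LFP (coupling = 1) and 8
# heterogeneous units, evaluated over the lfp / kin / kin+lfp / kin+hist
# ladders with a 20-permutation chance level.  Computed once and cached.
# The ground truth has zero LFP weights: spikes are driven by kinematics and
# history only, so every bit of LFP predictive power flows through the
# shared movement drive -- redundancy by construction.
acceptance_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- ground_truth_spec(coupling = 1,
                                 lfp_weights = c(delta_re = 0))
      session <- suppressWarnings(
        generate_session(truth, duration_s = 300, n_units = 8, seed = 601))
      report <- suppressWarnings(run_session(
        session, cv_config(seed = 602),
        ladders = c("lfp", "kin"),
        comparisons = list(c("kin", "kin+lfp"), c("kin", "kin+hist")),
        n_perm = 20))
      cache <<- list(session = session, report = report)
    }
    cache
  }
})
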