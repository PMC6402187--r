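# Shared fixtures: canonical scenarios and cost models, built fresh per run.
scn4 <- default_scenarios()
scn1 <- scn4[["Scenario 1"]]
scn2 <- scn4[["Scenario 2"]]

cm_default <- cost_model()                      # economies factor 0.8
cm_prop <- cost_model(economies_factor = 1)     # strictly proportional costs

random_scenario <- function() {
  scenario("random",
           stage_design(runif(1, 0.001, 0.5), runif(1, 0.05, 0.99)),
           phase3 = stage_design(runif(1, 0.001, 0.3), runif(1, 0.5, 0.99),
                                 n_trials = sample(1:3, 1)),
           p_eff = runif(1), n_candidates = sample(10:500, 1))
}
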