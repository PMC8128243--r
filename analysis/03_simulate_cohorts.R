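#!/usr/bin/env Rscript
# Simulate the two cohorts at the study's sample sizes (20 participants in
# the constant-disparity experiment, 12 in the variable-disparity one) and
# export their trial tables.

library(vaeframes)

dir.create("results", showWarnings = FALSE)

pop <- population_spec()
sim1 <- simulate_dataset(1, n_participants = 20, pop = pop, seed = 301)
sim2 <- simulate_dataset(2, n_participants = 12, pop = pop, seed = 302)

write_trials_csv(sim1$trials, "results/trials_exp1.csv")
write_trials_csv(sim2$trials, "results/trials_exp2.csv")
write.csv(rbind(sim1$participants, sim2$participants),
          "results/generative_parameters.csv", row.names = FALSE)

cat("Experiment 1 cohort:", length(unique(sim1$trials$participant)),
    "participants,", nrow(sim1$trials), "test trials",
    "(24 blocks x 40 responses each).\n")
cat("Experiment 2 cohort:", length(unique(sim2$trials$participant)),
    "participants,", nrow(sim2$trials), "test trials",
    "(8 blocks x 40 responses each).\n")
cat("Observer population: gain", pop$means$gain, "- bias",
    pop$means$bias, "deg - response SD", pop$means$response_noise_sd,
    "deg - outlier rate", pop$means$outlier_rate, "\n")
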