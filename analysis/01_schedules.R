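#!/usr/bin/env Rscript
# Build one instance of every experimental session schedule and tabulate
# the design counts: NPU threat task (2 runs, 16 trials per condition,
# 3 shocks per run), startle habituation (9 probes ~17 s apart), the
# three Sternberg variants, the 600-pulse iTBS session, and the 100-ms
# shock pulse train.

library(npustartle)

dir.create("results", showWarnings = FALSE)
seed <- 20260929L

npu <- place_shocks(build_npu_schedule(rng_seed = seed), 3,
                    rng_seed = seed + 1)
hab <- build_habituation_schedule(rng_seed = seed + 2)
targ <- build_sternberg_schedule("targeting", rng_seed = seed + 3)
thr <- build_sternberg_schedule("testing_threat", rng_seed = seed + 4)
tms <- build_sternberg_schedule("tms", rng_seed = seed + 5)
itbs <- build_itbs_schedule()
shock <- build_shock_pulse_train(100, 200, 2)

thr_kept <- thr$trials[!thr$trials$is_shock_trial, ]
counts <- data.frame(
  quantity = c("npu_trials_per_condition", "npu_shocks_per_run",
               "habituation_probes",
               "sternberg_targeting_trials_per_condition",
               "sternberg_threat_trials_per_cell",
               "sternberg_tms_trials_per_condition",
               "itbs_total_pulses", "shock_train_pulses"),
  value = c(unname(table(npu$trials$condition_label)["U_iti"]),
            nrow(npu$shocks) / 2,
            length(hab$probe_times_s),
            sum(targ$trials$trial_type == "sort"),
            sum(thr_kept$trial_type == "sort" &
                  thr_kept$block_condition == "threat"),
            sum(tms$trials$trial_type == "sort"),
            length(itbs$pulse_times_s),
            length(shock$pulse_times_s))
)
write_table(counts, "results/design_counts.csv")
write_events(schedule_events(npu, "sub01", "active"),
             "results/example_npu_events.csv")

cat("Design counts:\n")
print(counts, row.names = FALSE)
cat("\nNPU probe spacing: min",
    round(min(diff(sort(npu$trials$probe_time_s[npu$trials$run == 1]))), 2),
    "s (refractory floor 8 s); iTBS train length",
    itbs$params$train_on_s, "s.\n")
cat("Wrote results/design_counts.csv and results/example_npu_events.csv\n")
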