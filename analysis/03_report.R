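#!/usr/bin/env Rscript
# Assemble the prevalence and between-group comparison report from the
# fixture ascertainment run and write the five report tables plus the
# JSON bundle under results/report/.
suppressMessages(library(ddascertain))

cohort <- read_cohort("results/fixture/children.csv",
                      "results/fixture/maternal.csv",
                      "results/fixture/events.csv")
run <- run_ascertainment(cohort$children, cohort$maternal, cohort$events)
rep <- build_report(run)
print(rep)
write_report(rep, "results/report")
cat("\nwrote results/report/{table3..table7}.csv and report.json\n")
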