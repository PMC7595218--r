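#!/usr/bin/env Rscript
# Stage 4: association of the CNV score with visual outcome.
#
# LOCF-complete the follow-up visits, compute the logMAR change from
# baseline at months 3 and 12, and regress the change on the CNV score,
# unadjusted and adjusted for age, sex and baseline logMAR.  A negative
# score coefficient means higher (more PNV-like) scores improve faster.

suppressPackageStartupMessages(library(pachycnv))
out <- "results"
cohort <- read_cohort(file.path(out, "cohort.csv"))
visits <- read_visits(file.path(out, "visits.csv"))
scores <- readr::read_csv(file.path(out, "scores.csv"),
                          show_col_types = FALSE)

assoc <- outcome_association(
  cohort, visits, scores$score[match(cohort$patient_id, scores$patient_id)]
)
readr::write_csv(assoc, file.path(out, "outcome_regressions.csv"))
for (i in seq_len(nrow(assoc))) {
  cat(sprintf("month %2d %-10s B = %+.4f (SE %.4f), p = %.4g, n = %d\n",
              assoc$month[i],
              ifelse(assoc$adjusted[i], "adjusted", "unadjusted"),
              assoc$b_score[i], assoc$se_score[i], assoc$p_score[i],
              assoc$n[i]))
}
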