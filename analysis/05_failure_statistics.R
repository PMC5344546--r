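# Damage scores, stress-vs-score regression and risk classification,
# combining the packaged in vitro failure counts with the model's stresses.
source("analysis/00_setup.R")

bat <- readRDS(file.path(res_dir, "complex_battery.rds"))
counts <- invitro_failure_counts()
counts$score <- damage_score(counts)
cat("in vitro group damage scores:\n"); print(counts[c("scenario", "score")])

tb <- bat$table
sel <- tb$section %in% c("POST", "POST-LAT1", "POST-LAT2") &
  tb$subset %in% c("cranial", "middle", "caudal", "inner", "outer")
x <- tb[sel, ]
x$predictor <- paste(x$section, x$subset, x$direction, sep = "|")
xm <- stats::reshape(x[c("scenario", "predictor", "value")],
                     idvar = "scenario", timevar = "predictor",
                     direction = "wide")
rownames(xm) <- xm$scenario
xm <- as.matrix(xm[paste0("case", 1:5), -1])
colnames(xm) <- sub("^value\\.", "", colnames(xm))

# one row per specimen (six per group), identical within-scenario stresses
spec_x <- xm[rep(1:5, each = 6), ]
spec_score <- rep(counts$score / 6, each = 6)
reg <- regress_stress_vs_score(spec_x, spec_score)
reg <- reg[order(reg$p_value), ]
write_result_table(reg, file.path(res_dir, "regression_stress_vs_score"))
cat("\nsignificant predictors (per-predictor OLS, alpha = 0.05):\n")
print(reg[reg$significant & !is.na(reg$significant),
          c("predictor", "slope", "p_value")], digits = 3)

risk <- classify_risk(bat$table)
write_result_table(risk, file.path(res_dir, "risk_labels"))
cat("\nrisk label counts by scenario (axial direction, POST sections):\n")
rsel <- risk$direction == "axial" &
  risk$section %in% c("POST", "POST-LAT1", "POST-LAT2") & risk$subset == "all"
print(risk[rsel, c("scenario", "section", "value", "risk")], digits = 3)
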