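# The five complex loading scenarios: regional tensile stresses, interface
# stresses and risk labels.
source("analysis/00_setup.R")

mesh <- default_mesh()
mats <- default_materials()
sw_file <- file.path(res_dir, "swelling_state.rds")
sw <- if (file.exists(sw_file)) readRDS(sw_file) else
  initialize_swelling(mesh, mats)

bat <- run_battery(paste0("case", 1:5), mesh = mesh, materials = mats,
                   cfg = scenario_cfg(), prestate = sw)
if (length(bat$errors)) print(bat$errors)
write_result_table(bat$table, file.path(res_dir, "complex_regional_stresses"))
iface <- do.call(rbind, lapply(names(bat$results), function(id)
  cbind(scenario = id, bat$results[[id]]$interface)))
write_result_table(iface, file.path(res_dir, "complex_interface_stresses"))
cat("scenarios ranked by POST mean tensile axial stress:\n")
print(bat$ranking)
cat("\nPOST-LAT1 mean tensile axial stress per case (compare in vitro scores",
    "12, 8.5, 7.5, 4.5, 0):\n")
tb <- bat$table
print(tb[tb$section == "POST-LAT1" & tb$subset == "all" &
           tb$direction == "axial", c("scenario", "value", "risk")])
saveRDS(bat, file.path(res_dir, "complex_battery.rds"))
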