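# Shared setup for the analysis drivers: default model, output directory.
library(discfem)

res_dir <- "results"
dir.create(res_dir, showWarnings = FALSE)

default_mesh <- function() build_disc_mesh()
default_materials <- function() disc_materials()

scenario_cfg <- function(steps = 16000) {
  solver_config(mode = "explicit-relaxation", explicit_steps = steps,
                explicit_hold = max(2000, steps / 4), damping = 0.05,
                mass_update = 20)
}
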