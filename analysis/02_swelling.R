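# Initialize the 0.2 MPa nucleus swelling pre-stress and characterize it.
source("analysis/00_setup.R")

mesh <- default_mesh()
mats <- default_materials()
sw <- initialize_swelling(mesh, mats)
cat(sprintf("eigenstretch %.5f -> mean NP pressure %.5f MPa (target 0.2)\n",
            sw$swell_stretch, sw$np_pressure))
map <- build_section_map(mesh)
loc <- discfem:::local_normal_stresses(sw, mesh)
af <- map$is_af
cat(sprintf("mean AF circumferential stress: %.4f MPa (tensile hoop)\n",
            sum(loc[af, "circumferential"] * mesh$volumes[af]) /
              sum(mesh$volumes[af])))
saveRDS(sw, file.path(res_dir, "swelling_state.rds"))
write_vtu(mesh, file.path(res_dir, "swelling_stress.vtu"),
          cell_data = list(stress = sw$stress),
          point_data = list(u = matrix(sw$u, ncol = 3, byrow = TRUE)))
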