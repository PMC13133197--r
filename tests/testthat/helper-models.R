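# End-to-end fixtures shared between the acceptance tests and the
# pipeline unit tests (built once; the full scene is the expensive part).

full_scene_models <- function() {
  fixture("full_scene_models", function() {
    sp <- phantom_spec(seed = 42)
    fcc <- build_interbody_model(sp, scaffold = "fcc", mesh_edge_mm = 2,
                                 homogenize_n = 24)
    ti <- build_interbody_model(sp, scaffold = "ti_ring", mesh_edge_mm = 2)
    list(fcc = fcc, ti = ti)
  })
}

full_scene_reports <- function() {
  fixture("full_scene_reports", function() {
    m <- full_scene_models()
    list(standing = run_interbody_case(m$fcc, load_case("standing")),
         flexion = run_interbody_case(m$fcc, load_case("flexion")),
         ti_standing = run_interbody_case(m$ti, load_case("standing")))
  })
}
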