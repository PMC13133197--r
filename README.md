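# hapcage

Patient-specific finite element modelling of porous hydroxyapatite (HAp)
interbody fusion cages, from CT intensity to damage metrics.

Interbody fusion replaces a degenerated intervertebral disc with a cage
that must carry spinal loads while bone grows through it. Porous
3D-printed hydroxyapatite is an attractive cage material — bioactive and
chemically close to bone mineral — but brittle, so the microarchitecture
(lattice family, porosity, grading) has to be chosen with a mechanical
model of the implanted segment. `hapcage` implements that modelling chain
for users who want to study such designs without commercial tools, and
ships a synthetic vertebra phantom so every stage is testable without
clinical data:

1. **Phantom** (`make_vertebra_phantom`, `make_two_vertebra_scene`) —
   synthetic CT volumes of vertebral bodies with a thin cortical shell,
   an oriented trabecular texture with controllable principal direction
   and degree of anisotropy, and full ground truth.
2. **CT preparation** (`resample_isotropic`, `segment_by_threshold`,
   `fit_hu_threshold`) — cubic B-spline resampling, threshold
   segmentation with 3-D morphology, and a maximum-likelihood fit of the
   HU histogram whose 0.98 quantile separates dense cortical bone.
3. **HU → porosity** (`hu_to_porosity_trabecular`,
   `hu_to_porosity_cortical`) — split linear laws anchored at the
   trabecular HU mode (porosity 0.85) and minimum (0.92), and at the
   dense-bone threshold (porosity 0) and cortical minimum (0.5).
4. **Fabric** (`gradient_structure_tensor`) — per-voxel gradient
   structure tensor in a 7×7×7 window with a 25% boundary rule; the
   weakest-gradient eigenvector is the stiffest material axis,
   `DA = 1 − λ1/λ3`, and the Kelvin-cell aspect ratio is `R = λ3/λ1`.
5. **Micromechanics** (`cortical_stiffness`, `kelvin_cell_constants`,
   `beam_frame_unit_cell_oracle`, `map_bone_properties`,
   `nearest_voxel_assign`) — Mori–Tanaka cylindrical/spherical
   water-inclusion models for cortical bone; the elongated Kelvin-cell
   (tetrakaidecahedron) open-foam model for trabecular bone with
   `R = H/D = tan θ`, solved analytically by symmetry reduction and
   cross-validated against a periodic Timoshenko beam-frame
   homogenization; nearest-voxel mapping onto tetrahedra.
6. **Scaffold** (`generate_lattice`, `generate_ti_ring`,
   `homogenize_unit_cell`, `macroscopic_strength`) — FCC, Kelvin and
   Voronoi lattices (uniform 75% porosity or radial 90%→60% grading)
   clipped to the 27×32×9 mm cage footprint, a solid Ti6Al4V ring
   comparator, periodic voxel FE homogenization of unit cells, and the
   strength law `σ = 1.21 (1−φ)³ σ0`.
7. **FE + damage** (`solve_linear_static`, `run_interbody_case`) —
   linear tetrahedra, tied interfaces by node merging, rigid kinematic
   coupling of the superior surface to a loaded reference point
   (Standing 500 N; Flexion 1175 N + 7.5 N·m), and post-processing into
   failed scaffold volume, damaged trabecular volume (|ε_min| > 0.84%),
   fixation yield ratio / microstrains / load share, macroscopic
   stiffness and rotation.

## Worked example

```r
library(hapcage)

# strength thresholds of a 75%-porous HAp scaffold
macroscopic_strength(c(100, 350), 0.75)
#> [1] 1.890625 6.617188      # MPa, tension / compression

# phantom -> fabric recovery
sp  <- phantom_spec(body_half_axes = c(11, 9, 8), spacing = rep(0.326, 3),
                    texture_anisotropy = 0.5, seed = 7)
ph  <- make_vertebra_phantom(sp)
fab <- gradient_structure_tensor(ph$volume, ph$truth$labels == 2)
fabric_summary(fab, reference_direction = c(0, 0, 1))[
  c("median_angle_deg", "pooled_DA", "median_R")]
#> $median_angle_deg [1] 8.88     # stiff axis within 9 deg of the truth
#> $pooled_DA        [1] 0.507    # matches the seeded anisotropy 0.5
#> $median_R         [1] 2.96

# trabecular stiffness of an elongated Kelvin cell (E0 = 13 GPa)
kc <- kelvin_cell_constants(R = 1.72, porosity = 0.85, E0 = 13000)
round(c(E_axial = kc$E_axial, E_trans = kc$E_trans), 1)
#>  E_axial  E_trans
#>    258.9     54.4                # MPa: hundreds-of-MPa trabecular scale

# end-to-end phantom scene with a homogenized FCC cage
mod <- build_interbody_model(phantom_spec(seed = 42), scaffold = "fcc")
run_interbody_case(mod, load_case("flexion"))
#> damage_report (flexion):
#>   failed cage volume: 14.745% (tension 8.742%, compression 7.349%)
#>   anterior/posterior failed: 31.410% / 1.134%
#>   damaged trabecular volume: 1.241%
#>   fixation: yield ratio 46.0, load share 3.61%
#>   stiffness 15.79 kN/mm, rotation 3.45e-01 deg
```

The flexion report shows the expected mechanics: damage concentrates in
the anterior half of the cage under forward bending, the posterior
fixation carries a few percent of the load and stays far from yield, and
the fused segment is stiff with a sub-degree rotation.

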