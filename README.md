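# fibrogel

Coupled multi-scale mechanics of fibroblast-driven fibrin gel remodeling,
plus the image-analysis toolchain used to quantify it.

When clusters of dermal fibroblasts ("explants") sit on a fibrin gel —
an *in vitro* stand-in for the provisional matrix of a cutaneous wound —
their traction compacts the explants, drags the surrounding matrix inward
and aligns fibers along the corridors between explants, all within 24
hours. How far that remodeling reaches depends on the gel's constraints:
left attached to its mold (*Fixed*) versus released so only a small
central patch adheres (*Free*). `fibrogel` is for researchers in tissue
biomechanics and mechanobiology who want to simulate this system, analyze
time-lapse imaging of it, or validate either against synthetic ground
truth.

## What is inside

**The model.** The gel is a mesh of trilinear hexahedral elements; the
microstructure at each element is a cross-linked fiber-network
representative volume element (RVE). A fiber carries
`F(λ) = EfAf/B [exp(B εf) − 1]` with Green strain `εf = ½(λ² − 1)`
(defaults `EfAf = 3×10⁻¹⁰ N`, `B = 4`, fitted to a 6.8 mg/mL fibrin gel).
A deformed RVE's macroscopic Cauchy stress is the boundary-node sum
`⟨σij⟩ = (1/V) Σ xi Fj`; an additive compressible neo-Hookean term
`σᵑᴴ = G/J (B − I) + 2Gν/(J(1−2ν)) ln(J) I` (`G = 1 Pa`, `ν = 0.3`)
limits network distortion. Cell traction is modeled by uniformly
shortening the reference lengths of all fibers in the cellular (explant)
elements by 24% in equal multiplicative increments, re-solving coupled
macro/micro equilibrium after each. Both *Fixed* and *Free* boundary
conditions are built in.

**Image analysis.** A normalized-cross-correlation bead tracker with
sub-pixel refinement and lost-bead detection; cumulative / instantaneous /
period-average displacement statistics with regional grouping; explant
area and centroid-distance morphology; and an FFT-based fiber orientation
tensor with the alignment index `α = 1 − ω₁/ω₂` (0 = isotropic,
1 = fully aligned).

**Synthetic fixtures.** Bead-seeded image sequences advected by prescribed
displacement fields, and fiber textures with uniform or von Mises
orientation distributions — each with exact ground truth, so the whole
pipeline is testable without experimental data.

## Worked example

```r
library(fibrogel)

# a calibrated RVE: ~337 cross-linked fibers, nearly isotropic
net <- generate_network(seed = 1)
net
#> <fiber_network> 339 fibers, 315 nodes (194 boundary), seed 1
orientation_tensor_2d(net)
#> <orientation_result> alpha = 0.075, angle = 6.3 deg

# the fiber law at 10% stretch
fiber_force(1.1, network_material())
#> [1] 3.914712e-11      # N

# a seconds-scale smoke simulation (4x4x1 mesh, Fixed boundary)
res <- run_compaction(preset_config("paper-fixed", scale = "mini", seed = 5))
res$history[, c("increment", "compaction", "area_ratio", "dist_ratio",
                "mean_ecm_disp")]
#>   increment compaction area_ratio dist_ratio mean_ecm_disp
#> 1         0     0.0000      1.000      1.000       0.00000
#> 2         1     0.0874      0.965      0.996       0.00076
#> 3         2     0.1672      0.917      0.990       0.00175
#> 4         3     0.2400      0.854      0.982       0.00304
```

At 24% fiber shortening the explants have compacted to 85% of their
initial area, pulled 1.8% closer together, and displaced the surrounding
matrix by a few microns (`mean_ecm_disp` is the mean displacement
magnitude, in mm, of nodes outside the cellular domain). The laptop-scale
study configuration is `preset_config(..., scale = "desk")` (12×12×1
mesh, ~4 min per boundary case); `scale = "full"` encodes the complete
46×46×4 / 67,712-network configuration for cluster use.

The alignment operator recovers a known orientation distribution:

```r
tx <- render_fiber_texture(texture_spec(
  orientation = list(type = "vonmises", mu = pi/6, kappa = 2), seed = 3))
fft_alignment(tx$image)
#> <orientation_result> alpha = 0.817, angle = 31.5 deg
tx$alpha_analytic   # closed-form alpha of the distribution
#> [1] 0.822
```

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "fibrogel.R", package = "fibrogel"))') \
    simulate --preset paper-free --scale desk --seed 1 --out runs/free
```

Subcommands: `simulate`, `synth`, `track`, `align`, `report`. Every run
echoes its configuration and seed into the output directory; outputs are
legacy-VTK fields, CSV time series and tables, and multi-page TIFFs.

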