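# polycell

Finite-element mechanics of two-dimensional cell aggregates with
**polyline** (segmented, curvature-capable) cell edges, together with the
classical straight-edge (**monoline**) vertex model as its special case,
and the metrics needed to compare the two across the canonical cell–cell
interaction scenarios: annealing, single-cell and tissue engulfment,
sorting, invasion and checkerboard mixing.

The package is aimed at modellers of morphogenesis, wound healing and
cancer invasion, and at developers of force-inference methods who need
synthetic tissues whose contact angles and interface curvatures are
mechanically exact.

## The model

Each boundary between two regions (cell types or the medium) carries a net
interfacial tension γ; the cytoplasm of each cell damps its boundary nodes
through grounded orthogonal dashpots with per-node coefficient
μA/n_eff, where n_eff counts triple-junction nodes fully and intermediate
nodes at half weight.  A time step solves the overdamped saddle-point
system

    [ (1/Δt) C   Gᵀ ] [ Δu ]   [ f ]
    [     G      0  ] [ λ  ] = [ A₀ − A ]

with f the assembled rod tensions (exactly −∇ of Σ γ·length), C the
diagonal dashpot matrix, G the shoelace area gradients; −λ are the cell
pressures.  Edges are chains of straight rods joined by intermediate
nodes, kept between 2.5% and 25% of a mean cell diameter by automatic
bisection and merging; edges shorter than δ = 2.5% of a diameter undergo
T1 neighbour exchange (optionally protected by an embargo timer), and quad
junctions/rosettes are normalized into closely spaced triple junctions.
A polyline edge equilibrates to a circular arc with κ = Δp/γ
(Young–Laplace); a straight monoline edge instead transmits the shear
V = ½·Δp·L to its end junctions, perturbing the contact angles away from
the Young angles and arresting engulfment- and invasion-like motions.
The methods vignette (`vignettes/polyline-cell-mechanics.Rmd`) documents
every parameter, default and numerical choice.

## Worked example

Matched monoline/polyline runs of a 20-cell annealing aggregate with
intentional cell-size variation, uniform tensions:

```r
library(polycell)
sc <- build_scenario("annealing", seed = 7, n_cells = 20,
                     n_steps = 6000, snapshot_stride = 2000, dt_safety = 0.5)
pair <- run_pair(sc)

for (m in names(pair)) {
  term <- terminal_tissue(pair[[m]])
  method <- if (m == "monoline") "nearest_segment" else "arc_tangent"
  je <- junction_angle_errors(term, method, interior_only = TRUE)
  err <- je$rms_error[!je$flagged]
  cat(sprintf("%-9s median RMS Young-angle error: %5.2f deg (n = %d)\n",
              m, median(err), length(err)))
}
compare_trajectories(pair$monoline, pair$polyline)
```

printed:

```
monoline  median RMS Young-angle error: 12.77 deg (n = 24)
polyline  median RMS Young-angle error:  0.06 deg (n = 24)
  angle_error_pct boundary_length_pct displacement_pct curvature_terminal_diff
1        164.5272            1.576732         17.35253               0.2894534
```

The monoline junctions miss the 120° Young angles by ~13° at the median —
the equivalent-shear signature of straight edges — while circular-arc
tangents of the polyline model recover them to a twentieth of a degree.
The comparison row gives the time-averaged percentage discrepancies
between the two runs (and, for curvature, the terminal normalized mean
|κ| difference, since straight edges carry exactly zero curvature).

A thin command-line wrapper is installed at `inst/exec/polycell`
(`polycell run --config FILE --out DIR`, `compare`, `render`); run
configurations are YAML, trajectories are written as documented
line-delimited text snapshots plus an event log, metrics CSV and manifest,
and `render` emits one SVG frame per snapshot.

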