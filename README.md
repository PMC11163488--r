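# dvfmend

Quantify and reduce the *interior* uncertainty of deformable image
registration (DIR) fields, for adaptive-radiotherapy quality assurance.

## The problem

Deformable registration of daily images drives contour propagation and
dose accumulation in adaptive radiotherapy. Commercial DIR is usually
validated at organ *boundaries* — DICE similarity coefficient (DSC) and
mean distance to agreement (MDA) of propagated contours — but two fields
with identical boundaries can behave very differently *inside* an organ,
where no landmarks constrain them. The Jacobian determinant of the
deformation,

    J(x) = det(I + ∇u(x)),

is the local volume-change ratio (J = 1: volume preserving), and its
standard deviation over an organ (STD-JD) measures how erratically a
field deforms the organ interior. Low-contrast abdominal organs routinely
show "hot/cold spots" — interior regions with J far from 1 — even when
DSC and MDA look excellent.

`dvfmend` implements a mechanical remedy: keep the displacements the
registration got right (the organ surfaces) and re-derive everything
inside from linear elasticity. A tetrahedral mesh is scaled over the
organs, each element gets tissue elastic constants (E, ν), and the global
stiffness system

    K d = f,    with d₁…d_k prescribed at the driving nodes

is solved by exact partitioned elimination: the known boundary
displacements move to the right-hand side and the reduced
symmetric-positive-definite system yields the displacements of the free
nodes d_{k+1}…d_n. Two registration modes use this engine:

* **Hybrid correction** (`correct_field`): driving displacements are read
  from an *existing* DVF at organ-boundary voxels; the elastic solution
  replaces the DVF inside the mesh, and the field is untouched outside.
* **CM-FEM** (`register_cmfem`): driving displacements come from contour
  matching — each reference surface point `r_i` is matched to the moving
  surface point minimizing `G(r_i, m_j) + λ·N(r_i, m_j)`, a Euclidean
  distance plus a Gaussian-weighted local occupancy mismatch.

The package also provides the evaluation suite (DSC, MDA, Jacobian
statistics, one-tailed Wilcoxon–Mann–Whitney cohort comparisons), dose
warping with DVH/V_x summaries, NIfTI/MetaImage I/O, and a synthetic
phantom generator so the whole pipeline runs and is tested without
patient data.

## Worked example

Build a phantom "patient", deform it by a known transform, corrupt the
ground-truth field with interior bumps (organ boundaries untouched), then
correct the field mechanically:

```r
library(dvfmend)
ph  <- make_phantom(phantom_spec(seed = 42))
def <- deform_phantom(ph, "translation", list(t = c(6.5, -4.2, 3.1)))
corrupted <- corrupt_field(def$field, ph$labels, corruption_spec(seed = 42))
round(attr(corrupted, "achieved_std_jd"), 3)
#>     2     3     4
#> 0.305 0.324 0.346
corrected <- correct_field(corrupted, ph$labels, structure_labels = 2:4,
                           materials = ph$materials)
evaluate_registration(corrupted, ph$structures, def$structures)
#> Registration metric report
#>  structure   dsc   mda mean_jd std_jd frac_jd_in_range flagged
#>    organ_a 0.964 0.523       1  0.305            0.887   FALSE
#>    organ_b 0.952 0.682       1  0.324            0.877   FALSE
#>    organ_c 0.960 0.576       1  0.346            0.884   FALSE
evaluate_registration(corrected, ph$structures, def$structures)
#> Registration metric report
#>  structure   dsc   mda mean_jd std_jd frac_jd_in_range flagged
#>    organ_a 0.964 0.523       1      0                1   FALSE
#>    organ_b 0.952 0.682       1      0                1   FALSE
#>    organ_c 0.960 0.576       1      0                1   FALSE
```

Reading the reports: the corrupted field still warps every organ surface
correctly (DSC ≈ 0.96, MDA ≈ 0.6 mm — comfortably inside the 0.8 / 3 mm
QA thresholds, so `flagged` is FALSE), but its per-organ STD-JD of
0.30–0.35 reveals severe interior distortion, with only ~88 % of voxels
in the physiological J ∈ [0.8, 1.2] range. After correction the boundary
metrics are unchanged while STD-JD collapses to ~0 (the ground-truth
deformation here is a translation, so the exact interior field is
recovered).

`run_study()` repeats this comparison over many phantoms and reports a
cohort table (per-method DSC / MDA / STD-JD means ± SD and one-tailed WMW
p-values); `plot(report, "std_jd")` draws the per-method boxplots. A
command-line interface covering simulate / correct / evaluate / dose-map /
study lives at `inst/cli/dvfmend.R`.

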