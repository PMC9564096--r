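# surftrack

Topological object segmentation and tracking for image sequences, in R.

## The problem

A moving, deforming object can change appearance drastically between
frames, and a passing occluder can split it into pieces. Classical
segmentation groups pixels by appearance within single images and so cannot
tell a *texture edge* (a contrast contour interior to one surface, like a
marking on fur) from a true *occluding contour* (an object boundary), and
classical tracking relies on appearance similarity that deformation and
occlusion destroy. surftrack is for researchers in computational vision and
bio-image analysis who want both problems solved by geometry alone, without
learned models: it segments and tracks every smooth textured surface in a
sequence using only the transformations between successive frames.

## The idea

If a neighborhood of the scene contains a single surface patch, its images
in two successive frames are related by a local diffeomorphism, well
approximated to first order by a six-parameter affine map

    p  ->  A (p - c) + c + t,        a = (a11, a12, a21, a22, tx, ty).

The package decides whether such a map exists by projecting both patches
onto a bank of 18 Gabor receptive fields F_i (six orientations, three
spatial frequencies). The projections gamma_i = <F_i, f> form a *place
token*, and the receptive fields themselves are carried through the
conjugate affine transform, so that a transform g relating the patches
satisfies

    gamma'_i(p, a) = <F_i(g* o U), f'>  =  gamma_i(p),   i = 1..18.

Newton iteration on the token residual E(a) = ||gamma'(p, a) - gamma(p)||^2
(with the Jacobian assembled from *Lie germ receptive fields*, the
derivatives of the warped filters with respect to each affine parameter)
either converges — the patches are diffeomorphic, and `a` is the local
motion — or fails, which is itself the signal: at an occluding contour the
registration breaks down on the occluded side, where background material
accretes or is deleted.

From this single primitive the pipeline builds, per frame: an edge map; a
*super segmentation* labeling every contour-bounded component; side-wise
diffeomorphism tests at ~100 sampled edge neighborhoods classifying each
edge as texture (both sides agree) or occluding (they differ), with the
owner the side opposite the perceivable accretion; object segmentation maps
obtained by merging every pure-texture region (never a one-sided owner)
into its partner; and a scene graph linking components across frames
wherever a converged transform carries a patch into the next frame. The
connected components of that graph are the *invariant objects*; a backward
sweep relabels all frames with their ids, which is how pieces separated by
dynamic occlusion are reunited and per-frame segmentation mistakes vanish.

## A worked example

```r
library(surftrack)

config <- make_default_config(seed = 0)       # 160 frames, 4 moving objects
scene  <- render_sequence(config)             # frames + ground truth
run    <- run_pipeline(scene$frames,
                       pipeline_config(sampling_seed = 1),
                       gt = scene$gt)
run
#> surftrack run: 160 frames, 4 invariant objects recovered
#>   segmentation errors 2 / baseline 640 (0.31%), tracking errors 0
```

What these numbers mean: the scene graph recovered exactly the four moving
objects despite deformation, scale change and mutual partial occlusion.
Copying the super segmentation verbatim as the object segmentation would
leave each object's internal texture region unmerged in every one of the
160 frames — 640 errors. The full pipeline made 2 segmentation mistakes
(0.31% of that baseline), and after the backward tracking sweep every
remaining mistake was repaired (0 tracking errors), because the mislabelled
components were still correctly linked in the scene graph.

Lower-level entry points mirror the pipeline stages: `detect_edges()`,
`super_segmentation()`, `sample_edge_neighborhoods()`, `solve_affine()`,
`classify_edge()`, `accretion_score()`, `assign_owner()`,
`build_seg_map()`, `build_scene_graph()`, `backward_relabel()`,
`evaluate_sequence()`. A command-line wrapper with `generate`, `track` and
`evaluate` subcommands is installed under `inst/cli/surftrack.R`.

## Scope

The method assumes smooth textured surfaces under locally constant
lighting, viewed without sensor noise — the regime of the synthetic
generator. Re-identification after total occlusion, isoluminant boundaries
and learned front-ends are out of scope; see the methods vignette
(`vignettes/surface-tracking.Rmd`) for the model, parameter choices and
limitations.
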